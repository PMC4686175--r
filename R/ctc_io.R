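# Readers and writers for two on-disk dialects of a tracking result:
#  * a Cell-Tracking-Challenge-style directory: one 16-bit label-mask TIFF per
#    frame plus a whitespace-separated track file "label begin end parent"
#    (parent 0 encodes no ancestor);
#  * a self-contained JSON fixture dialect that lists markers as explicit
#    coordinate sets, so tests and fixtures never depend on TIFF specifics.

#' Directory dialect description
#'
#' Controls the file layout of [read_tracking_directory()] and
#' [write_tracking_directory()]: mask files are named
#' `<prefix><zero-padded frame><suffix>` and the lineage lives in
#' `track_file`, one line per track: `label begin end parent` with parent 0
#' meaning no ancestor.
#'
#' @param prefix,suffix Mask filename parts around the frame number.
#' @param pad_width Zero-padding of the frame number; must accommodate
#'   `n_frames - 1`.
#' @param track_file Name of the lineage text file.
#' @return An object of class `ctc_dialect`.
#' @export
ctc_dialect <- function(prefix = "mask", suffix = ".tif", pad_width = 3L,
                        track_file = "res_track.txt") {
  if (!is.numeric(pad_width) || length(pad_width) != 1L || pad_width < 1)
    stop("'pad_width' must be a positive integer")
  structure(list(prefix = prefix, suffix = suffix,
                 pad_width = as.integer(pad_width), track_file = track_file),
            class = "ctc_dialect")
}

mask_filename <- function(dialect, frame) {
  sprintf("%s%0*d%s", dialect$prefix, dialect$pad_width, frame,
          dialect$suffix)
}

read_mask <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # tolerate grey stored in chan 1
    p
  })
  if (length(pages) == 1L) pages[[1L]] else
    array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
}

mask_to_markers <- function(mask, frame) {
  labs <- sort(unique(as.vector(mask)))
  labs <- labs[labs != 0]
  lapply(labs, function(l) {
    px <- which(mask == l, arr.ind = TRUE)
    marker(l, frame, px)
  })
}

#' Read a tracking result from a mask directory
#'
#' Reads one label-mask TIFF per frame (2-D, or 3-D as a multi-page file) and
#' the lineage track file.  Markers are the full supports of each non-zero
#' label, connected or not.  The label sets found in the masks are
#' cross-checked against the track-file spans, and the assembled result must
#' pass [validate_tracking_result()].
#'
#' @param path Directory containing the mask files and the track file.
#' @param dialect A [ctc_dialect()].
#' @return A [tracking_result()].
#' @export
read_tracking_directory <- function(path, dialect = ctc_dialect()) {
  stopifnot(inherits(dialect, "ctc_dialect"))
  if (!dir.exists(path))
    stop("directory does not exist: ", path)
  tf <- file.path(path, dialect$track_file)
  if (!file.exists(tf))
    stop("track file not found: ", tf)
  if (length(readLines(tf, warn = FALSE)) == 0L) {
    tracks <- data.frame(label = integer(), t_init = integer(),
                         t_end = integer(), parent = integer())
  } else {
    tracks <- utils::read.table(tf, col.names = c("label", "t_init", "t_end",
                                                  "parent"))
    if (!all(vapply(tracks, is.numeric, TRUE)))
      stop("format error: non-integer field in track file ", tf)
  }
  n_frames <- if (nrow(tracks)) max(tracks$t_end) + 1L else
    length(list.files(path, pattern = paste0("^", dialect$prefix)))
  n_frames <- max(n_frames, 1L)
  markers <- list()
  for (f in seq_len(n_frames) - 1L) {
    mf <- file.path(path, mask_filename(dialect, f))
    if (!file.exists(mf))
      stop("missing mask file for frame ", f, ": ", mf)
    mask <- read_mask(mf)
    if (any(mask != round(mask)) || any(mask < 0))
      stop("format error: non-integer label values in ", mf)
    markers <- c(markers, mask_to_markers(mask, f))
  }
  result <- tracking_result(n_frames, tracks, markers)
  bad <- validate_tracking_result(result)
  if (length(bad))
    stop("inconsistent masks and track file in ", path, ": ",
         paste(utils::head(bad, 5L), collapse = "; "))
  result
}

rasterize_frame <- function(result, frame, shape) {
  mask <- array(0L, dim = shape)
  in_f <- result$markers[vapply(result$markers,
                                function(m) m$frame == frame, TRUE)]
  for (m in in_f) {
    idx <- m$pixels
    if (any(idx < 1L) || any(sweep(idx, 2L, shape, ">") > 0))
      stop("marker for track ", m$label, " frame ", frame,
           " falls outside the image shape")
    if (any(mask[idx] != 0L))
      stop("cannot rasterize frame ", frame,
           ": markers share a pixel")
    mask[idx] <- m$label
  }
  mask
}

#' Write a tracking result as a mask directory
#'
#' Rasterizes each frame into a 16-bit unsigned label mask (labels above 65535
#' are rejected) and writes the lineage track file.  Reading the directory
#' back reproduces the result exactly, and writing the same result twice
#' produces byte-identical files.
#'
#' @param result A valid [tracking_result()] with all coordinates >= 1.
#' @param path Output directory (created if needed).
#' @param dialect A [ctc_dialect()].
#' @param shape Image dimensions; default is the bounding box over all
#'   markers.
#' @return `path`, invisibly.
#' @export
write_tracking_directory <- function(result, path, dialect = ctc_dialect(),
                                     shape = NULL) {
  bad <- validate_tracking_result(result)
  if (length(bad))
    stop("refusing to write an invalid result: ", bad[1L])
  if (any(result$tracks$label > 65535L))
    stop("labels above 65535 cannot be stored in 16-bit masks")
  if (is.null(shape)) {
    if (length(result$markers)) {
      shape <- Reduce(pmax, lapply(result$markers,
                                   function(m) apply(m$pixels, 2L, max)))
    } else {
      shape <- c(1L, 1L)
    }
  }
  shape <- as.integer(shape)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (f in seq_len(result$n_frames) - 1L) {
    mask <- rasterize_frame(result, f, shape)
    target <- file.path(path, mask_filename(dialect, f))
    if (length(shape) == 2L) {
      tiff::writeTIFF(mask / 65535, target, bits.per.sample = 16L)
    } else {
      pages <- lapply(seq_len(shape[3L]),
                      function(s) mask[, , s] / 65535)
      tiff::writeTIFF(pages, target, bits.per.sample = 16L)
    }
  }
  tr <- result$tracks
  tr$parent[is.na(tr$parent)] <- 0L
  lines <- sprintf("%d %d %d %d", tr$label, tr$t_init, tr$t_end, tr$parent)
  writeLines(lines, file.path(path, dialect$track_file))
  invisible(path)
}

#' Read a tracking result from the JSON fixture dialect
#'
#' The document must contain `n_frames`, a `tracks` array of
#' `{label, t_init, t_end, parent}` objects (parent 0 = none) and a `markers`
#' array of `{label, frame, pixels}` objects where `pixels` is a list of
#' coordinate tuples.  Schema violations raise a format error naming the
#' offending entry; the assembled result must validate.
#'
#' @param path Path of the JSON file.
#' @return A [tracking_result()].
#' @export
read_fixture_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                  error = function(e)
                    stop("malformed JSON in ", path, ": ",
                         conditionMessage(e)))
  for (field in c("n_frames", "tracks", "markers"))
    if (is.null(doc[[field]]))
      stop("schema error in ", path, ": missing $", field)
  tracks <- as.data.frame(doc$tracks)
  if (length(doc$markers) && !all(c("label", "frame", "pixels") %in%
                                  names(doc$markers)))
    stop("schema error in ", path,
         ": $markers entries need label, frame, pixels")
  markers <- lapply(seq_along(doc$markers$label), function(i) {
    px <- doc$markers$pixels[[i]]
    if (is.null(px) || !length(px))
      stop("schema error in ", path, ": $markers[", i, "]$pixels is empty")
    marker(doc$markers$label[i], doc$markers$frame[i], px)
  })
  result <- tracking_result(doc$n_frames, tracks, markers)
  bad <- validate_tracking_result(result)
  if (length(bad))
    stop("invalid tracking result in ", path, ": ",
         paste(utils::head(bad, 5L), collapse = "; "))
  result
}

#' Write a tracking result in the JSON fixture dialect
#'
#' Lossless, byte-stable counterpart of [read_fixture_json()]: tracks are
#' ordered by label and markers by frame then label, so writing the same
#' result twice yields identical bytes.
#'
#' @param result A valid [tracking_result()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixture_json <- function(result, path) {
  bad <- validate_tracking_result(result)
  if (length(bad))
    stop("refusing to write an invalid result: ", bad[1L])
  tr <- result$tracks
  tr$parent[is.na(tr$parent)] <- 0L
  doc <- list(
    n_frames = result$n_frames,
    tracks = tr,
    markers = lapply(unname(result$markers), function(m)
      list(label = m$label, frame = m$frame,
           pixels = lapply(seq_len(nrow(m$pixels)),
                           function(i) m$pixels[i, ])))
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
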