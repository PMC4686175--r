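# Domain model: markers, tracks, tracking results, and their lineage graphs.
#
# A tracking result for an N-frame time-lapse series is the quadruple
# (Theta, P, I, T): a set of tracks, a parent function, and the initial and
# terminal frame indices of each track.  Every track owns one marker (a
# labelled set of pixel/voxel coordinates) per frame of its span.  The result
# maps onto an acyclic oriented graph whose vertices are the markers and whose
# edges are track links (consecutive markers of one track) or parent links
# (terminal marker of a track to the initial marker of a descendant track).

#' Construct a marker
#'
#' A marker is the set of pixels (or voxels) carrying one object's label in a
#' single frame.  Markers are the vertices of the lineage graph; their spatial
#' extent drives the majority-overlap detection test.
#'
#' @param label Positive integer object label.
#' @param frame Non-negative, zero-based frame index.
#' @param pixels Integer matrix of coordinates, one row per pixel, with 2 or 3
#'   columns (all markers of a result must share one dimensionality).
#'   Coordinates are 1-based array indices; duplicated rows are dropped.
#' @return An object of class `aogm_marker` with fields `label`, `frame` and
#'   `pixels`.
#' @examples
#' m <- marker(1, 0, rbind(c(5, 5), c(5, 6)))
#' @export
marker <- function(label, frame, pixels) {
  if (!is.numeric(label) || length(label) != 1L || is.na(label) ||
      label < 1 || label != round(label))
    stop("'label' must be a single positive integer")
  if (!is.numeric(frame) || length(frame) != 1L || is.na(frame) ||
      frame < 0 || frame != round(frame))
    stop("'frame' must be a single non-negative integer")
  if (is.data.frame(pixels)) pixels <- as.matrix(pixels)
  if (is.null(dim(pixels))) pixels <- matrix(pixels, nrow = 1L)
  if (!is.matrix(pixels) || nrow(pixels) == 0L)
    stop("'pixels' must be a non-empty matrix of coordinates")
  if (!ncol(pixels) %in% c(2L, 3L))
    stop("coordinates must be 2-D or 3-D")
  if (anyNA(pixels) || any(pixels != round(pixels)))
    stop("coordinates must be integers")
  storage.mode(pixels) <- "integer"
  dimnames(pixels) <- NULL
  pixels <- pixels[!duplicated(pixel_keys(pixels)), , drop = FALSE]
  structure(list(label = as.integer(label), frame = as.integer(frame),
                 pixels = pixels),
            class = "aogm_marker")
}

#' @export
print.aogm_marker <- function(x, ...) {
  cat(sprintf("<marker> label %d, frame %d, %d pixel(s), %d-D\n",
              x$label, x$frame, nrow(x$pixels), ncol(x$pixels)))
  invisible(x)
}

# One string per coordinate row; set arithmetic on markers runs on these keys.
pixel_keys <- function(pixels) {
  do.call(paste, c(lapply(seq_len(ncol(pixels)), function(j) pixels[, j]),
                   sep = ","))
}

# Canonical id of the marker of track `label` in frame `frame`.
marker_key <- function(label, frame) sprintf("%d.%d", label, frame)

#' Construct a tracking result
#'
#' Bundles the track table (the quadruple Theta, P, I, T) with the per-frame
#' markers.  `parent` uses `NA` for tracks without an ancestor; a value `j`
#' means the track descends from track `j` (division, or reappearance after a
#' temporal gap).
#'
#' @param n_frames Number of frames N of the time-lapse series; frames are
#'   indexed 0 to N-1.
#' @param tracks Data frame with integer columns `label`, `t_init`, `t_end`,
#'   `parent` (`NA` or `0` encode no parent).
#' @param markers List of [marker()] objects, one per frame of each track's
#'   span.
#' @return An object of class `tracking_result`.
#' @seealso [validate_tracking_result()], [tracks_to_graph()]
#' @export
tracking_result <- function(n_frames, tracks = NULL, markers = list()) {
  if (!is.numeric(n_frames) || length(n_frames) != 1L || is.na(n_frames) ||
      n_frames < 1 || n_frames != round(n_frames))
    stop("'n_frames' must be a single positive integer")
  if (is.null(tracks))
    tracks <- data.frame(label = integer(), t_init = integer(),
                         t_end = integer(), parent = integer())
  tracks <- as.data.frame(tracks)
  need <- c("label", "t_init", "t_end", "parent")
  if (!all(need %in% names(tracks)))
    stop("'tracks' must have columns label, t_init, t_end, parent")
  tracks <- tracks[need]
  for (cl in need) tracks[[cl]] <- as.integer(tracks[[cl]])
  tracks$parent[!is.na(tracks$parent) & tracks$parent == 0L] <- NA_integer_
  tracks <- tracks[order(tracks$label), , drop = FALSE]
  rownames(tracks) <- NULL
  if (!all(vapply(markers, inherits, TRUE, "aogm_marker")))
    stop("'markers' must be a list of aogm_marker objects")
  keys <- vapply(markers, function(m) marker_key(m$label, m$frame), "")
  if (anyDuplicated(keys))
    stop("duplicated marker for track/frame: ", keys[duplicated(keys)][1L])
  names(markers) <- keys
  ord <- order(vapply(markers, function(m) m$frame, 0L),
               vapply(markers, function(m) m$label, 0L))
  markers <- markers[ord]
  structure(list(n_frames = as.integer(n_frames), tracks = tracks,
                 markers = markers),
            class = "tracking_result")
}

#' @export
print.tracking_result <- function(x, ...) {
  cat(sprintf("<tracking_result> %d frame(s), %d track(s), %d marker(s)\n",
              x$n_frames, nrow(x$tracks), length(x$markers)))
  invisible(x)
}

#' Validate a tracking result
#'
#' Checks the structural invariants: track spans lie within the series, every
#' track has exactly one marker per frame of its span and none outside it,
#' parent tracks exist and terminate strictly before their children start, and
#' marker pixel sets within any single frame are pairwise disjoint.
#'
#' Validation never throws: it returns a character vector of human-readable
#' violation descriptors (empty when the result is well formed), naming the
#' offending track, frame, or pixel.  Loaders and graph construction decide
#' whether to abort.
#'
#' @param result A [tracking_result()].
#' @return Character vector of violations; `character(0)` if valid.
#' @export
validate_tracking_result <- function(result) {
  stopifnot(inherits(result, "tracking_result"))
  v <- character()
  tr <- result$tracks
  n <- result$n_frames
  if (anyDuplicated(tr$label))
    v <- c(v, sprintf("duplicated track label %d",
                      tr$label[duplicated(tr$label)]))
  bad_span <- is.na(tr$t_init) | is.na(tr$t_end) |
    tr$t_init < 0L | tr$t_end > n - 1L | tr$t_init > tr$t_end
  v <- c(v, sprintf("track %d: invalid span [%d, %d] for %d frame(s)",
                    tr$label[bad_span], tr$t_init[bad_span],
                    tr$t_end[bad_span], n))
  has_par <- !is.na(tr$parent)
  v <- c(v, sprintf("track %d: is its own parent",
                    tr$label[has_par & tr$parent == tr$label]))
  pi <- match(tr$parent, tr$label)
  dangling <- has_par & is.na(pi)
  v <- c(v, sprintf("track %d: parent %d does not exist",
                    tr$label[dangling], tr$parent[dangling]))
  ok_par <- has_par & !is.na(pi) & tr$parent != tr$label
  late <- ok_par & tr$t_end[pi] >= tr$t_init
  v <- c(v, sprintf(
    "track %d: parent %d terminates at frame %d, not before child start %d",
    tr$label[late], tr$parent[late], tr$t_end[pi][late], tr$t_init[late]))
  # marker coverage: one marker per spanned frame, none elsewhere
  span_ok <- !bad_span
  expected <- unlist(lapply(which(span_ok), function(i)
    marker_key(tr$label[i], tr$t_init[i]:tr$t_end[i])))
  have <- names(result$markers)
  gaps <- setdiff(expected, have)
  v <- c(v, sprintf("temporal gap: no marker for track/frame %s", gaps))
  orphans <- setdiff(have, expected)
  v <- c(v, sprintf("orphan marker %s outside any track span", orphans))
  for (key in have) {
    m <- result$markers[[key]]
    if (marker_key(m$label, m$frame) != key)
      v <- c(v, sprintf("marker stored under %s has label %d, frame %d",
                        key, m$label, m$frame))
  }
  dims <- unique(vapply(result$markers, function(m) ncol(m$pixels), 0L))
  if (length(dims) > 1L)
    v <- c(v, "markers mix 2-D and 3-D coordinates")
  # within-frame disjointness
  frames <- unique(vapply(result$markers, function(m) m$frame, 0L))
  for (f in frames) {
    in_f <- result$markers[vapply(result$markers,
                                  function(m) m$frame == f, TRUE)]
    if (length(in_f) < 2L) next
    keys <- lapply(in_f, function(m) pixel_keys(m$pixels))
    all_keys <- unlist(keys, use.names = FALSE)
    dup <- unique(all_keys[duplicated(all_keys)])
    v <- c(v, sprintf("overlap: frame %d pixel (%s) belongs to several markers",
                      f, dup))
  }
  v
}

#' Build the lineage graph of a tracking result
#'
#' Transforms the quadruple (Theta, P, I, T) into its acyclic oriented graph:
#' vertices are all markers; a track link joins each pair of consecutive
#' markers within a track; a parent link joins the terminal marker of a parent
#' track to the initial marker of each descendant.  Edge semantics are "T"
#' (track link) or "P" (parent link).  Edges always point forward in time,
#' which forces acyclicity.
#'
#' @param result A valid [tracking_result()].
#' @return An object of class `tracking_graph` with fields `vertices`
#'   (data frame `key`, `label`, `frame`), `edges` (data frame `from`, `to`,
#'   `semantics`), `markers`, and `n_frames`.
#' @export
tracks_to_graph <- function(result) {
  bad <- validate_tracking_result(result)
  if (length(bad))
    stop("invalid tracking result: ", bad[1L])
  tr <- result$tracks
  vertices <- data.frame(
    key = names(result$markers),
    label = vapply(result$markers, function(m) m$label, 0L),
    frame = vapply(result$markers, function(m) m$frame, 0L),
    row.names = NULL)
  from <- to <- sem <- character()
  for (i in seq_len(nrow(tr))) {
    if (tr$t_end[i] > tr$t_init[i]) {
      ts <- tr$t_init[i]:(tr$t_end[i] - 1L)
      from <- c(from, marker_key(tr$label[i], ts))
      to <- c(to, marker_key(tr$label[i], ts + 1L))
      sem <- c(sem, rep("T", length(ts)))
    }
  }
  kids <- which(!is.na(tr$parent))
  if (length(kids)) {
    pi <- match(tr$parent[kids], tr$label)
    from <- c(from, marker_key(tr$label[pi], tr$t_end[pi]))
    to <- c(to, marker_key(tr$label[kids], tr$t_init[kids]))
    sem <- c(sem, rep("P", length(kids)))
  }
  edges <- data.frame(from = from, to = to, semantics = sem)
  structure(list(vertices = vertices, edges = edges,
                 markers = result$markers, n_frames = result$n_frames),
            class = "tracking_graph")
}

#' @export
print.tracking_graph <- function(x, ...) {
  cat(sprintf(
    "<tracking_graph> %d vertex(es), %d edge(s) (%d track, %d parent)\n",
    nrow(x$vertices), nrow(x$edges), sum(x$edges$semantics == "T"),
    sum(x$edges$semantics == "P")))
  invisible(x)
}

#' Restrict a lineage graph to an initial span of frames
#'
#' Returns the subgraph induced by the vertices with frame index at most
#' `t_max`, preserving edge semantics.  Used to study how the accuracy measure
#' evolves as ground truth accumulates frame by frame.
#'
#' @param graph A [tracks_to_graph()] result.
#' @param t_max Last frame (0-based) to keep; must lie in `[0, n_frames - 1]`.
#' @return A `tracking_graph` covering frames `0..t_max`.
#' @export
restrict_to_frames <- function(graph, t_max) {
  stopifnot(inherits(graph, "tracking_graph"))
  if (!is.numeric(t_max) || length(t_max) != 1L || is.na(t_max) ||
      t_max < 0 || t_max > graph$n_frames - 1L || t_max != round(t_max))
    stop("'t_max' must be a frame index in [0, ", graph$n_frames - 1L, "]")
  keep <- graph$vertices$frame <= t_max
  vertices <- graph$vertices[keep, , drop = FALSE]
  rownames(vertices) <- NULL
  ekeep <- graph$edges$to %in% vertices$key
  edges <- graph$edges[ekeep, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(vertices = vertices, edges = edges,
                 markers = graph$markers[vertices$key],
                 n_frames = as.integer(t_max) + 1L),
            class = "tracking_graph")
}
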