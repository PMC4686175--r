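# Core matching machinery: the majority-overlap detection test, unique vertex
# matching, vertex classification, the induced subgraph on uniquely matched
# computed vertices, and edge-error classification.

#' Majority-overlap detection test
#'
#' A reference marker is assigned to a computed marker if and only if the
#' computed marker covers a strict majority of the reference marker's pixels:
#' `|ref & comp| > 0.5 * |ref|`.  Strictness means an exactly-half overlap
#' fails; together with the within-frame disjointness of computed markers this
#' makes the assignment of every reference marker unique, so no optimisation
#' is ever needed to match the graphs.
#'
#' @param ref,comp Two [marker()] objects from the same frame.
#' @return `TRUE` if `ref` is assigned to `comp`.
#' @export
detection_test <- function(ref, comp) {
  stopifnot(inherits(ref, "aogm_marker"), inherits(comp, "aogm_marker"))
  if (ref$frame != comp$frame)
    stop("markers come from different frames (", ref$frame, " vs ",
         comp$frame, ")")
  overlap <- sum(pixel_keys(ref$pixels) %in% pixel_keys(comp$pixels))
  overlap > 0.5 * nrow(ref$pixels)
}

#' Match reference vertices to computed vertices
#'
#' Runs the detection test frame by frame for every (reference, computed)
#' marker pair, conceptually filling the binary |V_R| x |V_C| detection
#' matrix.  Each reference marker ends up assigned to at most one computed
#' marker; a computed marker may collect several reference markers (its
#' "fiber"), which happens e.g. when daughter cells after an undetected
#' division stay clustered in a single computed marker.
#'
#' Uniqueness of the assignment is guaranteed by the strict majority rule and
#' verified while building the per-frame pixel occupancy; a violation signals
#' overlapping computed markers that slipped past validation.
#'
#' @param ref,comp Two [tracks_to_graph()] objects.
#' @return An object of class `vertex_matching` with `assignment` (named
#'   character vector, reference key to computed key or `NA`) and `fibers`
#'   (list, computed key to character vector of assigned reference keys).
#' @export
match_vertices <- function(ref, comp) {
  stopifnot(inherits(ref, "tracking_graph"), inherits(comp, "tracking_graph"))
  assignment <- rep(NA_character_, nrow(ref$vertices))
  names(assignment) <- ref$vertices$key
  frames <- sort(unique(ref$vertices$frame))
  for (f in frames) {
    ck <- comp$vertices$key[comp$vertices$frame == f]
    if (!length(ck)) next
    npix <- vapply(ck, function(k) nrow(comp$markers[[k]]$pixels), 0L)
    occ_pix <- unlist(lapply(ck, function(k)
      pixel_keys(comp$markers[[k]]$pixels)), use.names = FALSE)
    occ_key <- rep(ck, npix)
    if (anyDuplicated(occ_pix))
      stop("internal consistency error: computed markers overlap in frame ", f)
    rk <- ref$vertices$key[ref$vertices$frame == f]
    for (k in rk) {
      pk <- pixel_keys(ref$markers[[k]]$pixels)
      hit <- occ_key[match(pk, occ_pix)]
      hit <- hit[!is.na(hit)]
      if (!length(hit)) next
      tab <- table(hit)
      if (sum(tab > 0.5 * length(pk)) > 1L)
        stop("internal consistency error: reference marker ", k,
             " matches several computed markers")
      best <- which.max(tab)
      if (tab[[best]] > 0.5 * length(pk))
        assignment[[k]] <- names(tab)[best]
    }
  }
  matched <- !is.na(assignment)
  fibers <- split(names(assignment)[matched], assignment[matched])
  structure(list(assignment = assignment, fibers = fibers),
            class = "vertex_matching")
}

#' Classify vertices of both graphs
#'
#' Partitions the reference vertices into true positives (assigned to some
#' computed marker) and false negatives, and the computed vertices into true
#' positives (exactly one reference marker assigned), false positives (none),
#' and non-split vertices (two or more).  The number of split operations is
#' `NS = TP - |{computed vertices with >= 1 reference assigned}|`: a non-split
#' vertex with a fiber of size m needs m - 1 splits.
#'
#' @param matching A [match_vertices()] result.
#' @param ref,comp The graphs the matching was computed from.
#' @return An object of class `vertex_classification` carrying the four vertex
#'   sets, the counts `TP`, `FN`, `FP`, `VS`, `NS`, the number of matched
#'   computed vertices, and `m_star`, the largest fiber size over non-split
#'   vertices (1 when there is none).
#' @export
classify_vertices <- function(matching, ref, comp) {
  stopifnot(inherits(matching, "vertex_matching"),
            inherits(ref, "tracking_graph"), inherits(comp, "tracking_graph"))
  a <- matching$assignment
  ref_tp <- names(a)[!is.na(a)]
  ref_fn <- names(a)[is.na(a)]
  sizes <- lengths(matching$fibers)
  matched_comp <- names(matching$fibers)
  comp_vs <- matched_comp[sizes >= 2L]
  comp_tp <- matched_comp[sizes == 1L]
  comp_fp <- setdiff(comp$vertices$key, matched_comp)
  structure(list(
    ref_true_positive = ref_tp,
    ref_false_negative = ref_fn,
    comp_true_positive = comp_tp,
    comp_false_positive = comp_fp,
    comp_non_split = comp_vs,
    TP = length(ref_tp), FN = length(ref_fn), FP = length(comp_fp),
    VS = length(comp_vs),
    NS = length(ref_tp) - length(matched_comp),
    matched_comp = length(matched_comp),
    m_star = if (length(comp_vs)) max(sizes[sizes >= 2L]) else 1L
  ), class = "vertex_classification")
}

#' Induced subgraph on uniquely matched computed vertices
#'
#' Edge errors are evaluated only on the subgraph of the computed graph
#' induced by its true-positive (uniquely matched) vertices: edges touching a
#' false positive or a non-split vertex are inherently removed together with
#' deleting or splitting those vertices, so they never count as edge errors.
#'
#' @param comp The computed [tracks_to_graph()].
#' @param cls A [classify_vertices()] result for `comp`.
#' @return Data frame of edges (`from`, `to`, `semantics`) with both endpoints
#'   uniquely matched.
#' @export
induced_subgraph <- function(comp, cls) {
  stopifnot(inherits(comp, "tracking_graph"),
            inherits(cls, "vertex_classification"))
  e <- comp$edges
  keep <- e$from %in% cls$comp_true_positive &
    e$to %in% cls$comp_true_positive
  out <- e[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify edge errors
#'
#' A reference edge matches a computed edge when both endpoint detection tests
#' pass, which forces identical frame indices at both ends.  On the induced
#' subgraph this yields three disjoint error sets: redundant edges (computed
#' edges whose matched reference endpoint pair is not a reference edge),
#' missing edges (reference edges with no matching induced edge), and
#' wrong-semantics edges (matching pairs where a track link stands in for a
#' parent link or vice versa).
#'
#' @param ref The reference [tracks_to_graph()].
#' @param induced The [induced_subgraph()] edge set of the computed graph.
#' @param matching The [match_vertices()] result of the same comparison.
#' @return An object of class `edge_errors` with the three edge sets
#'   (`redundant`, `missing`, `wrong_semantics`) and counts `ED`, `EA`, `EC`.
#' @export
compute_edge_errors <- function(ref, induced, matching) {
  stopifnot(inherits(ref, "tracking_graph"),
            inherits(matching, "vertex_matching"))
  single_ref <- vapply(matching$fibers,
                       function(x) if (length(x) == 1L) x else NA_character_,
                       "")
  ref_ids <- paste(ref$edges$from, ref$edges$to, sep = "->")
  if (nrow(induced)) {
    ru <- unname(single_ref[induced$from])
    rv <- unname(single_ref[induced$to])
    ind_ids <- paste(ru, rv, sep = "->")
    pos <- match(ind_ids, ref_ids)
    is_match <- !is.na(pos)
  } else {
    is_match <- logical(0)
    pos <- integer(0)
  }
  redundant <- induced[!is_match, , drop = FALSE]
  matched <- induced[is_match, , drop = FALSE]
  ref_sem <- ref$edges$semantics[pos[is_match]]
  wrong <- matched[ref_sem != matched$semantics, , drop = FALSE]
  missing <- ref$edges[!(seq_along(ref_ids) %in% pos[is_match]), ,
                       drop = FALSE]
  rownames(redundant) <- rownames(wrong) <- rownames(missing) <- NULL
  structure(list(redundant = redundant, missing = missing,
                 wrong_semantics = wrong,
                 ED = nrow(redundant), EA = nrow(missing), EC = nrow(wrong)),
            class = "edge_errors")
}

#' Compare two lineage graphs
#'
#' Deterministic composition of [match_vertices()], [classify_vertices()],
#' [induced_subgraph()] and [compute_edge_errors()], yielding the six error
#' counts and the bookkeeping needed by the weighted measure.
#'
#' @param ref,comp Reference and computed [tracks_to_graph()] objects.
#' @return An object of class `aogm_comparison`; its `$counts` field is an
#'   [error_counts()] object.
#' @export
compare_graphs <- function(ref, comp) {
  m <- match_vertices(ref, comp)
  cls <- classify_vertices(m, ref, comp)
  ind <- induced_subgraph(comp, cls)
  ee <- compute_edge_errors(ref, ind, m)
  counts <- error_counts(
    NS = cls$NS, FN = cls$FN, FP = cls$FP,
    ED = ee$ED, EA = ee$EA, EC = ee$EC,
    n_ref_vertices = nrow(ref$vertices), n_ref_edges = nrow(ref$edges),
    m_star = cls$m_star)
  structure(list(
    counts = counts, classification = cls, edge_errors = ee, matching = m,
    n_ref_vertices = nrow(ref$vertices), n_ref_edges = nrow(ref$edges),
    n_comp_vertices = nrow(comp$vertices), n_comp_edges = nrow(comp$edges),
    induced_edges = ind
  ), class = "aogm_comparison")
}

#' Compare two tracking results
#'
#' Validates both results, converts them to lineage graphs, and runs the full
#' graph comparison.
#'
#' @param ref,comp Reference and computed [tracking_result()] objects covering
#'   the same number of frames.
#' @return An `aogm_comparison`; see [compare_graphs()].
#' @examples
#' ex <- worked_example()
#' cmp <- compare_tracking(ex$reference, ex$computed)
#' cmp$counts
#' @export
compare_tracking <- function(ref, comp) {
  stopifnot(inherits(ref, "tracking_result"),
            inherits(comp, "tracking_result"))
  if (ref$n_frames != comp$n_frames)
    stop("results cover different numbers of frames (", ref$n_frames,
         " vs ", comp$n_frames, ")")
  compare_graphs(tracks_to_graph(ref), tracks_to_graph(comp))
}

#' @export
print.aogm_comparison <- function(x, ...) {
  c6 <- x$counts
  cat("<aogm_comparison>\n")
  cat(sprintf("  reference: %d vertex(es), %d edge(s); computed: %d, %d\n",
              x$n_ref_vertices, x$n_ref_edges,
              x$n_comp_vertices, x$n_comp_edges))
  cat(sprintf("  NS=%d FN=%d FP=%d ED=%d EA=%d EC=%d (m*=%d)\n",
              c6$NS, c6$FN, c6$FP, c6$ED, c6$EA, c6$EC, c6$m_star))
  invisible(x)
}
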