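# Weighted aggregation of the six error counts, the detection-only and
# association-only variants, the minimality condition on the weights,
# normalised error rates, and the temporal evolution of the measure.

#' Weight vector for the six error types
#'
#' Non-negative penalties for the six graph operations: split a vertex (`ns`),
#' add a vertex (`fn`), delete a vertex (`fp`), delete an edge (`ed`), add an
#' edge (`ea`) and alter edge semantics (`ec`).  The defaults are the
#' reference configuration of the first Cell Tracking Challenge, chosen to
#' reflect the manual effort of correcting each error type; it satisfies the
#' minimality condition for every m*.
#'
#' @param ns,fn,fp,ed,ea,ec Non-negative penalties; at least one must be
#'   positive.
#' @return Named numeric vector of class `aogm_weights`.
#' @export
aogm_weights <- function(ns = 5, fn = 10, fp = 1, ed = 1, ea = 1.5, ec = 1) {
  w <- c(ns = ns, fn = fn, fp = fp, ed = ed, ea = ea, ec = ec)
  validate_weights(w)
  structure(w, class = "aogm_weights")
}

validate_weights <- function(w) {
  if (!is.numeric(w) || length(w) != 6L || anyNA(w))
    stop("weights must be six numeric values")
  if (is.null(names(w)) || !identical(sort(names(w)),
                                      sort(c("ns", "fn", "fp", "ed", "ea",
                                             "ec"))))
    stop("weights must be named ns, fn, fp, ed, ea, ec")
  if (any(w < 0))
    stop("weights must be non-negative")
  if (all(w == 0))
    stop("at least one weight must be positive")
  invisible(w)
}

#' Error counts of a tracking comparison
#'
#' Container for the six tallies together with the context needed by
#' normalised rates and the minimality condition: the number of reference
#' vertices and edges and m*, the largest number of reference markers sharing
#' one computed marker.
#'
#' @param NS,FN,FP,ED,EA,EC Non-negative integer error counts.
#' @param n_ref_vertices,n_ref_edges Sizes of the reference graph (may be `NA`
#'   when only aggregation is needed).
#' @param m_star Largest fiber size over non-split vertices; 1 when there is
#'   none.
#' @return An object of class `error_counts`.
#' @export
error_counts <- function(NS = 0, FN = 0, FP = 0, ED = 0, EA = 0, EC = 0,
                         n_ref_vertices = NA_integer_,
                         n_ref_edges = NA_integer_, m_star = 1L) {
  cnt <- c(NS = NS, FN = FN, FP = FP, ED = ED, EA = EA, EC = EC)
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("error counts must be non-negative integers")
  structure(list(NS = as.integer(NS), FN = as.integer(FN),
                 FP = as.integer(FP), ED = as.integer(ED),
                 EA = as.integer(EA), EC = as.integer(EC),
                 n_ref_vertices = as.integer(n_ref_vertices),
                 n_ref_edges = as.integer(n_ref_edges),
                 m_star = as.integer(m_star)),
            class = "error_counts")
}

#' @export
print.error_counts <- function(x, ...) {
  cat(sprintf("<error_counts> NS=%d FN=%d FP=%d ED=%d EA=%d EC=%d\n",
              x$NS, x$FN, x$FP, x$ED, x$EA, x$EC))
  invisible(x)
}

as_error_counts <- function(x) {
  if (inherits(x, "aogm_comparison")) return(x$counts)
  if (inherits(x, "error_counts")) return(x)
  stop("expected an 'aogm_comparison' or 'error_counts' object")
}

#' Zero the weights outside a measure variant
#'
#' The detection variant (AOGM-D) keeps only the vertex-related weights
#' positive and therefore scores the ability to detect objects; the
#' association variant (AOGM-A) keeps only the edge-related weights and scores
#' the ability to follow objects in time.  `"full"` returns the weights
#' unchanged.
#'
#' @param weights An [aogm_weights()] vector.
#' @param variant One of `"full"`, `"detection"`, `"association"`.
#' @return The adjusted weight vector.
#' @export
variant_weights <- function(weights,
                            variant = c("full", "detection", "association")) {
  validate_weights(weights)
  variant <- match.arg(variant)
  w <- unclass(weights)
  if (variant == "detection") w[c("ed", "ea", "ec")] <- 0
  if (variant == "association") w[c("ns", "fn", "fp")] <- 0
  if (all(w == 0))
    stop("variant '", variant, "' zeroes every positive weight")
  structure(w, class = "aogm_weights")
}

#' Aggregate error counts into the weighted measure
#'
#' The measure is the weighted sum
#' `w_ns*NS + w_fn*FN + w_fp*FP + w_ed*ED + w_ea*EA + w_ec*EC`: the cost of
#' transforming the computed graph into the reference one using the six graph
#' operations.  It is zero exactly when every positively weighted count is
#' zero, and grows without bound with the complexity of the required
#' transformation.
#'
#' @param x An `aogm_comparison` or [error_counts()] object.
#' @param weights An [aogm_weights()] vector.
#' @param variant Measure variant, see [variant_weights()].
#' @return A single non-negative number.
#' @examples
#' aogm(error_counts(NS = 5, FN = 5, FP = 3, ED = 1, EA = 16, EC = 2))
#' @export
aogm <- function(x, weights = aogm_weights(),
                 variant = c("full", "detection", "association")) {
  cnt <- as_error_counts(x)
  w <- variant_weights(weights, match.arg(variant))
  w <- unclass(w)[c("ns", "fn", "fp", "ed", "ea", "ec")]
  sum(w * c(cnt$NS, cnt$FN, cnt$FP, cnt$ED, cnt$EA, cnt$EC))
}

#' Minimality condition on the weights
#'
#' A non-split vertex with m assigned reference markers can be corrected
#' either by m - 1 split operations or by deleting it and adding m vertices.
#' The measure value equals the minimum transformation cost whenever
#' `w_ns * (m* - 1) <= w_fp + w_fn * m*`, with m* the largest fiber size in
#' the comparison.  The weakened, input-independent form is `w_ns <= w_fn`.
#'
#' @param weights An [aogm_weights()] vector.
#' @param m_star Largest fiber size over non-split vertices (>= 1).
#' @return List with logical fields `holds` (the condition at `m_star`) and
#'   `weakened` (the input-independent condition).
#' @export
check_minimality <- function(weights, m_star = 1L) {
  validate_weights(weights)
  if (!is.numeric(m_star) || length(m_star) != 1L || is.na(m_star) ||
      m_star < 1)
    stop("'m_star' must be a single integer >= 1")
  w <- unclass(weights)
  list(holds = w[["ns"]] * (m_star - 1) <= w[["fp"]] + w[["fn"]] * m_star,
       weakened = w[["ns"]] <= w[["fn"]])
}

#' Normalised error rates
#'
#' Vertex-level counts (NS, FN, FP) divided by the number of reference
#' vertices and edge-level counts (ED, EA, EC) divided by the number of
#' reference edges, so datasets with different object counts become
#' comparable.  Zero denominators yield `NA` rates rather than errors.
#'
#' @param x An `aogm_comparison` or [error_counts()] object carrying reference
#'   graph sizes.
#' @return Named numeric vector with elements `NS`, `FN`, `FP`, `ED`, `EA`,
#'   `EC`.
#' @export
normalized_rates <- function(x) {
  cnt <- as_error_counts(x)
  nv <- cnt$n_ref_vertices
  ne <- cnt$n_ref_edges
  vd <- if (is.na(nv) || nv == 0L) NA_real_ else as.numeric(nv)
  ed <- if (is.na(ne) || ne == 0L) NA_real_ else as.numeric(ne)
  c(NS = cnt$NS / vd, FN = cnt$FN / vd, FP = cnt$FP / vd,
    ED = cnt$ED / ed, EA = cnt$EA / ed, EC = cnt$EC / ed)
}

#' Temporal evolution of the measure
#'
#' Recomputes the comparison on the frame prefix `0..t` for every `t`,
#' showing how the measure accumulates as ground truth grows and after how
#' many frames algorithm rankings stabilise.  The final entry equals the
#' measure on the full series.
#'
#' @param ref,comp Reference and computed [tracking_result()] objects.
#' @param weights An [aogm_weights()] vector.
#' @param variant Measure variant, see [variant_weights()].
#' @return Data frame with columns `frame` (0-based prefix end) and `value`.
#' @export
temporal_evolution <- function(ref, comp, weights = aogm_weights(),
                               variant = c("full", "detection",
                                           "association")) {
  stopifnot(inherits(ref, "tracking_result"),
            inherits(comp, "tracking_result"))
  variant <- match.arg(variant)
  if (ref$n_frames != comp$n_frames)
    stop("results cover different numbers of frames")
  gr <- tracks_to_graph(ref)
  gc <- tracks_to_graph(comp)
  ts <- 0:(ref$n_frames - 1L)
  values <- vapply(ts, function(t) {
    aogm(compare_graphs(restrict_to_frames(gr, t),
                        restrict_to_frames(gc, t)),
         weights = weights, variant = variant)
  }, 0)
  data.frame(frame = ts, value = values)
}
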