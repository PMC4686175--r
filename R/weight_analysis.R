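# Sensitivity of algorithm rankings to the choice of weights: ranking under a
# configuration, Kendall transposition distance between rankings, and 2-D
# weight-space sector maps showing which regions of weight space preserve a
# reference ranking.

#' Rank algorithms by their measure values
#'
#' Lower measure values mean fewer (weighted) errors, so algorithms are
#' ranked ascending: rank 1 is the best.  Exact ties are never broken
#' silently; tied algorithms share the smaller rank and the result is
#' flagged.
#'
#' @param x Either a list of [error_counts()] / `aogm_comparison` objects
#'   (values are computed with `weights`/`variant`), or a numeric vector of
#'   already-computed measure values.
#' @param weights An [aogm_weights()] vector (ignored for numeric input).
#' @param variant Measure variant, see [variant_weights()].
#' @return An object of class `aogm_ranking` with fields `values`, `ranking`
#'   (integer ranks, ties share the minimum) and `tie` (logical flag).
#' @examples
#' rank_algorithms(c(1415, 6376, 4977, 2879))$ranking  # 1 4 3 2
#' @export
rank_algorithms <- function(x, weights = aogm_weights(),
                            variant = c("full", "detection", "association")) {
  variant <- match.arg(variant)
  values <- if (is.numeric(x)) {
    as.numeric(x)
  } else {
    if (length(x) < 2L) stop("need at least two algorithms to rank")
    vapply(x, aogm, 0, weights = weights, variant = variant)
  }
  if (length(values) < 2L) stop("need at least two algorithms to rank")
  structure(list(values = values,
                 ranking = as.integer(rank(values, ties.method = "min")),
                 tie = anyDuplicated(values) > 0L),
            class = "aogm_ranking")
}

#' @export
print.aogm_ranking <- function(x, ...) {
  cat("<aogm_ranking>", paste(x$ranking, collapse = " "),
      if (x$tie) "(ties present)" else "", "\n")
  invisible(x)
}

#' Kendall transposition distance between two rankings
#'
#' Counts the discordant pairs: pairs of algorithms ordered one way in `r`
#' and the other way in `reference`.  Zero means identical rankings; the
#' maximum is `n * (n - 1) / 2` for a full reversal.
#'
#' @param r,reference Two rankings of the same algorithms: integer vectors of
#'   equal length, or `aogm_ranking` objects.
#' @return Non-negative integer count of transpositions.
#' @export
transpositions <- function(r, reference) {
  if (inherits(r, "aogm_ranking")) r <- r$ranking
  if (inherits(reference, "aogm_ranking")) reference <- reference$ranking
  if (length(r) != length(reference))
    stop("rankings must cover the same algorithms")
  n <- length(r)
  if (n < 2L) return(0L)
  count <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if ((r[i] - r[j]) * (reference[i] - reference[j]) < 0)
      count <- count + 1L
  }
  count
}

#' Map ranking sectors over a 2-D slice of weight space
#'
#' Varies two chosen weights over a rectangular domain (the others stay at
#' `fixed`), recomputes the ranking at every grid point, and groups the
#' points into sectors of identical ranking.  Because the measure is linear
#' in the weights, true sectors are polygonal; the grid sampling reports
#' their relative areas and the number of transpositions of each sector's
#' ranking against the ranking at a reference configuration (the domain
#' centre by default).  Grid points where at least two algorithms tie
#' exactly fall into a separate `"tie"` pseudo-sector rather than being
#' broken arbitrarily.
#'
#' @param counts_list List of [error_counts()] / `aogm_comparison` objects,
#'   one per algorithm.
#' @param axes Character vector of two distinct weight names (among `"ns"`,
#'   `"fn"`, `"fp"`, `"ed"`, `"ea"`, `"ec"`).
#' @param domain List of two `c(lo, hi)` ranges, one per axis.
#' @param fixed An [aogm_weights()] vector supplying the non-varied weights.
#' @param resolution Number of grid points per axis (>= 2).
#' @param reference_point Numeric length-2 weight pair whose ranking anchors
#'   the transposition counts; defaults to the domain centre and must lie
#'   inside the domain.
#' @return An object of class `sector_map` with the per-cell `grid` data
#'   frame, the `sectors` summary (ranking, cells, relative area in percent,
#'   transpositions), and the reference ranking.
#' @export
sector_map <- function(counts_list, axes = c("ns", "fn"),
                       domain = list(c(0, 10), c(0, 20)),
                       fixed = aogm_weights(), resolution = 201L,
                       reference_point = NULL) {
  validate_weights(fixed)
  axes <- as.character(axes)
  wn <- c("ns", "fn", "fp", "ed", "ea", "ec")
  if (length(axes) != 2L || axes[1L] == axes[2L] || !all(axes %in% wn))
    stop("'axes' must be two distinct weight names")
  if (length(domain) != 2L || !all(lengths(domain) == 2L))
    stop("'domain' must be two c(lo, hi) ranges")
  if (resolution < 2L) stop("'resolution' must be >= 2")
  lo <- vapply(domain, min, 0); hi <- vapply(domain, max, 0)
  if (any(lo < 0)) stop("weights cannot be negative")
  if (is.null(reference_point)) reference_point <- (lo + hi) / 2
  if (any(reference_point < lo) || any(reference_point > hi))
    stop("'reference_point' lies outside the domain")

  cnt <- vapply(counts_list, function(x) {
    c6 <- as_error_counts(x)
    c(ns = c6$NS, fn = c6$FN, fp = c6$FP, ed = c6$ED, ea = c6$EA, ec = c6$EC)
  }, numeric(6L))                      # 6 x n_algorithms
  n_alg <- ncol(cnt)
  w0 <- unclass(fixed)[wn]
  w_base <- w0
  w_base[axes] <- 0
  base <- as.numeric(w_base %*% cnt)   # constant part per algorithm
  c1 <- cnt[axes[1L], ]
  c2 <- cnt[axes[2L], ]

  value_at <- function(w1, w2) base + w1 * c1 + w2 * c2
  ranking_of <- function(v) as.integer(rank(v, ties.method = "min"))
  ref_ranking <- ranking_of(value_at(reference_point[1L],
                                     reference_point[2L]))

  g1 <- seq(lo[1L], hi[1L], length.out = resolution)
  g2 <- seq(lo[2L], hi[2L], length.out = resolution)
  grid <- expand.grid(w1 = g1, w2 = g2)
  vals <- outer(grid$w1, c1) + outer(grid$w2, c2) +
    matrix(base, nrow(grid), n_alg, byrow = TRUE)
  rk <- t(apply(vals, 1L, ranking_of))
  tied <- apply(vals, 1L, anyDuplicated) > 0L
  sector <- ifelse(tied, "tie",
                   apply(rk, 1L, paste, collapse = "-"))
  tp <- ifelse(tied, NA_integer_,
               apply(rk, 1L, transpositions, reference = ref_ranking))
  grid$sector <- sector
  grid$transpositions <- tp
  names(grid)[1:2] <- axes

  agg <- as.data.frame(table(sector), stringsAsFactors = FALSE)
  names(agg) <- c("ranking", "cells")
  agg$area_pct <- 100 * agg$cells / nrow(grid)
  agg$transpositions <- vapply(agg$ranking, function(s) {
    if (s == "tie") return(NA_integer_)
    transpositions(as.integer(strsplit(s, "-")[[1L]]), ref_ranking)
  }, 0L)
  agg <- agg[order(-agg$area_pct), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(grid = grid, sectors = agg, axes = axes,
                 domain = list(lo = lo, hi = hi),
                 reference_point = reference_point,
                 reference_ranking = ref_ranking),
            class = "sector_map")
}

#' @export
print.sector_map <- function(x, ...) {
  cat(sprintf("<sector_map> axes (%s, %s), %d sector(s); reference ranking %s\n",
              x$axes[1L], x$axes[2L], nrow(x$sectors),
              paste(x$reference_ranking, collapse = " ")))
  print(x$sectors)
  invisible(x)
}
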