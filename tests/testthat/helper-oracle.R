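# Independent brute-force oracle for the matching stage: tests every
# same-frame (reference, computed) marker pair directly against the strict
# majority-overlap rule, with plain data-frame row intersection instead of
# the package's occupancy-map machinery.

bf_overlap <- function(a, b) {
  nrow(merge(as.data.frame(a$pixels), as.data.frame(b$pixels)))
}

bf_match <- function(ref_result, comp_result) {
  rg <- tracks_to_graph(ref_result)
  cg <- tracks_to_graph(comp_result)
  assignment <- rep(NA_character_, nrow(rg$vertices))
  names(assignment) <- rg$vertices$key
  for (rk in rg$vertices$key) {
    rm <- rg$markers[[rk]]
    hits <- character()
    for (ck in cg$vertices$key) {
      cm <- cg$markers[[ck]]
      if (cm$frame != rm$frame) next
      if (bf_overlap(rm, cm) > 0.5 * nrow(rm$pixels)) hits <- c(hits, ck)
    }
    stopifnot(length(hits) <= 1L)   # guaranteed by strict majority
    if (length(hits)) assignment[[rk]] <- hits
  }
  assignment
}
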