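# Small builders shared across the suite.  Everything is generated in code;
# no binary fixtures.

# a square marker of half-width 1 centred at `ctr`
sq_marker <- function(label, frame, ctr, radius = 1L) {
  marker(label, frame,
         as.matrix(expand.grid(lapply(ctr, function(c)
           (c - radius):(c + radius)))))
}

dot_marker <- function(label, frame, ctr) {
  marker(label, frame, matrix(as.integer(ctr), nrow = 1L))
}

# one track per column of `spans` (label, t_init, t_end, parent), with square
# markers riding at the given centres
make_result <- function(n_frames, spans, centres, radius = 1L) {
  markers <- list()
  for (i in seq_len(nrow(spans))) {
    for (f in spans$t_init[i]:spans$t_end[i])
      markers <- c(markers, list(sq_marker(spans$label[i], f,
                                           centres[[i]], radius)))
  }
  tracking_result(n_frames, spans, markers)
}

# generator settings used throughout the suite: an 8-frame 64x64 field with
# 5 starting cells and mild event rates keeps instances small but eventful
test_params <- function(seed, ...) {
  defaults <- list(n_frames = 8L, shape = c(64L, 64L), n_initial = 5L,
                   radius = 2L, p_divide = 0.05, p_disappear = 0.03,
                   p_appear = 0.05, max_step = 3L, seed = seed)
  override <- list(...)
  defaults[names(override)] <- override
  do.call(lineage_params, defaults)
}

counts_vec <- function(x) {
  cnt <- if (inherits(x, "aogm_comparison")) x$counts else x
  c(NS = cnt$NS, FN = cnt$FN, FP = cnt$FP, ED = cnt$ED, EA = cnt$EA,
    EC = cnt$EC)
}

empty_result <- function(n_frames) tracking_result(n_frames)
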