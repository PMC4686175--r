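# A small, fully worked reference/computed pair exercising every error type
# at once.  The pair is shipped as JSON fixtures under inst/extdata and is a
# synthetic transcription: the geometry is chosen so that the comparison
# produces a known census of every error type (see below), which doubles as
# the package's end-to-end regression anchor.
#
# Layout (5 frames, reference dots of one pixel on row 10, computed markers
# are 3x3 squares or larger blobs):
#
# reference tracks                       computed tracks
#   1: frames 0-4            col 10        1: frame  1          square @10
#   2: frames 0-1            col 20        2: frames 2-4, parent 1; frame 4 is
#   3: frames 2-4, parent 2  col 18           a blob also covering col 30
#   4: frames 2-4, parent 2  col 22        3: frames 1-4; frames 2-4 are a
#   5: frames 0-4            col 30           16..24 blob over both daughters
#   6: frames 0-2            col 40        4: frames 0-1         square @30
#   7: frames 3-4            col 38        5: frame  2           square @30
#   8: frames 3-4, parent 6  col 42        6: frame  3, parent 5 square @30
#                                          7: frame  2           square @40
#                                          8: frames 3-4, parent 7; frame 4 is
#                                             a 37..43 blob over cols 38+42
#                                          9: frames 0-2 spurious square @60
#
# Census: 25 reference markers (20 detected, 5 missed), 18 computed markers
# (10 uniquely matched, 5 holding two reference markers each, 3 spurious),
# hence NS = 20 - 15 = 5; the computed graph keeps 4 matching links of which
# 2 carry the wrong semantics (divisions faked as track continuations), has
# 1 redundant link (a dead track wrongly joined to a newborn one), and misses
# 16 of the 20 reference links.

#' Worked example: a reference/computed pair with every error type
#'
#' Loads the small fixture pair whose comparison yields NS = 5, FN = 5,
#' FP = 3, ED = 1, EA = 16, EC = 2 with 20 true positive reference markers
#' and 15 computed markers holding at least one reference marker.  With the
#' default weights the measure evaluates to
#' `5*5 + 10*5 + 1*3 + 1*1 + 1.5*16 + 1*2 = 105`.
#'
#' @return List with elements `reference` and `computed`, both
#'   [tracking_result()] objects.
#' @examples
#' ex <- worked_example()
#' compare_tracking(ex$reference, ex$computed)
#' @export
worked_example <- function() {
  list(
    reference = read_fixture_json(system.file(
      "extdata", "worked_example_ref.json", package = "aogm",
      mustWork = TRUE)),
    computed = read_fixture_json(system.file(
      "extdata", "worked_example_comp.json", package = "aogm",
      mustWork = TRUE)))
}

# In-code builder behind the shipped fixtures; kept so tests can assert the
# files and the construction never drift apart.
build_worked_example <- function() {
  dot <- function(label, frame, col) marker(label, frame, cbind(10L, col))
  sq <- function(label, frame, col)
    marker(label, frame, square_pixels(c(10L, col), 1L))
  band <- function(label, frame, col_lo, col_hi)
    marker(label, frame,
           as.matrix(expand.grid(9:11, col_lo:col_hi)))

  ref_tracks <- data.frame(
    label = 1:8,
    t_init = c(0L, 0L, 2L, 2L, 0L, 0L, 3L, 3L),
    t_end = c(4L, 1L, 4L, 4L, 4L, 2L, 4L, 4L),
    parent = c(NA, NA, 2L, 2L, NA, NA, NA, 6L))
  ref_cols <- c(10L, 20L, 18L, 22L, 30L, 40L, 38L, 42L)
  ref_markers <- list()
  for (i in 1:8)
    for (f in ref_tracks$t_init[i]:ref_tracks$t_end[i])
      ref_markers <- c(ref_markers, list(dot(i, f, ref_cols[i])))
  reference <- tracking_result(5L, ref_tracks, ref_markers)

  comp_tracks <- data.frame(
    label = 1:9,
    t_init = c(1L, 2L, 1L, 0L, 2L, 3L, 2L, 3L, 0L),
    t_end = c(1L, 4L, 4L, 1L, 2L, 3L, 2L, 4L, 2L),
    parent = c(NA, 1L, NA, NA, NA, 5L, NA, 7L, NA))
  comp_markers <- list(
    sq(1L, 1L, 10L),
    sq(2L, 2L, 10L), sq(2L, 3L, 10L),
    marker(2L, 4L, rbind(square_pixels(c(10L, 10L), 1L),
                         square_pixels(c(10L, 30L), 1L))),
    sq(3L, 1L, 20L),
    band(3L, 2L, 16L, 24L), band(3L, 3L, 16L, 24L), band(3L, 4L, 16L, 24L),
    sq(4L, 0L, 30L), sq(4L, 1L, 30L),
    sq(5L, 2L, 30L),
    sq(6L, 3L, 30L),
    sq(7L, 2L, 40L),
    sq(8L, 3L, 38L),
    band(8L, 4L, 37L, 43L),
    sq(9L, 0L, 60L), sq(9L, 1L, 60L), sq(9L, 2L, 60L))
  computed <- tracking_result(5L, comp_tracks, comp_markers)

  list(reference = reference, computed = computed)
}
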