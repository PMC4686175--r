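test_that("generator honours event probabilities and its determinism contract", {
  quiet <- lineage_params(n_frames = 8L, n_initial = 4L, p_divide = 0,
                          p_disappear = 0, p_appear = 0, seed = 7L)
  ref <- generate_reference(quiet)
  expect_identical(nrow(ref$tracks), 4L)
  expect_true(all(ref$tracks$t_init == 0L))
  expect_true(all(ref$tracks$t_end == 7L))

  p <- test_params(42L, p_divide = 0.1, p_appear = 0.1)
  a <- generate_reference(p)
  b <- generate_reference(p)
  expect_identical(a$tracks, b$tracks)
  expect_identical(lapply(a$markers, unclass), lapply(b$markers, unclass))

  forced <- lineage_params(n_frames = 2L, shape = c(64L, 64L),
                           n_initial = 1L, p_divide = 1, p_disappear = 0,
                           p_appear = 0, seed = 3L)
  fam <- generate_reference(forced)
  expect_identical(nrow(fam$tracks), 3L)
  g <- tracks_to_graph(fam)
  expect_identical(sum(g$edges$semantics == "P"), 2L)
})

test_that("every generated reference is structurally valid", {
  for (s in 1:150) {
    ref <- generate_reference(test_params(s, n_frames = 6L,
                                          p_divide = 0.08, p_appear = 0.1))
    expect_identical(validate_tracking_result(ref), character(0))
  }
})

test_that("the empty script is the identity corruption", {
  ref <- generate_reference(test_params(1L))
  out <- inject_errors(ref, edit_script(list()))
  expect_identical(unname(counts_vec(out$expected)), rep(0L, 6L))
  cmp <- compare_tracking(ref, out$result)
  expect_identical(unname(counts_vec(cmp)), rep(0L, 6L))
})

test_that("each edit type carries its documented count delta", {
  # deletions inside a track cost one vertex and its two links
  plain <- generate_reference(test_params(11L, p_divide = 0,
                                          p_disappear = 0, p_appear = 0,
                                          n_frames = 5L, n_initial = 3L))
  del <- inject_errors(plain, edit_script(edit_delete_vertex(1L, 2L)))
  expect_identical(counts_vec(del$expected),
                   c(NS = 0L, FN = 1L, FP = 0L, ED = 0L, EA = 2L, EC = 0L))
  expect_identical(counts_vec(compare_tracking(plain, del$result)),
                   counts_vec(del$expected))

  # spurious markers match nothing
  spur <- inject_errors(plain, edit_script(
    edit_add_spurious(0L, c(40L, 40L)), edit_add_spurious(2L, c(40L, 40L)),
    edit_add_spurious(4L, c(44L, 44L))))
  expect_identical(counts_vec(spur$expected),
                   c(NS = 0L, FN = 0L, FP = 3L, ED = 0L, EA = 0L, EC = 0L))
  expect_identical(counts_vec(compare_tracking(plain, spur$result)),
                   counts_vec(spur$expected))

  # merging two parallel tracks costs one split per frame and all their links
  mer <- inject_errors(plain, edit_script(edit_merge(1L, 2L)))
  expect_identical(counts_vec(mer$expected),
                   c(NS = 5L, FN = 0L, FP = 0L, ED = 0L, EA = 8L, EC = 0L))
  expect_identical(counts_vec(compare_tracking(plain, mer$result)),
                   counts_vec(mer$expected))

  # a faked division at a real division site is one semantics error plus the
  # dropped sibling link
  div <- make_result(4L, data.frame(label = 1:3, t_init = c(0L, 2L, 2L),
                                    t_end = c(1L, 3L, 3L),
                                    parent = c(NA, 1L, 1L)),
                     list(c(20L, 20L), c(12L, 12L), c(28L, 28L)))
  flip <- inject_errors(div, edit_script(edit_flip_semantics(1L)))
  expect_identical(counts_vec(flip$expected),
                   c(NS = 0L, FN = 0L, FP = 0L, ED = 0L, EA = 1L, EC = 1L))
  expect_identical(counts_vec(compare_tracking(div, flip$result)),
                   counts_vec(flip$expected))

  # overlapping edit sites are refused
  expect_error(inject_errors(plain, edit_script(edit_delete_vertex(1L, 2L),
                                                edit_cut_edge(1L, 2L))),
               "sites overlap")
})

test_that("injected corruptions always yield valid results with exact recovery", {
  for (s in 1:80) {
    ref <- generate_reference(test_params(s, p_divide = 0.08,
                                          p_appear = 0.08))
    out <- inject_errors(ref, random_edit_script(ref, n_edits = 4L,
                                                 seed = s + 100L))
    expect_identical(validate_tracking_result(out$result), character(0))
    expect_identical(counts_vec(compare_tracking(ref, out$result)),
                     counts_vec(out$expected))
  }
})
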