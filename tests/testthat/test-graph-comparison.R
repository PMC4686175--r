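test_that("detection test requires a strict pixel majority", {
  ref <- marker(1L, 0L, cbind(1L, 1:10))
  over6 <- marker(2L, 0L, cbind(1L, 1:6))
  over5 <- marker(2L, 0L, cbind(1L, 1:5))
  expect_true(detection_test(ref, over6))    # 6 of 10
  expect_false(detection_test(ref, over5))   # exactly half fails
  dot <- marker(1L, 0L, cbind(4L, 4L))
  expect_true(detection_test(dot, sq_marker(9L, 0L, c(4L, 4L))))
  expect_error(detection_test(dot, sq_marker(9L, 1L, c(4L, 4L))),
               "different frames")
})

test_that("one computed blob clustering several reference markers is a split site", {
  # 5 reference dots; one blob swallows 3 of them, two matched one-to-one
  refs <- lapply(1:5, function(i)
    dot_marker(i, 0L, c(5L, 10L * i)))
  ref <- tracking_result(1L, data.frame(label = 1:5, t_init = 0L,
                                        t_end = 0L, parent = NA), refs)
  blob <- marker(1L, 0L, as.matrix(expand.grid(4:6, 8:32)))
  comp <- tracking_result(1L, data.frame(label = 1:3, t_init = 0L,
                                         t_end = 0L, parent = NA),
                          list(blob, sq_marker(2L, 0L, c(5L, 40L)),
                               sq_marker(3L, 0L, c(5L, 50L))))
  cmp <- compare_tracking(ref, comp)
  expect_identical(cmp$classification$TP, 5L)
  expect_identical(cmp$classification$matched_comp, 3L)
  expect_identical(cmp$counts$NS, 2L)
  expect_identical(cmp$counts$m_star, 3L)
  expect_identical(lengths(cmp$matching$fibers)[["1.0"]], 3L)
})

test_that("a track link standing in for a parent link is a semantics error only", {
  # reference: division edge (parent link) between consecutive frames
  ref <- make_result(2L, data.frame(label = 1:2, t_init = c(0L, 1L),
                                    t_end = c(0L, 1L), parent = c(NA, 1L)),
                     list(c(5L, 5L), c(5L, 8L)))
  # computed: same markers joined as one continuing track (track link)
  comp <- tracking_result(2L, data.frame(label = 1L, t_init = 0L,
                                         t_end = 1L, parent = NA),
                          list(sq_marker(1L, 0L, c(5L, 5L)),
                               sq_marker(1L, 1L, c(5L, 8L))))
  cmp <- compare_tracking(ref, comp)
  expect_identical(counts_vec(cmp),
                   c(NS = 0L, FN = 0L, FP = 0L, ED = 0L, EA = 0L, EC = 1L))
})

test_that("edges touching non-split or false-positive vertices never count", {
  # chain a->b->c where b is a non-split blob: both incident edges excluded,
  # so the two reference links are missing, not redundant or mismatched
  ref <- make_result(3L, data.frame(label = 1:2, t_init = c(0L, 0L),
                                    t_end = c(2L, 2L), parent = NA),
                     list(c(5L, 5L), c(5L, 15L)))
  blob <- marker(1L, 1L, as.matrix(expand.grid(4:6, 4:16)))
  comp <- tracking_result(
    3L, data.frame(label = 1:2, t_init = c(0L, 0L), t_end = c(2L, 2L),
                   parent = NA),
    list(sq_marker(1L, 0L, c(5L, 5L)), blob, sq_marker(1L, 2L, c(5L, 5L)),
         sq_marker(2L, 0L, c(5L, 15L)), sq_marker(2L, 1L, c(5L, 25L)),
         sq_marker(2L, 2L, c(5L, 15L))))
  cmp <- compare_tracking(ref, comp)
  cls <- cmp$classification
  expect_identical(cls$comp_non_split, "1.1")
  expect_identical(nrow(cmp$induced_edges), 0L)
  expect_identical(cmp$counts$ED, 0L)
  expect_identical(cmp$counts$EA, 4L)   # every reference link unmatched
})

test_that("identity and degenerate comparisons behave as contracts state", {
  ex <- worked_example()
  self <- compare_tracking(ex$reference, ex$reference)
  expect_identical(unname(counts_vec(self)), rep(0L, 6L))

  gr <- tracks_to_graph(ex$reference)
  vs <- nrow(gr$vertices); es <- nrow(gr$edges)
  none <- compare_tracking(ex$reference, empty_result(5L))
  expect_identical(counts_vec(none),
                   c(NS = 0L, FN = vs, FP = 0L, ED = 0L, EA = es, EC = 0L))
  flip <- compare_tracking(empty_result(5L), ex$reference)
  expect_identical(counts_vec(flip),
                   c(NS = 0L, FN = 0L, FP = vs, ED = 0L, EA = 0L, EC = 0L))
})

test_that("vertex partitions and counting identities hold on random pairs", {
  for (s in 1:300) {
    ref <- generate_reference(test_params(s, n_frames = 6L, n_initial = 4L,
                                          shape = c(56L, 56L)))
    out <- inject_errors(ref, random_edit_script(ref, n_edits = 3L,
                                                 seed = s + 5000L))
    rg <- tracks_to_graph(ref)
    cg <- tracks_to_graph(out$result)
    m <- match_vertices(rg, cg)
    cls <- classify_vertices(m, rg, cg)
    expect_identical(cls$TP + cls$FN, nrow(rg$vertices))
    expect_identical(length(cls$comp_true_positive) + cls$FP + cls$VS,
                     nrow(cg$vertices))
    expect_setequal(c(cls$ref_true_positive, cls$ref_false_negative),
                    rg$vertices$key)
    expect_true(cls$NS >= cls$VS)
    expect_identical(sum(lengths(m$fibers) - 1L), cls$NS)
  }
})

test_that("matching agrees with the brute-force all-pairs oracle", {
  for (s in 1:60) {
    ref <- generate_reference(test_params(s, n_frames = 2L, n_initial = 4L,
                                          shape = c(48L, 48L),
                                          p_divide = 0.15))
    out <- inject_errors(ref, random_edit_script(ref, n_edits = 2L,
                                                 seed = s + 7000L))
    got <- match_vertices(tracks_to_graph(ref),
                          tracks_to_graph(out$result))$assignment
    expect_identical(got, bf_match(ref, out$result))
  }
})
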