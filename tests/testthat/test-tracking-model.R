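test_that("validation reports temporal gaps, overlaps and lineage defects", {
  spans <- data.frame(label = 1:2, t_init = c(0L, 0L), t_end = c(2L, 2L),
                      parent = NA_integer_)
  good <- make_result(3L, spans, list(c(5L, 5L), c(5L, 15L)))
  expect_identical(validate_tracking_result(good), character(0))

  # drop the frame-1 marker of track 1
  gap <- good
  gap$markers[[marker_key <- "1.1"]] <- NULL
  gap <- tracking_result(3L, gap$tracks, unname(gap$markers))
  expect_match(validate_tracking_result(gap), "temporal gap", all = FALSE)

  # two markers sharing a pixel in one frame
  clash <- tracking_result(1L, data.frame(label = 1:2, t_init = 0L,
                                          t_end = 0L, parent = NA),
                           list(sq_marker(1L, 0L, c(5L, 5L)),
                                sq_marker(2L, 0L, c(5L, 6L))))
  expect_match(validate_tracking_result(clash), "overlap", all = FALSE)

  # dangling parent and parent not terminating before the child
  dangle <- make_result(3L, data.frame(label = 1L, t_init = 0L, t_end = 2L,
                                       parent = 7L), list(c(5L, 5L)))
  expect_match(validate_tracking_result(dangle), "parent 7 does not exist",
               all = FALSE)
  late <- make_result(3L, data.frame(label = 1:2, t_init = c(0L, 1L),
                                     t_end = c(2L, 2L), parent = c(NA, 1L)),
                      list(c(5L, 5L), c(5L, 15L)))
  expect_match(validate_tracking_result(late), "not before child start",
               all = FALSE)
})

test_that("graph construction yields track and parent links per definition", {
  # division: theta1 on 0-1; theta2, theta3 on 2-3 with parent 1
  spans <- data.frame(label = 1:3, t_init = c(0L, 2L, 2L),
                      t_end = c(1L, 3L, 3L), parent = c(NA, 1L, 1L))
  res <- make_result(4L, spans, list(c(10L, 10L), c(5L, 5L), c(15L, 15L)))
  g <- tracks_to_graph(res)
  expect_identical(nrow(g$vertices), 6L)
  expect_identical(sum(g$edges$semantics == "T"), 3L)
  expect_identical(sum(g$edges$semantics == "P"), 2L)
  expect_setequal(g$edges$to[g$edges$semantics == "P"], c("2.2", "3.2"))

  # single one-frame track: a vertex, no edges
  single <- make_result(1L, data.frame(label = 1L, t_init = 0L, t_end = 0L,
                                       parent = NA), list(c(3L, 3L)))
  gs <- tracks_to_graph(single)
  expect_identical(nrow(gs$vertices), 1L)
  expect_identical(nrow(gs$edges), 0L)

  # reappearance after a gap: parent link bridges non-consecutive frames
  gapres <- make_result(7L, data.frame(label = 1:2, t_init = c(0L, 5L),
                                       t_end = c(2L, 6L), parent = c(NA, 1L)),
                        list(c(10L, 10L), c(10L, 12L)))
  gg <- tracks_to_graph(gapres)
  pe <- gg$edges[gg$edges$semantics == "P", ]
  expect_identical(pe$from, "1.2")
  expect_identical(pe$to, "2.5")

  expect_error(tracks_to_graph(make_result(
    3L, data.frame(label = 1L, t_init = 0L, t_end = 2L, parent = 7L),
    list(c(5L, 5L)))), "invalid tracking result")
})

test_that("frame restriction induces the frame-prefix subgraph", {
  spans <- data.frame(label = 1:3, t_init = c(0L, 2L, 2L),
                      t_end = c(1L, 3L, 3L), parent = c(NA, 1L, 1L))
  g <- tracks_to_graph(make_result(4L, spans,
                                   list(c(10L, 10L), c(5L, 5L),
                                        c(15L, 15L))))
  expect_identical(restrict_to_frames(g, 3L)$edges, g$edges)
  g1 <- restrict_to_frames(g, 1L)
  expect_identical(nrow(g1$vertices), 2L)
  expect_identical(g1$edges$semantics, "T")
  g0 <- restrict_to_frames(g, 0L)
  expect_identical(nrow(g0$vertices), 1L)
  expect_identical(nrow(g0$edges), 0L)
  expect_error(restrict_to_frames(g, 4L), "frame index")
})

test_that("graphs of random lineages are acyclic with the exact edge census", {
  skip_if_not_installed("igraph")
  for (s in 1:400) {
    ref <- generate_reference(test_params(s, n_frames = 6L, n_initial = 4L,
                                          shape = c(56L, 56L)))
    g <- tracks_to_graph(ref)
    frame_of <- stats::setNames(g$vertices$frame, g$vertices$key)
    expect_true(all(frame_of[g$edges$from] < frame_of[g$edges$to]))
    with_parent <- sum(!is.na(ref$tracks$parent))
    expect_identical(nrow(g$edges),
                     sum(ref$tracks$t_end - ref$tracks$t_init) + with_parent)
    if (s %% 40 == 0 && nrow(g$edges)) {
      ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")])
      expect_true(igraph::is_dag(ig))
    }
    # determinism of the transformation
    if (s %% 100 == 0)
      expect_identical(tracks_to_graph(ref)$edges, g$edges)
  }
})
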