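test_that("minimal mask directory round-trips a one-track result", {
  d <- withr::local_tempdir()
  res <- make_result(2L, data.frame(label = 1L, t_init = 0L, t_end = 1L,
                                    parent = NA), list(c(5L, 5L)))
  write_tracking_directory(res, d, shape = c(16L, 16L))
  back <- read_tracking_directory(d)
  expect_identical(back$tracks, res$tracks)
  expect_identical(lapply(back$markers, unclass), lapply(res$markers, unclass))
})

test_that("directory writing is lossless and byte-stable, 2-D and 3-D", {
  ref <- generate_reference(test_params(5L, p_divide = 0.1, p_appear = 0.1))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_tracking_directory(ref, d1, shape = c(64L, 64L))
  write_tracking_directory(ref, d2, shape = c(64L, 64L))
  back <- read_tracking_directory(d1)
  expect_identical(back$tracks, ref$tracks)
  expect_identical(lapply(back$markers, unclass), lapply(ref$markers, unclass))
  f1 <- list.files(d1, full.names = TRUE); f2 <- list.files(d2,
                                                            full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  ref3 <- generate_reference(lineage_params(n_frames = 3L,
                                            shape = c(24L, 24L, 9L),
                                            n_initial = 2L, radius = 1L,
                                            p_divide = 0, p_disappear = 0,
                                            p_appear = 0, seed = 2L))
  d3 <- withr::local_tempdir()
  write_tracking_directory(ref3, d3, shape = c(24L, 24L, 9L))
  back3 <- read_tracking_directory(d3)
  expect_identical(lapply(back3$markers, unclass),
                   lapply(ref3$markers, unclass))

  empty <- empty_result(2L)
  d4 <- withr::local_tempdir()
  write_tracking_directory(empty, d4, shape = c(8L, 8L))
  expect_identical(nrow(read_tracking_directory(d4)$tracks), 0L)
})

test_that("mask/track cross-consistency is enforced on read", {
  d <- withr::local_tempdir()
  res <- make_result(3L, data.frame(label = 1L, t_init = 0L, t_end = 2L,
                                    parent = NA), list(c(5L, 5L)))
  write_tracking_directory(res, d, shape = c(16L, 16L))
  # claim a span the masks do not support
  writeLines("2 1 3 1", file.path(d, "res_track.txt"))
  expect_error(read_tracking_directory(d), "inconsistent|missing mask")
  # dangling parent
  writeLines(c("1 0 2 0", "2 1 2 7"), file.path(d, "res_track.txt"))
  expect_error(read_tracking_directory(d), "inconsistent")
  # missing track file
  file.remove(file.path(d, "res_track.txt"))
  expect_error(read_tracking_directory(d), "track file not found")
})

test_that("JSON fixture dialect round-trips losslessly and byte-stably", {
  ref <- generate_reference(test_params(9L, p_divide = 0.1))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_fixture_json(ref, f1)
  write_fixture_json(ref, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_fixture_json(f1)
  expect_identical(back$tracks, ref$tracks)
  expect_identical(lapply(back$markers, unclass), lapply(ref$markers, unclass))

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"n_frames": 1, "tracks": []}', bad)
  expect_error(read_fixture_json(bad), "schema error")
  writeLines("{not json", bad)
  expect_error(read_fixture_json(bad), "malformed JSON")
  writeLines(paste0('{"n_frames":1,"tracks":[{"label":1,"t_init":0,',
                    '"t_end":0,"parent":0}],"markers":[{"label":1,',
                    '"frame":0,"pixels":[]}]}'), bad)
  expect_error(read_fixture_json(bad), "pixels")
})

test_that("shipped worked-example fixtures match their in-code construction", {
  ex <- worked_example()
  built <- aogm:::build_worked_example()
  expect_identical(ex$reference$tracks, built$reference$tracks)
  expect_identical(ex$computed$tracks, built$computed$tracks)
  expect_identical(lapply(ex$reference$markers, unclass),
                   lapply(built$reference$markers, unclass))
  expect_identical(lapply(ex$computed$markers, unclass),
                   lapply(built$computed$markers, unclass))
})
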