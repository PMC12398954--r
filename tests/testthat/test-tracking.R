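test_that("a static noiseless scene tracks to exactly zero displacement", {
  sc <- scene_spec("flat", 560, marker_spec(side_mm = 25), fps = 10,
                   duration_s = 1)
  seq <- render_sequence(sc, test_intrinsics(), noise = NULL, seed = 1)
  tr <- track_sequence(seq, tracker_config(roi = c(70, 30, 100, 100),
                                           decimation = 1))
  expect_true(all(tr$status == "TRACKED"))
  expect_lt(max(abs(tr$y_vert_mm)), 1e-6)
  expect_lt(max(abs(tr$z_long_mm)), 1e-6)
  expect_lt(max(abs(tr$x_lat_mm)), 1e-6)
})

test_that("noiseless vertical sinusoid is recovered to sub-0.1 mm", {
  intr <- test_intrinsics()
  seq <- render_sequence(vertical_scene(amplitude_mm = 20, duration_s = 9),
                         intr, noise = NULL, seed = 1)
  tr <- track_sequence(seq, tracker_config(roi = c(70, 15, 100, 130),
                                           decimation = 1))
  ok <- tr$status == "TRACKED"
  expect_true(all(ok))
  gt <- seq$ground_truth
  expect_lt(mae(tr$y_vert_mm, gt$y_vert_mm), 0.1)
  expect_gt(pearson_r(tr$y_vert_mm, gt$y_vert_mm), 0.999)
  # axis separability: pure vertical motion leaks nothing into depth and
  # almost nothing into the lateral axis
  expect_equal(sd(tr$z_long_mm), 0)
  expect_lt(sd(tr$x_lat_mm), 0.05)
})

test_that("decimation selects a subsequence of the full trace times", {
  sc <- vertical_scene(duration_s = 3, fps = 15)
  seq <- render_sequence(sc, test_intrinsics(), noise = NULL, seed = 2)
  t1 <- track_sequence(seq, tracker_config(roi = c(70, 15, 100, 130),
                                           decimation = 1))
  t3 <- track_sequence(seq, tracker_config(roi = c(70, 15, 100, 130),
                                           decimation = 3))
  expect_equal(t3$t_s, t1$t_s[seq(1, nrow(t1), by = 3)])
  expect_equal(nrow(t3), ceiling(nrow(t1) / 3))
})

test_that("tracking suspends when the marker leaves the ROI", {
  # tight ROI: the downward half-cycle carries the marker out at the bottom
  intr <- test_intrinsics()
  seq <- render_sequence(vertical_scene(amplitude_mm = 20, duration_s = 6,
                                        fps = 15),
                         intr, noise = NULL, seed = 1)
  roi <- c(70, 40, 100, 55)
  tr <- track_sequence(seq, tracker_config(roi = roi, decimation = 1))
  sus <- which(tr$status == "SUSPENDED")
  expect_gt(length(sus), 0)
  k <- sus[1]
  expect_gt(k, 5)
  expect_true(all(tr$status[k:nrow(tr)] == "SUSPENDED"))
  expect_true(all(is.na(tr$y_vert_mm[sus])))
})

test_that("reset_roi resumes tracking with the baseline preserved", {
  intr <- test_intrinsics()
  seq <- render_sequence(vertical_scene(amplitude_mm = 20, duration_s = 8,
                                        fps = 15),
                         intr, noise = NULL, seed = 1)
  roi <- c(70, 40, 100, 55)
  state <- tracker_init(tracker_config(roi = roi, decimation = 1), intr)
  gt <- seq$ground_truth
  did_reset <- FALSE
  for (i in seq_along(seq$frames)) {
    if (!did_reset && state$suspended && gt$y_vert_mm[i] > 5) {
      state <- reset_roi(state, c(70, 15, 100, 130))
      did_reset <- TRUE
    }
    state <- tracker_step(state, seq$frames[[i]])
  }
  expect_true(did_reset)
  tr <- tracker_finalize(state)
  post <- which(tr$status == "TRACKED")
  post <- post[post > which(tr$status == "SUSPENDED")[1]]
  expect_gt(length(post), 5)
  # displacements remain referenced to the pre-suspension baseline
  expect_lt(mae(tr$y_vert_mm[post], gt$y_vert_mm[post]), 0.1)
})

test_that("reset_roi guards its preconditions", {
  intr <- test_intrinsics()
  sc <- scene_spec("flat", 560, marker_spec(side_mm = 25), fps = 10,
                   duration_s = 1)
  seq <- render_sequence(sc, intr, noise = NULL, seed = 1)
  cfg <- tracker_config(roi = c(70, 30, 100, 100), decimation = 1)
  state <- tracker_init(cfg, intr)
  state <- tracker_step(state, seq$frames[[1]])
  expect_warning(reset_roi(state, c(0, 0, 50, 50)), "active")
  # a reset into a markerless ROI suspends again at the next frame
  state$suspended <- TRUE
  state <- reset_roi(state, c(0, 0, 60, 60))
  state <- tracker_step(state, seq$frames[[2]])
  expect_true(state$suspended)
  expect_error(reset_roi(state, c(-5, 0, 50, 50)), "valid")
})

test_that("a markerless ROI yields an all-suspended trace with a warning", {
  sc <- scene_spec("flat", 560, marker_spec(side_mm = 25), fps = 10,
                   duration_s = 1)
  seq <- render_sequence(sc, test_intrinsics(), noise = NULL, seed = 1)
  expect_warning(
    tr <- track_sequence(seq, tracker_config(roi = c(0, 0, 60, 50),
                                             decimation = 1)),
    "no frame was tracked")
  expect_true(all(tr$status == "SUSPENDED"))
})

test_that("late-only detections trigger an initialization error", {
  sc <- scene_spec("flat", 560, marker_spec(side_mm = 25), fps = 10,
                   duration_s = 1.5)
  seq <- render_sequence(sc, test_intrinsics(), noise = NULL, seed = 1)
  state <- tracker_init(tracker_config(roi = c(0, 0, 60, 50), decimation = 1),
                        test_intrinsics())
  for (i in 1:8) state <- tracker_step(state, seq$frames[[i]])
  state <- reset_roi(state, c(70, 30, 100, 100))
  for (i in 9:15) state <- tracker_step(state, seq$frames[[i]])
  expect_error(tracker_finalize(state), "initialization")
})
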