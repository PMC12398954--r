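test_that("static noiseless scene renders identical frames with zero truth", {
  sc <- scene_spec("flat", 560, marker_spec(side_mm = 25), fps = 6,
                   duration_s = 1)
  seq <- render_sequence(sc, test_intrinsics(), noise = NULL, seed = 3)
  expect_length(seq$frames, 6)
  for (f in seq$frames[-1]) {
    expect_identical(f$color, seq$frames[[1]]$color)
    expect_identical(f$depth, seq$frames[[1]]$depth)
  }
  expect_true(all(seq$ground_truth$y_vert_mm == 0))
  expect_true(all(seq$ground_truth$z_long_mm == 0))
  expect_true(all(seq$frames[[1]]$depth == 560))
})

test_that("rendering is deterministic and seeds only change the noise", {
  sc <- vertical_scene(duration_s = 0.5, fps = 10)
  a <- render_sequence(sc, test_intrinsics(), seed = 5)
  b <- render_sequence(sc, test_intrinsics(), seed = 5)
  c <- render_sequence(sc, test_intrinsics(), seed = 6)
  expect_identical(a$frames[[3]]$depth, b$frames[[3]]$depth)
  expect_identical(a$frames[[3]]$color, b$frames[[3]]$color)
  expect_false(identical(a$frames[[3]]$depth, c$frames[[3]]$depth))
  expect_identical(a$ground_truth, c$ground_truth)
})

test_that("rendered marker centroid matches the analytic pose", {
  # oracle: project the analytically displaced marker and compare with the
  # detector centroid, converted back to mm
  intr <- test_intrinsics()
  sc <- vertical_scene(amplitude_mm = 20, duration_s = 3, fps = 10)
  seq <- render_sequence(sc, intr, noise = NULL, seed = 1)
  mk <- sc$marker$vertices_mm
  err <- vapply(seq(1, 30, by = 2), function(i) {
    gt <- seq$ground_truth[i, ]
    verts <- cbind(mk[, 1] + gt$x_lat_mm, mk[, 2] + gt$y_vert_mm,
                   560 + gt$z_long_mm)
    truth <- colMeans(project_point(verts, intr))
    det <- detect_marker(seq$frames[[i]]$color)
    expect_length(det, 1)
    vpx <- det[[1]]$centroid_px[2] - truth[2]
    abs(pixel_disp_to_mm(vpx, 560, intr$fy))
  }, numeric(1))
  expect_lt(mean(err), 0.05)
})

test_that("depth noise converges to the anchored bias and sigma", {
  sc <- scene_spec("flat", 560, marker_spec(side_mm = 25), fps = 2,
                   duration_s = 1)
  seq <- render_sequence(sc, test_intrinsics(), noise = depth_noise_model(),
                         seed = 11)
  resid <- unlist(lapply(seq$frames, function(f) f$depth - 560))
  n <- length(resid)
  expect_lt(abs(mean(resid) - 0.03), 3 * 0.13 / sqrt(n))
  expect_lt(abs(sd(resid) - 0.13), 0.01)
})

test_that("torso surface carries the marker rigidly under coupled motion", {
  fps <- 10
  vert <- waveform_sinusoid(8, 0.25, duration_s = 3, sample_rate_hz = fps)
  long <- waveform_sinusoid(4, 0.25, duration_s = 3, sample_rate_hz = fps)
  sc <- scene_spec("torso", 560, marker_spec(side_mm = 25),
                   motion = list(vertical = vert, longitudinal = long),
                   fps = fps, duration_s = 3,
                   torso = list(half_width_mm = 120, bulge_mm = 50))
  intr <- test_intrinsics()
  seq <- render_sequence(sc, intr, noise = NULL, seed = 2)
  mk <- sc$marker$vertices_mm
  rest <- cbind(mk[, 1], mk[, 2],
                560 + 50 * (mk[, 1] / 120)^2)
  d_rest <- dist(rest)
  for (i in c(1, 10, 20, 30)) {
    gt <- seq$ground_truth[i, ]
    verts <- sweep(rest, 2,
                   c(gt$x_lat_mm, gt$y_vert_mm, gt$z_long_mm), "+")
    expect_equal(as.numeric(dist(verts)), as.numeric(d_rest))
    # marker still detectable on the curved surface
    det <- detect_marker(seq$frames[[i]]$color)
    expect_length(det, 1)
    # depth under the centroid follows the surface plus the programmed
    # longitudinal displacement
    cen <- det[[1]]$centroid_px
    z <- seq$frames[[i]]$depth[round(cen[2]) + 1, round(cen[1]) + 1]
    zc <- mean(rest[, 3]) + gt$z_long_mm
    expect_lt(abs(z - zc), 1.5)
  }
})

test_that("a marker outside the field of view is rejected at rest", {
  sc <- scene_spec("flat", 560, marker_spec(center_mm = c(400, 0)))
  expect_error(render_sequence(sc, test_intrinsics(), NULL, 1),
               "field of view")
})
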