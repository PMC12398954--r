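test_that("a clean triangle is detected with the right centroid", {
  img <- triangle_image(rbind(c(100, 100), c(160, 100), c(100, 160)))
  det <- detect_marker(img)
  expect_length(det, 1)
  expect_lt(max(abs(det[[1]]$centroid_px - c(120, 120))), 0.5)
  expect_true(det[[1]]$score > 0 && det[[1]]$score <= 1)
  expect_equal(nrow(det[[1]]$vertices), 3)
})

test_that("blank images and squares yield no detection", {
  blank <- array(120, c(120, 120, 3))
  expect_length(detect_marker(blank), 0)
  expect_length(detect_marker(square_image()), 0)
})

test_that("ROI restricts and offsets the detection", {
  img <- triangle_image(rbind(c(100, 100), c(160, 100), c(100, 160)))
  det <- detect_marker(img, roi = c(80, 80, 100, 100))
  expect_length(det, 1)
  expect_lt(max(abs(det[[1]]$centroid_px - c(120, 120))), 0.5)
  # ROI away from the marker finds nothing
  expect_length(detect_marker(img, roi = c(0, 0, 60, 60)), 0)
  expect_error(detect_marker(img, roi = c(0, 0, 0, 10)), "degenerate")
  expect_error(detect_marker(img, roi = c(200, 200, 100, 100)), "bounds")
})

test_that("detector centroid is translation-equivariant", {
  base <- rbind(c(60, 70), c(120, 65), c(80, 130))
  d0 <- detect_marker(triangle_image(base))[[1]]$centroid_px
  for (shift in list(c(25, 0), c(0, 30), c(40, 35))) {
    uv <- sweep(base, 2, shift, "+")
    d1 <- detect_marker(triangle_image(uv))[[1]]$centroid_px
    expect_lt(max(abs(d1 - d0 - shift)), 0.5)
  }
})

test_that("mask centroid is the first moment and equivariant", {
  m <- matrix(FALSE, 10, 10)
  # right triangle with pixel vertices (0,0), (6,0), (0,6)
  for (v in 0:6) for (u in 0:(6 - v)) m[v + 1, u + 1] <- TRUE
  cen <- mask_centroid(m)
  expect_lt(max(abs(cen - c(2, 2))), 0.5)
  single <- matrix(FALSE, 30, 30); single[21, 11] <- TRUE
  expect_equal(mask_centroid(single), c(10, 20))
  shifted <- matrix(FALSE, 20, 20)
  shifted[(1:7) + 4, (1:7) + 3] <- m[1:7, 1:7]
  expect_equal(mask_centroid(shifted), mask_centroid(m[1:7, 1:7]) + c(3, 4))
  expect_error(mask_centroid(matrix(FALSE, 5, 5)), "empty")
})

test_that("mean average precision follows precision-recall counting", {
  mk <- function(rows, cols) {
    m <- matrix(FALSE, 20, 20); m[rows, cols] <- TRUE; m
  }
  g1 <- mk(1:5, 1:5); g2 <- mk(10:14, 10:14)
  hit1 <- list(score = 0.9, mask = g1)
  # all ground truths matched, no false positives
  expect_equal(mean_average_precision(
    list(list(hit1, list(score = 0.8, mask = g2))), list(list(g1, g2))), 1)
  # no predictions at all
  expect_equal(mean_average_precision(list(list()), list(list(g1))), 0)
  # 2 ground truths, 1 correct prediction: recall saturates at 0.5
  expect_equal(mean_average_precision(
    list(list(hit1)), list(list(g1, g2))), 0.5)
  # degenerate conventions
  expect_equal(mean_average_precision(list(list()), list(list())), 1)
  expect_equal(mean_average_precision(
    list(list(hit1)), list(list())), 0)
  # a false positive scoring below all true positives leaves AP at 1
  fp <- list(score = 0.1, mask = mk(16:18, 1:3))
  expect_equal(mean_average_precision(
    list(list(hit1, fp)), list(list(g1))), 1)
  # a false positive outscoring the true positive lowers AP
  fp_hi <- list(score = 0.95, mask = mk(16:18, 1:3))
  expect_lt(mean_average_precision(
    list(list(hit1, fp_hi)), list(list(g1))), 1)
  expect_error(mean_average_precision(list(), list(), iou_threshold = 1.2),
               "iou_threshold")
})

test_that("mAP is non-increasing in the IoU threshold", {
  ds <- render_detection_dataset(15, seed = 4)
  preds <- lapply(ds, function(e) detect_marker(e$image))
  gts <- lapply(ds, function(e) e$mask)
  maps <- vapply(c(0.5, 0.75, 0.9, 0.95),
                 function(th) mean_average_precision(preds, gts, th),
                 numeric(1))
  expect_true(all(diff(maps) <= 1e-12))
})
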