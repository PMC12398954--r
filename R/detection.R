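#' Tuning parameters for the classical triangle-marker detector
#'
#' The reference detector segments candidate regions by color contrast
#' against the local background, extracts contours, simplifies them to
#' polygons (Douglas-Peucker at a fraction of the contour perimeter) and
#' keeps candidates that are 3-gons, solid, and well fitted by their vertex
#' triangle.
#'
#' @param min_area_px Minimum candidate area in pixels (suppresses noise
#'   speckles).
#' @param solidity_min Minimum area / convex-hull-area ratio.
#' @param approx_frac Polygon-approximation tolerance as a fraction of the
#'   contour perimeter.
#' @param fit_tol Maximum relative mismatch between the candidate pixel
#'   area and the area of its fitted vertex triangle.
#' @param min_contrast Minimum peak color distance (0..255 RGB units) from
#'   the background for any detection to be attempted.
#' @export
detector_params <- function(min_area_px = 50, solidity_min = 0.9,
                            approx_frac = 0.02, fit_tol = 0.25,
                            min_contrast = 30) {
  structure(list(min_area_px = min_area_px, solidity_min = solidity_min,
                 approx_frac = approx_frac, fit_tol = fit_tol,
                 min_contrast = min_contrast),
            class = "detector_params")
}

# Iterative Douglas-Peucker on an open polyline (n x 2 matrix).
dp_open <- function(pts, eps) {
  n <- nrow(pts)
  keep <- logical(n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack) > 0) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a
    len <- sqrt(sum(ab^2))
    idx <- (i + 1):(j - 1)
    d <- if (len < 1e-12) {
      sqrt((pts[idx, 1] - a[1])^2 + (pts[idx, 2] - a[2])^2)
    } else {
      abs(ab[1] * (pts[idx, 2] - a[2]) - ab[2] * (pts[idx, 1] - a[1])) / len
    }
    k <- which.max(d)
    if (d[k] > eps) {
      m <- idx[k]
      keep[m] <- TRUE
      stack[[length(stack) + 1]] <- c(i, m)
      stack[[length(stack) + 1]] <- c(m, j)
    }
  }
  pts[keep, , drop = FALSE]
}

# Douglas-Peucker simplification of a closed contour. The contour is split
# at its two mutually farthest points so both half-chains are simplified
# with stable anchors.
dp_closed <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 3) return(pts)
  d1 <- (pts[, 1] - pts[1, 1])^2 + (pts[, 2] - pts[1, 2])^2
  i0 <- which.max(d1)
  d2 <- (pts[, 1] - pts[i0, 1])^2 + (pts[, 2] - pts[i0, 2])^2
  i1 <- which.max(d2)
  lo <- min(i0, i1); hi <- max(i0, i1)
  chain_a <- pts[lo:hi, , drop = FALSE]
  chain_b <- pts[c(hi:n, 1:lo), , drop = FALSE]
  sa <- dp_open(chain_a, eps)
  sb <- dp_open(chain_b, eps)
  rbind(sa, sb[-c(1, nrow(sb)), , drop = FALSE])
}

# Color distance of every pixel to a robust planar background model.
# Each channel is modelled as a + b*u + c*v so uniform backgrounds and
# smooth illumination gradients are both absorbed; the marker stands out
# as the residual. One reweighting pass downweights the marker pixels so
# they do not skew the background fit.
background_residual_dist <- function(crop) {
  H <- dim(crop)[1]; W <- dim(crop)[2]
  u <- rep(seq_len(W) - 1, each = H)
  v <- rep(seq_len(H) - 1, times = W)
  X <- cbind(1, u, v)
  Y <- matrix(crop, nrow = H * W, ncol = 3)
  res <- Y - X %*% stats::lm.fit(X, Y)$coefficients
  rn <- sqrt(rowSums(res^2))
  keep <- rn <= 2.5 * stats::median(rn) + 1e-6
  if (sum(keep) >= 12 && any(!keep)) {
    fit <- stats::lm.fit(X[keep, , drop = FALSE], Y[keep, , drop = FALSE])
    res <- Y - X %*% fit$coefficients
    rn <- sqrt(rowSums(res^2))
  }
  matrix(rn, nrow = H, ncol = W)
}

shoelace_area <- function(pts) {
  n <- nrow(pts)
  j <- c(2:n, 1)
  abs(sum(pts[, 1] * pts[j, 2] - pts[j, 1] * pts[, 2])) / 2
}

# Collapse near-collinear / corner-cut vertices: repeatedly drop the vertex
# closest to the chord of its neighbours while that distance stays within
# `tol`. Rasterized triangle corners are often cut by 1-3 px, producing a
# spurious 4th vertex; genuine polygon corners (e.g. of a square) deviate by
# about half a side length and survive.
decimate_polygon <- function(poly, tol) {
  while (nrow(poly) > 3) {
    n <- nrow(poly)
    d <- vapply(seq_len(n), function(i) {
      a <- poly[if (i == 1) n else i - 1, ]
      b <- poly[if (i == n) 1 else i + 1, ]
      ab <- b - a
      len <- sqrt(sum(ab^2))
      if (len < 1e-12) return(0)
      abs(ab[1] * (poly[i, 2] - a[2]) - ab[2] * (poly[i, 1] - a[1])) / len
    }, numeric(1))
    i <- which.min(d)
    if (d[i] > tol) break
    poly <- poly[-i, , drop = FALSE]
  }
  poly
}

# Number of integer pixel centres inside (or on) a convex polygon given by
# hull vertices (col, row); crange/rrange bound the candidate grid.
count_pixels_in_convex_poly <- function(hp, crange, rrange) {
  cs <- crange[1]:crange[2]
  rs <- rrange[1]:rrange[2]
  u <- rep(cs, each = length(rs))
  v <- rep(rs, times = length(cs))
  n <- nrow(hp)
  if (n < 3) return(length(u))
  j <- c(2:n, 1)
  area2 <- sum(hp[, 1] * hp[j, 2] - hp[j, 1] * hp[, 2])
  s <- if (area2 >= 0) 1 else -1
  inside <- rep(TRUE, length(u))
  for (k in seq_len(n)) {
    e <- hp[j[k], ] - hp[k, ]
    cr <- e[1] * (v - hp[k, 2]) - e[2] * (u - hp[k, 1])
    inside <- inside & (s * cr >= -1e-9)
  }
  sum(inside)
}

contour_perimeter <- function(pts) {
  j <- c(2:nrow(pts), 1)
  sum(sqrt(rowSums((pts[j, , drop = FALSE] - pts)^2)))
}

#' Detect the triangular marker in a color frame
#'
#' Reference implementation of the marker-detection contract: candidate
#' regions are segmented inside the ROI by thresholding the color distance
#' to the background (Otsu), contours are extracted and simplified to
#' polygons; a candidate survives if it has exactly 3 vertices, area at
#' least `min_area_px`, solidity at least `solidity_min` and a triangle-fit
#' residual below `fit_tol`. The centroid is computed with sub-pixel
#' precision from contrast-weighted first moments. A learned
#' instance-segmentation backend can replace this function without
#' changing downstream code, as long as it honours the same contract.
#'
#' @param image H x W x 3 color array in 0..255.
#' @param roi Pixel rectangle `c(u0, v0, w, h)` (zero-based corner, size);
#'   `NULL` means the whole image.
#' @param params A [detector_params()].
#' @param frame_index Optional frame index stored in each detection.
#' @return List of `marker_detection` objects sorted by decreasing score
#'   (ties broken by larger area). Each has fields `mask` (ROI-local
#'   logical matrix), `vertices` (3 x 2 global pixel coords), `centroid_px`
#'   (global, sub-pixel), `score` in 0..1, `area`, `offset_px`, and
#'   `frame_index`. Empty list if nothing qualifies.
#' @export
detect_marker <- function(image, roi = NULL, params = detector_params(),
                          frame_index = NA_integer_) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (is.null(roi)) roi <- c(0, 0, W, H)
  if (roi[3] <= 0 || roi[4] <= 0) stop("degenerate ROI (zero area)")
  if (roi[1] < 0 || roi[2] < 0 || roi[1] + roi[3] > W || roi[2] + roi[4] > H) {
    stop("ROI must lie within the image bounds")
  }
  rows <- (roi[2] + 1):(roi[2] + roi[4])
  cols <- (roi[1] + 1):(roi[1] + roi[3])
  crop <- image[rows, cols, , drop = FALSE]
  dist <- background_residual_dist(crop)
  dmax <- max(dist)
  if (dmax < params$min_contrast) return(list())
  dn <- dist / dmax
  thr <- EBImage::otsu(EBImage::Image(t(dn)), range = c(0, 1))
  mask <- dn > thr
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask * 1)))))
  nlab <- max(lab)
  if (nlab == 0) return(list())
  areas <- tabulate(lab[lab > 0], nbins = nlab)
  contours <- EBImage::ocontour(EBImage::Image(t(lab)))
  out <- list()
  for (li in seq_len(nlab)) {
    if (areas[li] < params$min_area_px) next
    ct <- contours[[li]]           # 0-based (u, v) in ROI-local coords
    if (is.null(ct) || nrow(ct) < 3) next
    per <- contour_perimeter(ct)
    # tolerance floor of 1.5 px: rasterization staircases are ~1 px
    # regardless of marker size
    poly <- dp_closed(ct, eps = max(params$approx_frac * per, 1.5))
    if (nrow(poly) > 3) {
      poly <- decimate_polygon(poly, tol = max(2.5, 1.5 * params$approx_frac * per))
    }
    if (nrow(poly) != 3) next
    comp <- lab == li
    idx <- which(comp, arr.ind = TRUE)
    hull <- grDevices::chull(idx[, 2], idx[, 1])
    hp <- cbind(idx[hull, 2], idx[hull, 1])
    hull_px <- count_pixels_in_convex_poly(hp, range(idx[, 2]), range(idx[, 1]))
    solidity <- min(1, areas[li] / max(hull_px, 1))
    if (solidity < params$solidity_min) next
    # pixel-count-equivalent area of the vertex triangle (boundary pixels
    # straddle the continuous edge by half a pixel: Pick-style correction)
    tri_area <- shoelace_area(poly) + contour_perimeter(poly) / 2 + 1
    if (tri_area < 1e-9) next
    resid <- abs(areas[li] - tri_area) / tri_area
    if (resid > params$fit_tol) next
    # contrast-weighted sub-pixel centroid over the slightly dilated mask
    wmask <- EBImage::dilate(EBImage::Image(t(comp * 1)),
                             EBImage::makeBrush(3, "box"))
    wmask <- t(EBImage::imageData(wmask)) > 0
    fg_level <- stats::median(dist[comp])
    wts <- pmin(1, dist / fg_level) * wmask
    sw <- sum(wts)
    cu <- sum(wts * matrix(0:(ncol(dn) - 1), nrow(dn), ncol(dn), byrow = TRUE)) / sw
    cv <- sum(wts * matrix(0:(nrow(dn) - 1), nrow(dn), ncol(dn))) / sw
    score <- solidity * max(0, 1 - resid / params$fit_tol)
    out[[length(out) + 1]] <- structure(list(
      mask = comp,
      vertices = cbind(poly[, 1] + roi[1], poly[, 2] + roi[2]),
      centroid_px = c(cu + roi[1], cv + roi[2]),
      score = score, area = areas[li],
      offset_px = roi[1:2], frame_index = frame_index
    ), class = "marker_detection")
  }
  if (length(out) > 1) {
    o <- order(vapply(out, `[[`, numeric(1), "score"),
               vapply(out, `[[`, numeric(1), "area"), decreasing = TRUE)
    out <- out[o]
  }
  out
}

#' First-moment centroid of a binary mask
#'
#' @param x A logical/0-1 matrix (mask with `mask[v + 1, u + 1]` indexing),
#'   or a `marker_detection` (its ROI-local mask is used and the ROI offset
#'   applied).
#' @return Numeric `c(u, v)` zero-based pixel coordinates.
#' @export
mask_centroid <- function(x) {
  off <- c(0, 0)
  if (inherits(x, "marker_detection")) {
    off <- x$offset_px
    x <- x$mask
  }
  idx <- which(x > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  c(mean(idx[, 2]) - 1 + off[1], mean(idx[, 1]) - 1 + off[2])
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b Logical matrices of equal dimensions.
#' @return IoU in 0..1 (0 if both masks are empty).
#' @export
mask_iou <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(0)
  inter / uni
}

# Place an ROI-local detection mask onto a full-size canvas.
detection_full_mask <- function(det, dim_hw) {
  full <- matrix(FALSE, dim_hw[1], dim_hw[2])
  m <- det$mask
  r0 <- det$offset_px[2]; c0 <- det$offset_px[1]
  full[(r0 + 1):(r0 + nrow(m)), (c0 + 1):(c0 + ncol(m))] <- m
  full
}

#' Mean average precision of a single-class detector
#'
#' Predictions are matched to ground truths greedily in order of
#' decreasing score; a prediction is a true positive if its mask IoU with
#' an unmatched ground truth of the same image reaches `iou_threshold`
#' (each ground truth is matched at most once). AP is the area under the
#' precision-recall curve using the standard right-continuous precision
#' envelope; with a single class, mAP = AP.
#'
#' @param predictions List (one element per image) of lists of predictions;
#'   each prediction needs `score` and a full-size logical `mask` (a
#'   `marker_detection` is converted given its offset).
#' @param ground_truths List (per image) of lists of full-size logical
#'   ground-truth masks (a single matrix per image is also accepted).
#' @param iou_threshold IoU matching threshold in (0, 1).
#' @return mAP in 0..1. Defined as 1 when there are neither ground truths
#'   nor predictions, and 0 when predictions exist without ground truths.
#' @export
mean_average_precision <- function(predictions, ground_truths,
                                   iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold >= 1) {
    stop("iou_threshold must lie in (0, 1)")
  }
  stopifnot(length(predictions) == length(ground_truths))
  gts <- lapply(ground_truths, function(g) {
    if (is.matrix(g)) list(g) else g
  })
  n_gt <- sum(vapply(gts, length, integer(1)))
  flat <- list()
  for (i in seq_along(predictions)) {
    for (p in predictions[[i]]) {
      m <- if (inherits(p, "marker_detection")) {
        dim_hw <- dim(if (is.matrix(gts[[i]][[1]])) gts[[i]][[1]] else p$mask)
        detection_full_mask(p, dim_hw)
      } else p$mask
      flat[[length(flat) + 1]] <- list(image = i, score = p$score, mask = m)
    }
  }
  if (length(flat) == 0) return(if (n_gt == 0) 1 else 0)
  if (n_gt == 0) return(0)
  ord <- order(vapply(flat, `[[`, numeric(1), "score"), decreasing = TRUE)
  flat <- flat[ord]
  matched <- lapply(gts, function(g) logical(length(g)))
  tp <- numeric(length(flat))
  for (k in seq_along(flat)) {
    p <- flat[[k]]
    ious <- vapply(gts[[p$image]], function(g) mask_iou(p$mask, g), numeric(1))
    ious[matched[[p$image]]] <- -1
    if (length(ious) > 0 && max(ious) >= iou_threshold) {
      j <- which.max(ious)
      matched[[p$image]][j] <- TRUE
      tp[k] <- 1
    }
  }
  ctp <- cumsum(tp)
  precision <- ctp / seq_along(tp)
  recall <- ctp / n_gt
  # right-continuous precision envelope, integrated over recall steps
  penv <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * penv)
}

#' Run the reference detector over a detection dataset and score it
#'
#' @param dataset A [render_detection_dataset()] result.
#' @param params A [detector_params()].
#' @param iou_threshold IoU threshold for [mean_average_precision()].
#' @return mAP in 0..1.
#' @export
evaluate_detector <- function(dataset, params = detector_params(),
                              iou_threshold = 0.5) {
  preds <- lapply(dataset, function(e) detect_marker(e$image, params = params))
  gts <- lapply(dataset, function(e) e$mask)
  mean_average_precision(preds, gts, iou_threshold)
}
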