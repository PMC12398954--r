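#' Contrast-limited adaptive histogram equalization of a color image
#'
#' Equalizes the luminance channel tile-wise with clipped histograms and
#' bilinear tile interpolation (via \code{EBImage::clahe}), then rescales
#' the RGB channels by the luminance ratio so chroma is preserved. Used to
#' stabilise marker appearance under ambient-light variation before
#' detection.
#'
#' @param image H x W x 3 numeric array in 0..255 (a grayscale H x W matrix
#'   is also accepted).
#' @param clip_limit Histogram clip limit (> 0); higher means stronger
#'   enhancement.
#' @param tile_grid Integer pair: number of tiles along width and height.
#' @return Enhanced image, same shape and range as the input.
#' @export
clahe_enhance <- function(image, clip_limit = 2, tile_grid = c(8, 8)) {
  if (length(image) == 0) stop("empty image")
  if (clip_limit <= 0) stop("clip_limit must be > 0")
  gray <- is.matrix(image)
  lum <- if (gray) image else {
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  }
  H <- nrow(lum); W <- ncol(lum)
  # EBImage images are width-major; keep tile counts feasible for small ROIs
  nx <- max(1L, min(tile_grid[1], W %/% 8))
  ny <- max(1L, min(tile_grid[2], H %/% 8))
  # clahe requires dimensions divisible by the tile counts: pad by edge
  # replication, equalize, crop back
  Wp <- ceiling(W / nx) * nx
  Hp <- ceiling(H / ny) * ny
  lpad <- lum[c(seq_len(H), rep(H, Hp - H)), c(seq_len(W), rep(W, Wp - W)),
              drop = FALSE]
  eq <- EBImage::clahe(EBImage::Image(t(lpad) / 255), nx = nx, ny = ny,
                       limit = clip_limit)
  lum_new <- t(EBImage::imageData(eq))[seq_len(H), seq_len(W)] * 255
  if (gray) return(pmin(255, pmax(0, lum_new)))
  ratio <- lum_new / pmax(lum, 1e-6)
  out <- image
  for (k in 1:3) out[, , k] <- pmin(255, pmax(0, image[, , k] * ratio))
  out
}

#' Temporal median filter over a short window of depth frames
#'
#' Per-pixel median over (up to) the five most recent depth maps, the
#' standard defence against single-frame depth anomalies. Invalid pixels
#' (value 0) are excluded from the median; a pixel invalid across the whole
#' window stays 0 in the output. With fewer than `window_size` frames
#' buffered (session warm-up) the median of the available frames is used.
#'
#' @param window List of H x W depth matrices in mm, oldest first.
#' @param window_size Nominal window length (default 5).
#' @return H x W matrix of median-filtered depth in mm (0 where no valid
#'   sample exists).
#' @export
temporal_median_depth <- function(window, window_size = 5) {
  if (!is.list(window) || length(window) == 0) {
    stop("window must hold at least one depth frame")
  }
  k <- length(window)
  if (k > window_size) window <- window[(k - window_size + 1):k]
  stack <- vapply(window, as.vector, numeric(length(window[[1]])))
  stack <- matrix(stack, ncol = length(window))
  stack[stack <= 0] <- NA_real_
  med <- apply(stack, 1, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  matrix(med, nrow = nrow(window[[1]]), ncol = ncol(window[[1]]))
}

#' Median-filtered depth at a marker centroid
#'
#' Applies the temporal median over the frame window inside a square patch
#' centred on the (rounded) centroid, then averages the valid pixels. The
#' patch average beats a single-pixel read because depth noise is
#' independent per pixel.
#'
#' @param frame_window List of H x W depth matrices, oldest first (the
#'   rolling five-frame buffer).
#' @param centroid_px Numeric `c(u, v)` zero-based pixel coordinates; must
#'   lie inside the image.
#' @param patch_radius_px Half-width of the square patch in pixels.
#' @return Mean median-filtered depth in mm, or `NA_real_` if no valid
#'   depth pixel exists in the patch (missing-depth condition).
#' @export
depth_at_centroid <- function(frame_window, centroid_px, patch_radius_px = 3) {
  if (!is.list(frame_window) || length(frame_window) == 0) {
    stop("frame_window must hold at least one depth frame")
  }
  d1 <- frame_window[[1]]
  H <- nrow(d1); W <- ncol(d1)
  uc <- round(centroid_px[1]); vc <- round(centroid_px[2])
  if (uc < 0 || uc > W - 1 || vc < 0 || vc > H - 1) {
    stop("centroid lies outside the image")
  }
  rows <- max(1, vc + 1 - patch_radius_px):min(H, vc + 1 + patch_radius_px)
  cols <- max(1, uc + 1 - patch_radius_px):min(W, uc + 1 + patch_radius_px)
  patches <- lapply(frame_window, function(d) d[rows, cols, drop = FALSE])
  med <- temporal_median_depth(patches)
  valid <- med > 0
  if (!any(valid)) return(NA_real_)
  mean(med[valid])
}
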