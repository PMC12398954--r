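#' Pinhole camera intrinsics
#'
#' Bundles the pinhole-model parameters that tie image pixels to physical
#' millimetres: focal lengths, principal point and sensor resolution.
#' Pixel coordinates are zero-based with `u` along the image width
#' (columns, rightward) and `v` along the height (rows, downward).
#'
#' @param fx,fy Focal lengths in pixels; must be positive.
#' @param cx,cy Principal point in pixels; must lie on the sensor.
#' @param width,height Sensor resolution in pixels.
#' @return An object of class `camera_intrinsics`.
#' @examples
#' intr <- camera_intrinsics(600, 600, 424, 240, 848, 480)
#' project_point(c(0, 0, 600), intr)
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height) {
  stopifnot(is.numeric(fx), is.numeric(fy), length(fx) == 1, length(fy) == 1)
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive")
  if (width <= 0 || height <= 0) stop("sensor dimensions must be positive")
  if (cx < 0 || cx >= width) stop("principal point cx must lie within [0, width)")
  if (cy < 0 || cy >= height) stop("principal point cy must lie within [0, height)")
  structure(
    list(fx = as.numeric(fx), fy = as.numeric(fy),
         cx = as.numeric(cx), cy = as.numeric(cy),
         width = as.integer(width), height = as.integer(height)),
    class = "camera_intrinsics"
  )
}

#' Default simulation intrinsics
#'
#' 848x480 sensor with fx = fy = 600 px and centred principal point,
#' approximating a wide-angle consumer depth camera at its native
#' streaming resolution.
#'
#' @return A `camera_intrinsics` object.
#' @export
default_intrinsics <- function() {
  camera_intrinsics(fx = 600, fy = 600, cx = 424, cy = 240,
                    width = 848, height = 480)
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera_intrinsics: %dx%d px, fx=%.1f fy=%.1f cx=%.1f cy=%.1f\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  invisible(x)
}

#' Project room-coordinate points to pixel coordinates
#'
#' Room coordinates are millimetres with `z_long` along the camera principal
#' axis (positive away from the camera, aligned with the couch longitudinal
#' axis), `y_vert` vertical up-positive and `x_lat` lateral right-positive
#' when facing the camera image. Because the image `v` axis points down,
#' `v = cy - fy * y_vert / z_long`.
#'
#' @param point Numeric vector `c(x_lat, y_vert, z_long)` in mm, or an
#'   n x 3 matrix of such rows.
#' @param intr A [camera_intrinsics()] object.
#' @return Numeric vector `c(u, v)` or an n x 2 matrix of pixel coordinates.
#' @export
project_point <- function(point, intr) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  p <- if (is.matrix(point)) point else matrix(point, nrow = 1)
  if (ncol(p) != 3) stop("point must have 3 coordinates (x_lat, y_vert, z_long)")
  if (any(p[, 3] <= 0)) stop("z_long must be positive for a visible point")
  u <- intr$cx + intr$fx * p[, 1] / p[, 3]
  v <- intr$cy - intr$fy * p[, 2] / p[, 3]
  out <- cbind(u = u, v = v)
  if (!is.matrix(point)) out[1, ] else out
}

#' Deproject a pixel plus depth to room coordinates
#'
#' Exact inverse of [project_point()] at the given depth.
#'
#' @param u,v Pixel coordinates (zero-based, sub-pixel allowed).
#' @param depth_mm Depth along the principal axis in mm; must be positive
#'   (0 is the invalid-depth sentinel).
#' @param intr A [camera_intrinsics()] object.
#' @return Numeric vector `c(x_lat, y_vert, z_long)` in mm (or an n x 3
#'   matrix for vector input).
#' @export
deproject_pixel <- function(u, v, depth_mm, intr) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  if (any(!is.finite(depth_mm)) || any(depth_mm <= 0)) {
    stop("depth_mm must be positive (0 marks invalid depth)")
  }
  x <- (u - intr$cx) * depth_mm / intr$fx
  y <- (intr$cy - v) * depth_mm / intr$fy
  out <- cbind(x_lat = x, y_vert = y, z_long = depth_mm)
  if (length(u) == 1) out[1, ] else out
}

#' Convert a pixel displacement to millimetres at a given depth
#'
#' Optical (in-plane) marker motion scales linearly with depth under the
#' pinhole model: `mm = delta_px * depth_mm / f_px`.
#'
#' @param delta_px Pixel displacement.
#' @param depth_mm Depth in mm; must be positive.
#' @param f_px Focal length in pixels; must be positive.
#' @return Displacement in mm.
#' @export
pixel_disp_to_mm <- function(delta_px, depth_mm, f_px) {
  if (any(depth_mm <= 0)) stop("depth_mm must be positive")
  if (any(f_px <= 0)) stop("f_px must be positive")
  delta_px * depth_mm / f_px
}
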