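#' Marker geometry specification
#'
#' Describes the triangular fiducial sticker affixed to the tracked surface.
#' Either give explicit `vertices_mm` (3 x 2 matrix of `(x_lat, y_vert)`
#' surface coordinates) or an equilateral side length, centre and rotation.
#'
#' @param side_mm Side length of an equilateral triangle in mm.
#' @param center_mm Centre `c(x_lat, y_vert)` on the surface in mm.
#' @param rotation_rad In-plane rotation.
#' @param color RGB triple in 0..255.
#' @param vertices_mm Optional explicit 3 x 2 vertex matrix; overrides the
#'   equilateral construction.
#' @export
marker_spec <- function(side_mm = 40, center_mm = c(0, 0), rotation_rad = 0,
                        color = c(220, 50, 50), vertices_mm = NULL) {
  if (is.null(vertices_mm)) {
    r <- side_mm / sqrt(3)
    ang <- rotation_rad + pi / 2 + c(0, 2, 4) * pi / 3
    vertices_mm <- cbind(center_mm[1] + r * cos(ang),
                         center_mm[2] + r * sin(ang))
  }
  vertices_mm <- as.matrix(vertices_mm)
  if (!all(dim(vertices_mm) == c(3, 2))) stop("vertices_mm must be 3 x 2")
  if (length(color) != 3 || any(color < 0) || any(color > 255)) {
    stop("color must be an RGB triple in 0..255")
  }
  structure(list(vertices_mm = vertices_mm, color = as.numeric(color)),
            class = "marker_spec")
}

#' Scene specification for the synthetic RGB-D phantom
#'
#' Emulates the phantom experiments the pipeline is validated on: a flat
#' surface perpendicular to the camera axis carrying the marker (1D motion
#' tests at 560-1120 mm stand-off), or a curved torso-like surface (a
#' parabolic cylinder) with coupled anterior-posterior and
#' superior-inferior motion.
#'
#' @param surface `"flat"` or `"torso"`.
#' @param base_depth_mm Rest distance from camera to the surface apex in mm;
#'   must lie in 400-1500 mm.
#' @param marker A [marker_spec()].
#' @param motion Named list of [waveform_sinusoid()]-style specs for any of
#'   `vertical`, `longitudinal`, `lateral`. Missing axes stay still.
#' @param fps Frame rate in Hz (native camera stream rate).
#' @param duration_s Sequence duration; defaults to the longest waveform.
#' @param background List: `level` (RGB or gray base color), `texture_sd`
#'   (per-pixel texture SD in intensity units).
#' @param illumination List: `gain_sd`, `offset_sd` for per-frame global
#'   ambient-light jitter applied to the color image.
#' @param torso List: `half_width_mm`, `bulge_mm` describing the parabolic
#'   cross-section (apex at `base_depth_mm`, receding by `bulge_mm` at the
#'   lateral edges).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(surface = c("flat", "torso"), base_depth_mm = 560,
                       marker = marker_spec(), motion = list(),
                       fps = 30, duration_s = NULL,
                       background = list(level = c(120, 120, 120), texture_sd = 3),
                       illumination = list(gain_sd = 0, offset_sd = 0),
                       torso = list(half_width_mm = 150, bulge_mm = 60)) {
  surface <- match.arg(surface)
  if (base_depth_mm < 400 || base_depth_mm > 1500) {
    stop("base_depth_mm must lie within [400, 1500] mm")
  }
  stopifnot(inherits(marker, "marker_spec"))
  if (length(motion) > 0) {
    if (is.null(names(motion)) ||
        !all(names(motion) %in% c("vertical", "longitudinal", "lateral"))) {
      stop("motion must be a named list over vertical/longitudinal/lateral")
    }
    for (m in motion) stopifnot(inherits(m, "waveform_spec"))
  }
  if (is.null(duration_s)) {
    duration_s <- if (length(motion) > 0) {
      max(vapply(motion, function(m) m$duration_s, numeric(1)))
    } else 1
  }
  if (length(background$level) == 1) background$level <- rep(background$level, 3)
  structure(list(surface = surface, base_depth_mm = base_depth_mm,
                 marker = marker, motion = motion, fps = fps,
                 duration_s = duration_s, background = background,
                 illumination = illumination, torso = torso),
            class = "scene_spec")
}

# Anti-aliased coverage of a triangle over an image grid.
# uv: 3 x 2 matrix of zero-based pixel vertices. Returns an H x W matrix of
# per-pixel coverage fractions in [0, 1] (ss^2 supersamples per pixel).
triangle_coverage <- function(uv, width, height, ss = 4) {
  cov <- matrix(0, nrow = height, ncol = width)
  clo <- max(1, floor(min(uv[, 1])));  chi <- min(width,  ceiling(max(uv[, 1])) + 2)
  rlo <- max(1, floor(min(uv[, 2])));  rhi <- min(height, ceiling(max(uv[, 2])) + 2)
  if (clo > chi || rlo > rhi) return(cov)
  c0 <- clo:chi
  r0 <- rlo:rhi
  u <- rep(c0 - 1, each = length(r0))   # zero-based pixel centres
  v <- rep(r0 - 1, times = length(c0))
  offs <- (seq_len(ss) - (ss + 1) / 2) / ss
  acc <- numeric(length(u))
  e <- rbind(uv[2, ] - uv[1, ], uv[3, ] - uv[2, ], uv[1, ] - uv[3, ])
  orient <- e[1, 1] * (uv[3, 2] - uv[1, 2]) - e[1, 2] * (uv[3, 1] - uv[1, 1])
  if (orient == 0) return(cov)
  s <- sign(orient)
  for (du in offs) for (dv in offs) {
    uu <- u + du; vv <- v + dv
    inside <- rep(TRUE, length(uu))
    for (k in 1:3) {
      cr <- e[k, 1] * (vv - uv[k, 2]) - e[k, 2] * (uu - uv[k, 1])
      inside <- inside & (s * cr >= 0)
    }
    acc <- acc + inside
  }
  cov[cbind(rep(r0, times = length(c0)), rep(c0, each = length(r0)))] <-
    acc / (ss * ss)
  cov
}

# Depth map (mm) of the scene surface for one frame, before sensor noise.
surface_depth_map <- function(scene, intr, dz) {
  W <- intr$width; H <- intr$height
  if (scene$surface == "flat") {
    return(matrix(scene$base_depth_mm + dz, nrow = H, ncol = W))
  }
  hw <- scene$torso$half_width_mm
  b <- scene$torso$bulge_mm
  z0 <- scene$base_depth_mm + dz
  zbg <- scene$base_depth_mm + b
  up <- ((seq_len(W) - 1) - intr$cx) / intr$fx   # x = up * z
  a <- b * up^2 / hw^2
  disc <- 1 - 4 * a * z0
  zcol <- rep(zbg, W)
  ok <- disc >= 0
  # near root of a z^2 - z + z0 = 0; a -> 0 limit is z = z0
  za <- ifelse(a[ok] < 1e-12, z0, (1 - sqrt(disc[ok])) / (2 * a[ok]))
  hit <- abs(up[ok] * za) <= hw
  zcol[ok][hit] <- za[hit]
  matrix(zcol, nrow = H, ncol = W, byrow = TRUE)
}

# z-coordinate of the rest surface at lateral position x (mm).
surface_rest_z <- function(scene, x) {
  if (scene$surface == "flat") return(rep(scene$base_depth_mm, length(x)))
  scene$base_depth_mm +
    scene$torso$bulge_mm * (x / scene$torso$half_width_mm)^2
}

#' Render a ground-truthed synthetic RGB-D frame sequence
#'
#' Renders the triangular marker on the moving surface at each frame pose,
#' produces per-pixel true depth plus Gaussian sensor noise from the
#' distance-dependent noise model, and records the exact marker-centroid
#' displacement as ground truth. Deterministic given `seed`; the static
#' background texture is derived from the scene alone so different seeds
#' change only the noise realization.
#'
#' @param scene A [scene_spec()].
#' @param intr A [camera_intrinsics()]; the marker must be fully inside the
#'   field of view at rest.
#' @param noise A [depth_noise_model()], or `NULL` for noiseless depth.
#' @param seed Integer seed for the noise realization.
#' @return An object of class `frame_sequence`: list with `frames` (each a
#'   list `timestamp_s`, `color` H x W x 3 array in 0..255, `depth` H x W
#'   matrix in mm, `frame_index`), `ground_truth` (data frame of per-frame
#'   displacements in mm), `scene`, `intrinsics`, `fps`.
#' @export
render_sequence <- function(scene, intr = default_intrinsics(),
                            noise = depth_noise_model(), seed = 1) {
  stopifnot(inherits(scene, "scene_spec"), inherits(intr, "camera_intrinsics"))
  n <- max(1L, floor(scene$duration_s * scene$fps))
  t <- (seq_len(n) - 1) / scene$fps
  disp <- cbind(
    x_lat = if (!is.null(scene$motion$lateral)) eval_waveform(scene$motion$lateral, t) else numeric(n),
    y_vert = if (!is.null(scene$motion$vertical)) eval_waveform(scene$motion$vertical, t) else numeric(n),
    z_long = if (!is.null(scene$motion$longitudinal)) eval_waveform(scene$motion$longitudinal, t) else numeric(n)
  )
  v2 <- scene$marker$vertices_mm
  rest <- cbind(v2[, 1], v2[, 2], surface_rest_z(scene, v2[, 1]))
  uv0 <- project_point(rest, intr)
  if (any(uv0[, 1] < 0) || any(uv0[, 1] > intr$width - 1) ||
      any(uv0[, 2] < 0) || any(uv0[, 2] > intr$height - 1)) {
    stop("marker lies outside the field of view at rest")
  }
  H <- intr$height; W <- intr$width
  bg <- with_local_seed(8191L, {
    tex <- matrix(stats::rnorm(H * W, 0, scene$background$texture_sd), H, W)
    arr <- array(0, c(H, W, 3))
    for (k in 1:3) arr[, , k] <- pmin(255, pmax(0, scene$background$level[k] + tex))
    arr
  })
  frames <- vector("list", n)
  with_local_seed(seed, {
    for (i in seq_len(n)) {
      verts <- sweep(rest, 2, disp[i, ], "+")
      uv <- project_point(verts, intr)
      cov <- triangle_coverage(uv, W, H)
      col <- bg
      for (k in 1:3) {
        col[, , k] <- (1 - cov) * col[, , k] + cov * scene$marker$color[k]
      }
      gsd <- scene$illumination$gain_sd %||% 0
      osd <- scene$illumination$offset_sd %||% 0
      if (gsd > 0 || osd > 0) {
        gain <- 1 + stats::rnorm(1, 0, gsd)
        off <- stats::rnorm(1, 0, osd)
        col <- pmin(255, pmax(0, col * gain + off))
      }
      dep <- surface_depth_map(scene, intr, disp[i, 3])
      if (!is.null(noise)) {
        np <- depth_noise_params(as.vector(dep), noise)
        dep <- dep + matrix(np$bias_mm + stats::rnorm(H * W) * np$sigma_mm, H, W)
      }
      frames[[i]] <- list(timestamp_s = t[i], color = col, depth = dep,
                          frame_index = i)
    }
  })
  gt <- data.frame(frame_index = seq_len(n), t_s = t,
                   x_lat_mm = disp[, 1], y_vert_mm = disp[, 2],
                   z_long_mm = disp[, 3])
  structure(list(frames = frames, ground_truth = gt, scene = scene,
                 intrinsics = intr, fps = scene$fps, seed = as.integer(seed)),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("frame_sequence: %d frames @ %g fps, %dx%d px, surface=%s\n",
              length(x$frames), x$fps, x$intrinsics$width,
              x$intrinsics$height, x$scene$surface))
  invisible(x)
}

#' Generate a synthetic triangle-detection dataset
#'
#' Renders `n_images` color images each containing one filled triangle of
#' random size, shape, rotation and color against varied backgrounds
#' (uniform skin-tone-like or gray colors, smooth gradients, mild pixel
#' noise), with ground-truth vertices and masks — the benchmark used to
#' score the marker detector with mean average precision.
#'
#' @param n_images Number of images.
#' @param seed Integer seed.
#' @param width,height Image size in pixels.
#' @param side_px Range of triangle scales (circumradius spans about
#'   `side_px / sqrt(3)`).
#' @param noise_sd_max Maximum per-pixel background noise SD.
#' @return An object of class `detection_dataset`: list of entries, each
#'   with `image` (H x W x 3, 0..255), `vertices_px` (3 x 2, zero-based)
#'   and `mask` (H x W logical).
#' @export
render_detection_dataset <- function(n_images = 60, seed = 1,
                                     width = 200, height = 150,
                                     side_px = c(20, 80), noise_sd_max = 5) {
  palette <- rbind(c(244, 208, 177), c(224, 172, 138), c(198, 134, 94),
                   c(141, 85, 36), c(90, 56, 37), c(120, 120, 120),
                   c(180, 180, 180), c(60, 60, 60))
  with_local_seed(seed, {
    lapply(seq_len(n_images), function(i) {
      base <- palette[sample(nrow(palette), 1), ] + stats::runif(3, -15, 15)
      img <- array(0, c(height, width, 3))
      if (stats::runif(1) < 0.5) {   # smooth illumination gradient
        gu <- stats::runif(1, -30, 30); gv <- stats::runif(1, -30, 30)
        gg <- outer(seq(0, 1, length.out = height) - 0.5,
                    rep(1, width)) * gv +
              outer(rep(1, height),
                    seq(0, 1, length.out = width) - 0.5) * gu
      } else gg <- matrix(0, height, width)
      nsd <- stats::runif(1, 0, noise_sd_max)
      for (k in 1:3) {
        img[, , k] <- pmin(255, pmax(0, base[k] + gg +
          matrix(stats::rnorm(height * width, 0, nsd), height, width)))
      }
      repeat {
        tcol <- stats::runif(3, 0, 255)
        if (sqrt(sum((tcol - base)^2)) >= 100) break
      }
      side <- stats::runif(1, side_px[1], side_px[2])
      r <- side / sqrt(3)
      margin <- r * 1.3
      cx <- stats::runif(1, margin, width - 1 - margin)
      cy <- stats::runif(1, margin, height - 1 - margin)
      rot <- stats::runif(1, 0, 2 * pi)
      repeat {   # jittered triangle, rejected if too flat
        ang <- rot + c(0, 2, 4) * pi / 3 + stats::runif(3, -0.25, 0.25)
        rad <- r * stats::runif(3, 0.85, 1.15)
        uv <- cbind(cx + rad * cos(ang), cy + rad * sin(ang))
        ar <- abs((uv[2, 1] - uv[1, 1]) * (uv[3, 2] - uv[1, 2]) -
                  (uv[2, 2] - uv[1, 2]) * (uv[3, 1] - uv[1, 1])) / 2
        if (ar > 0.25 * side^2) break
      }
      cov <- triangle_coverage(uv, width, height)
      for (k in 1:3) img[, , k] <- (1 - cov) * img[, , k] + cov * tcol[k]
      list(image = img, vertices_px = uv, mask = cov > 0.5)
    })
  }) -> entries
  structure(entries, class = "detection_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
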