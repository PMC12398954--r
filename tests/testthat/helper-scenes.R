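# Shared fixtures: a small sensor and quick scene builders keep rendering
# cheap while preserving the geometry of the full-resolution setups.

test_intrinsics <- function() {
  camera_intrinsics(fx = 600, fy = 600, cx = 120, cy = 80,
                    width = 240, height = 160)
}

# Flat-surface vertical sinusoid with a 1 s static pre-roll so the tracker
# baseline is established on the resting surface.
vertical_scene <- function(amplitude_mm = 20, frequency_hz = 0.2,
                           duration_s = 9, base_depth_mm = 560,
                           side_mm = 25, fps = 30) {
  wf <- waveform_sinusoid(amplitude_mm, frequency_hz, duration_s = duration_s,
                          sample_rate_hz = fps, delay_s = 1)
  scene_spec("flat", base_depth_mm, marker_spec(side_mm = side_mm),
             motion = list(vertical = wf), fps = fps,
             duration_s = duration_s)
}

# Render a filled triangle on a plain background (detector fixture).
triangle_image <- function(uv, color = c(230, 40, 40), bg = 120,
                           width = 220, height = 220) {
  img <- array(bg, c(height, width, 3))
  cov <- rgbdtrack:::triangle_coverage(uv, width, height)
  for (k in 1:3) img[, , k] <- (1 - cov) * img[, , k] + cov * color[k]
  img
}

square_image <- function(corner = c(60, 60), side = 60, color = c(230, 40, 40),
                         bg = 120, width = 220, height = 220) {
  img <- array(bg, c(height, width, 3))
  a <- corner; b <- corner + c(side, 0); cc <- corner + c(side, side)
  d <- corner + c(0, side)
  cov <- pmin(1, rgbdtrack:::triangle_coverage(rbind(a, b, cc), width, height) +
                 rgbdtrack:::triangle_coverage(rbind(a, cc, d), width, height))
  for (k in 1:3) img[, , k] <- (1 - cov) * img[, , k] + cov * color[k]
  img
}
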