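#' Read a run configuration file
#'
#' A single declarative YAML document describing the simulation scene,
#' camera intrinsics, depth-noise model, tracker settings, metrics options
#' and seed. Command-line flags override config values.
#'
#' @param path YAML file path.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

waveform_from_config <- function(w) {
  kind <- w$kind %||% "sinusoid"
  switch(kind,
    sinusoid = waveform_sinusoid(
      amplitude_mm = w$amplitude_mm, frequency_hz = w$frequency_hz,
      duration_s = w$duration_s, sample_rate_hz = w$sample_rate_hz %||% 30,
      phase_rad = w$phase_rad %||% 0),
    constant = waveform_constant(value_mm = w$value_mm %||% 0,
                                 duration_s = w$duration_s,
                                 sample_rate_hz = w$sample_rate_hz %||% 30),
    breathhold_trace = waveform_breathhold(
      amplitude_mm = w$amplitude_mm %||% 5,
      frequency_hz = w$frequency_hz %||% 0.25,
      duration_s = w$duration_s %||% 110,
      sample_rate_hz = w$sample_rate_hz %||% 30,
      holds = lapply(w$holds %||% list(c(25, 45, 15), c(70, 90, 15)),
                     unlist),
      transition_s = w$transition_s %||% 1.5,
      phase_rad = w$phase_rad %||% 0),
    stop("unknown waveform kind in config: ", kind)
  )
}

config_intrinsics <- function(cfg) {
  ic <- cfg$intrinsics
  if (is.null(ic)) return(default_intrinsics())
  camera_intrinsics(ic$fx, ic$fy, ic$cx, ic$cy, ic$width, ic$height)
}

config_noise <- function(cfg) {
  nc <- cfg$noise
  if (is.null(nc)) return(depth_noise_model())
  if (isTRUE(nc$none)) return(NULL)
  anchors <- if (is.null(nc$anchors)) default_noise_anchors() else {
    do.call(rbind, lapply(nc$anchors, unlist))
  }
  depth_noise_model(anchors)
}

config_scene <- function(cfg) {
  sc <- cfg$scene
  if (is.null(sc)) stop("config lacks a scene section")
  mk <- sc$marker %||% list()
  marker <- marker_spec(side_mm = mk$side_mm %||% 40,
                        center_mm = unlist(mk$center_mm %||% c(0, 0)),
                        rotation_rad = mk$rotation_rad %||% 0,
                        color = unlist(mk$color %||% c(220, 50, 50)))
  motion <- lapply(sc$motion %||% list(), waveform_from_config)
  scene_spec(surface = sc$surface %||% "flat",
             base_depth_mm = sc$base_depth_mm %||% 560,
             marker = marker, motion = motion,
             fps = sc$fps %||% 30, duration_s = sc$duration_s,
             background = sc$background %||%
               list(level = c(120, 120, 120), texture_sd = 3),
             illumination = sc$illumination %||%
               list(gain_sd = 0, offset_sd = 0),
             torso = sc$torso %||%
               list(half_width_mm = 150, bulge_mm = 60))
}

config_tracker <- function(cfg, intr) {
  tc <- cfg$tracker %||% list()
  roi <- unlist(tc$roi %||% c(0, 0, intr$width, intr$height))
  tracker_config(roi = roi, decimation = tc$decimation %||% 3,
                 patch_radius_px = tc$patch_radius_px %||% 3,
                 baseline_n_frames = tc$baseline_n_frames %||% 5,
                 clahe = tc$clahe %||% TRUE,
                 recenter_roi = tc$recenter_roi %||% FALSE)
}
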