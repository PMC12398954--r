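#' Tracker configuration
#'
#' @param roi Pixel rectangle `c(u0, v0, w, h)`, zero-based corner plus
#'   size, within which the marker is detected each frame.
#' @param decimation Emit every `decimation`-th frame (>= 1). The native
#'   30 fps stream decimated by 3 reproduces the ~10 Hz effective rate of
#'   the acquisition pipeline after ROI selection and filtering.
#' @param patch_radius_px Half-width of the depth-averaging patch around
#'   the centroid.
#' @param baseline_n_frames Number of initial tracked frames averaged into
#'   the baseline (zero-displacement) pose.
#' @param detector A [detector_params()].
#' @param clahe Apply CLAHE to the ROI before detection.
#' @param clip_limit,tile_grid CLAHE parameters (see [clahe_enhance()]).
#' @param recenter_roi If `TRUE`, re-centre the ROI on the tracked centroid
#'   after every tracked frame (adaptive ROI); default keeps the ROI fixed
#'   with suspend-on-exit semantics.
#' @param median_window Temporal depth median window length.
#' @export
tracker_config <- function(roi, decimation = 3, patch_radius_px = 3,
                           baseline_n_frames = 5,
                           detector = detector_params(), clahe = TRUE,
                           clip_limit = 2, tile_grid = c(8, 8),
                           recenter_roi = FALSE, median_window = 5) {
  if (length(roi) != 4 || roi[3] <= 0 || roi[4] <= 0) {
    stop("roi must be c(u0, v0, w, h) with positive size")
  }
  if (decimation < 1) stop("decimation must be >= 1")
  if (baseline_n_frames < 1) stop("baseline_n_frames must be >= 1")
  structure(list(roi = roi, decimation = as.integer(decimation),
                 patch_radius_px = patch_radius_px,
                 baseline_n_frames = as.integer(baseline_n_frames),
                 detector = detector, clahe = clahe,
                 clip_limit = clip_limit, tile_grid = tile_grid,
                 recenter_roi = recenter_roi,
                 median_window = as.integer(median_window)),
            class = "tracker_config")
}

#' Initialise an incremental tracker
#'
#' @param config A [tracker_config()].
#' @param intr A [camera_intrinsics()]; the ROI must lie on the sensor.
#' @return A tracker state to be threaded through [tracker_step()] and
#'   finished with [tracker_finalize()].
#' @export
tracker_init <- function(config, intr) {
  stopifnot(inherits(config, "tracker_config"),
            inherits(intr, "camera_intrinsics"))
  r <- config$roi
  if (r[1] < 0 || r[2] < 0 || r[1] + r[3] > intr$width ||
      r[2] + r[4] > intr$height) {
    stop("roi must lie within the sensor bounds")
  }
  list(config = config, intr = intr, roi = r, depth_window = list(),
       n_seen = 0L, suspended = FALSE, samples = list())
}

#' Advance the tracker by one frame
#'
#' Pushes the frame's depth map into the rolling median window; on emitted
#' frames (per the decimation factor) runs CLAHE, detects the marker inside
#' the ROI, reads the median-filtered patch depth at the centroid and
#' deprojects to a 3D pose. A frame with no acceptable detection suspends
#' tracking until [reset_roi()]; a frame without valid depth in the patch
#' is emitted with status `MISSING_DEPTH`.
#'
#' @param state Tracker state from [tracker_init()].
#' @param frame A frame: list with `timestamp_s`, `color`, `depth`,
#'   `frame_index`.
#' @return Updated state.
#' @export
tracker_step <- function(state, frame) {
  cfg <- state$config
  state$depth_window <- c(state$depth_window, list(frame$depth))
  if (length(state$depth_window) > cfg$median_window) {
    state$depth_window <- state$depth_window[-1]
  }
  state$n_seen <- state$n_seen + 1L
  if ((state$n_seen - 1L) %% cfg$decimation != 0L) return(state)
  t <- frame$timestamp_s
  emit <- function(state, pose, status) {
    state$samples[[length(state$samples) + 1]] <-
      list(t_s = t, pose = pose, status = status)
    state
  }
  if (state$suspended) return(emit(state, NULL, "SUSPENDED"))
  r <- state$roi
  rows <- (r[2] + 1):(r[2] + r[4])
  cols <- (r[1] + 1):(r[1] + r[3])
  crop <- frame$color[rows, cols, , drop = FALSE]
  if (isTRUE(cfg$clahe)) {
    crop <- clahe_enhance(crop, cfg$clip_limit, cfg$tile_grid)
  }
  dets <- detect_marker(crop, params = cfg$detector,
                        frame_index = frame$frame_index)
  if (length(dets) == 0) {
    state$suspended <- TRUE
    return(emit(state, NULL, "SUSPENDED"))
  }
  cen <- dets[[1]]$centroid_px + r[1:2]
  depth <- depth_at_centroid(state$depth_window, cen, cfg$patch_radius_px)
  if (is.na(depth)) return(emit(state, NULL, "MISSING_DEPTH"))
  pose <- deproject_pixel(cen[1], cen[2], depth, state$intr)
  state <- emit(state, pose, "TRACKED")
  if (isTRUE(cfg$recenter_roi)) {
    u0 <- round(cen[1] - r[3] / 2); v0 <- round(cen[2] - r[4] / 2)
    u0 <- min(max(u0, 0), state$intr$width - r[3])
    v0 <- min(max(v0, 0), state$intr$height - r[4])
    state$roi <- c(u0, v0, r[3], r[4])
  }
  state
}

#' Resume a suspended tracker with a new ROI
#'
#' Mirrors the interactive reset prompt of the acquisition GUI: after the
#' marker exits the ROI and tracking suspends, the user supplies a new ROI
#' and tracking resumes. The baseline pose is preserved so displacements
#' remain comparable across the gap. If the marker is not found in the new
#' ROI, the tracker suspends again at the next frame.
#'
#' @param state Tracker state.
#' @param new_roi Pixel rectangle `c(u0, v0, w, h)`.
#' @return Updated state. Calling while tracking is active is a no-op with
#'   a warning.
#' @export
reset_roi <- function(state, new_roi) {
  if (!isTRUE(state$suspended)) {
    warning("reset_roi called while tracking is active; ignored")
    return(state)
  }
  if (length(new_roi) != 4 || new_roi[3] <= 0 || new_roi[4] <= 0 ||
      new_roi[1] < 0 || new_roi[2] < 0 ||
      new_roi[1] + new_roi[3] > state$intr$width ||
      new_roi[2] + new_roi[4] > state$intr$height) {
    stop("new_roi must be a valid on-sensor rectangle")
  }
  state$roi <- new_roi
  state$suspended <- FALSE
  state
}

#' Finish tracking and assemble the motion trace
#'
#' The baseline (zero-displacement) pose is the mean of the first
#' `baseline_n_frames` tracked poses; displacements are reported relative
#' to it. Longitudinal displacement comes from depth change; vertical and
#' lateral displacements from optical centroid motion scaled by depth (via
#' the deprojected poses).
#'
#' @param state Tracker state after all frames.
#' @return A `motion_trace`: data frame with columns `t_s`, `x_lat_mm`,
#'   `y_vert_mm`, `z_long_mm`, `status`; attributes `reference_pose` and
#'   `metadata`.
#' @export
tracker_finalize <- function(state) {
  cfg <- state$config
  n <- length(state$samples)
  if (n == 0) stop("no frames were processed")
  status <- vapply(state$samples, `[[`, character(1), "status")
  t_s <- vapply(state$samples, `[[`, numeric(1), "t_s")
  poses <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (status[i] == "TRACKED") poses[i, ] <- state$samples[[i]]$pose
  }
  tracked <- which(status == "TRACKED")
  if (length(tracked) == 0) {
    warning("no frame was tracked; trace contains no displacements")
    baseline <- c(NA_real_, NA_real_, NA_real_)
    disp <- poses
  } else {
    if (all(status[seq_len(min(cfg$baseline_n_frames, n))] != "TRACKED")) {
      stop("tracking initialization failed: no detection in the first ",
           cfg$baseline_n_frames, " frames")
    }
    bidx <- tracked[seq_len(min(cfg$baseline_n_frames, length(tracked)))]
    baseline <- colMeans(poses[bidx, , drop = FALSE])
    disp <- sweep(poses, 2, baseline, "-")
  }
  trace <- data.frame(t_s = t_s, x_lat_mm = disp[, 1], y_vert_mm = disp[, 2],
                      z_long_mm = disp[, 3], status = status,
                      stringsAsFactors = FALSE)
  attr(trace, "reference_pose") <- baseline
  attr(trace, "metadata") <- list(roi = cfg$roi, decimation = cfg$decimation,
                                  baseline_n_frames = cfg$baseline_n_frames)
  class(trace) <- c("motion_trace", "data.frame")
  trace
}

#' Track a whole frame sequence
#'
#' Convenience wrapper: [tracker_init()], [tracker_step()] over every
#' frame, [tracker_finalize()].
#'
#' @param frames A `frame_sequence` from [render_sequence()] /
#'   [read_sequence_dir()], or a plain list of frames (then `intr` is
#'   required).
#' @param config A [tracker_config()].
#' @param intr Camera intrinsics; defaults to the sequence's own.
#' @return A `motion_trace`.
#' @export
track_sequence <- function(frames, config, intr = NULL) {
  if (inherits(frames, "frame_sequence")) {
    if (is.null(intr)) intr <- frames$intrinsics
    frames <- frames$frames
  }
  if (is.null(intr)) stop("intrinsics required when passing a raw frame list")
  if (length(frames) < 1) stop("need at least one frame")
  state <- tracker_init(config, intr)
  for (f in frames) state <- tracker_step(state, f)
  tracker_finalize(state)
}
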