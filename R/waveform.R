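#' Waveform specifications for simulated respiratory motion
#'
#' A waveform spec describes a 1D displacement-versus-time program used to
#' drive the synthetic phantom: a pure sinusoid (the programmed motion of a
#' dynamic thorax phantom), a breath-hold trace (regular breathing
#' interrupted by constant plateaus, emulating deep-inspiration
#' breath-holds), or a constant (static scene).
#'
#' @param amplitude_mm Peak displacement in mm (>= 0).
#' @param frequency_hz Breathing frequency in Hz (> 0). Typical clinical
#'   programs span 6-20 cycles/min, i.e. 0.1-0.33 Hz.
#' @param duration_s Total duration in seconds (> 0).
#' @param sample_rate_hz Sampling rate used by [make_waveform()].
#' @param phase_rad Phase offset in radians.
#' @param delay_s Static pre-roll in seconds before the motion program
#'   starts (displacement 0 for t < delay_s), emulating baseline
#'   acquisition on the resting surface.
#' @return An object of class `waveform_spec`.
#' @seealso [waveform_breathhold()], [waveform_constant()], [make_waveform()]
#' @export
waveform_sinusoid <- function(amplitude_mm, frequency_hz, duration_s,
                              sample_rate_hz = 30, phase_rad = 0,
                              delay_s = 0) {
  if (amplitude_mm < 0) stop("amplitude_mm must be >= 0")
  if (frequency_hz <= 0) stop("frequency_hz must be > 0 for a sinusoid")
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be > 0")
  if (delay_s < 0) stop("delay_s must be >= 0")
  structure(list(kind = "sinusoid", amplitude_mm = amplitude_mm,
                 frequency_hz = frequency_hz, duration_s = duration_s,
                 sample_rate_hz = sample_rate_hz, phase_rad = phase_rad,
                 delay_s = delay_s),
            class = "waveform_spec")
}

#' @rdname waveform_sinusoid
#' @param value_mm Constant displacement in mm.
#' @export
waveform_constant <- function(value_mm = 0, duration_s = 10,
                              sample_rate_hz = 30) {
  if (duration_s <= 0) stop("duration_s must be > 0")
  structure(list(kind = "constant", value_mm = value_mm,
                 duration_s = duration_s, sample_rate_hz = sample_rate_hz),
            class = "waveform_spec")
}

#' Breath-hold waveform: regular breathing with constant plateaus
#'
#' Outside the hold segments the displacement follows the base sinusoid;
#' inside each `(start_s, end_s, plateau_mm)` segment it is held constant at
#' the plateau. A raised-cosine ramp of width `transition_s` on either side
#' of each hold keeps the trace continuous, mimicking the gradual
#' inspiration into and release out of a breath-hold.
#'
#' The defaults reproduce the structure of a recorded volunteer trace used
#' for irregular-motion testing: 110 s of breathing at 0.25 Hz with two deep
#' inspiration breath-holds.
#'
#' @inheritParams waveform_sinusoid
#' @param holds List of numeric triples `c(start_s, end_s, plateau_mm)`;
#'   segments must be non-overlapping (including ramps) and lie inside the
#'   duration.
#' @param transition_s Ramp width in seconds on each side of a hold.
#' @export
waveform_breathhold <- function(amplitude_mm = 5, frequency_hz = 0.25,
                                duration_s = 110, sample_rate_hz = 30,
                                holds = list(c(25, 45, 15), c(70, 90, 15)),
                                transition_s = 1.5, phase_rad = 0,
                                delay_s = 0) {
  if (delay_s < 0) stop("delay_s must be >= 0")
  if (amplitude_mm < 0) stop("amplitude_mm must be >= 0")
  if (frequency_hz <= 0) stop("frequency_hz must be > 0")
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (transition_s < 0) stop("transition_s must be >= 0")
  if (length(holds) > 0) {
    seg <- t(vapply(holds, function(h) {
      if (length(h) != 3) stop("each hold must be c(start_s, end_s, plateau_mm)")
      h
    }, numeric(3)))
    if (any(seg[, 1] >= seg[, 2])) stop("hold start must precede hold end")
    if (any(seg[, 1] < 0) || any(seg[, 2] > duration_s)) {
      stop("holds must lie within the waveform duration")
    }
    o <- order(seg[, 1])
    seg <- seg[o, , drop = FALSE]
    if (nrow(seg) > 1 &&
        any(seg[-1, 1] - seg[-nrow(seg), 2] < 2 * transition_s)) {
      stop("holds (including transition ramps) must not overlap")
    }
    holds <- lapply(seq_len(nrow(seg)), function(i) seg[i, ])
  }
  structure(list(kind = "breathhold_trace", amplitude_mm = amplitude_mm,
                 frequency_hz = frequency_hz, duration_s = duration_s,
                 sample_rate_hz = sample_rate_hz, holds = holds,
                 transition_s = transition_s, phase_rad = phase_rad,
                 delay_s = delay_s),
            class = "waveform_spec")
}

#' Evaluate a waveform at arbitrary times
#'
#' @param spec A `waveform_spec`.
#' @param t Numeric vector of times in seconds.
#' @return Displacement in mm at each time.
#' @export
eval_waveform <- function(spec, t) {
  stopifnot(inherits(spec, "waveform_spec"))
  before_start <- if (!is.null(spec$delay_s) && spec$delay_s > 0) {
    t < spec$delay_s
  } else rep(FALSE, length(t))
  t <- t - (spec$delay_s %||% 0)
  out <- switch(spec$kind,
    constant = rep(spec$value_mm, length(t)),
    sinusoid = spec$amplitude_mm *
      sin(2 * pi * spec$frequency_hz * t + spec$phase_rad),
    breathhold_trace = {
      d <- spec$amplitude_mm *
        sin(2 * pi * spec$frequency_hz * t + spec$phase_rad)
      w <- spec$transition_s
      for (h in spec$holds) {
        t0 <- h[1]; t1 <- h[2]; p <- h[3]
        inside <- t >= t0 & t <= t1
        d[inside] <- p
        if (w > 0) {
          pre <- t >= t0 - w & t < t0
          a <- (t[pre] - (t0 - w)) / w
          blend <- (1 - cos(pi * a)) / 2   # 0 -> 1 raised cosine
          d[pre] <- (1 - blend) * d[pre] + blend * p
          post <- t > t1 & t <= t1 + w
          a <- (t[post] - t1) / w
          blend <- (1 + cos(pi * a)) / 2   # 1 -> 0
          d[post] <- blend * p + (1 - blend) * d[post]
        }
      }
      d
    },
    stop("unknown waveform kind: ", spec$kind)
  )
  out[before_start] <- 0
  out
}

#' Sample a waveform on its regular time grid
#'
#' @param spec A `waveform_spec`.
#' @return A data frame with columns `t_s` and `d_mm`, one row per sample at
#'   the spec's sample rate, starting at t = 0.
#' @export
make_waveform <- function(spec) {
  stopifnot(inherits(spec, "waveform_spec"))
  n <- max(1L, floor(spec$duration_s * spec$sample_rate_hz))
  t <- (seq_len(n) - 1) / spec$sample_rate_hz
  data.frame(t_s = t, d_mm = eval_waveform(spec, t))
}
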