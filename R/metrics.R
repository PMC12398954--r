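#' Tracking success rate
#'
#' Percentage of paired samples whose absolute deviation from the nominal
#' motion is strictly less than each threshold. The clinical QA thresholds
#' are 2, 1.5 and 1 mm.
#'
#' @param measured,nominal Equal-length numeric vectors (mm).
#' @param thresholds_mm Positive thresholds in mm.
#' @return Named numeric vector of percentages in 0..100, one per
#'   threshold; non-decreasing in the threshold.
#' @export
tsr <- function(measured, nominal, thresholds_mm = c(1, 1.5, 2)) {
  check_paired(measured, nominal)
  if (any(thresholds_mm <= 0)) stop("thresholds must be positive")
  dev <- abs(measured - nominal)
  out <- vapply(thresholds_mm, function(tau) 100 * mean(dev < tau), numeric(1))
  names(out) <- as.character(thresholds_mm)
  out
}

#' Mean absolute error between paired traces
#'
#' @param measured,nominal Equal-length numeric vectors (mm).
#' @return MAE in mm.
#' @export
mae <- function(measured, nominal) {
  check_paired(measured, nominal)
  mean(abs(measured - nominal))
}

#' Pearson correlation between paired traces
#'
#' @param a,b Equal-length numeric vectors, n >= 3, both non-constant.
#' @return Sample Pearson product-moment correlation.
#' @export
pearson_r <- function(a, b) {
  check_paired(a, b)
  if (length(a) < 3) stop("need at least 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a constant series")
  }
  stats::cor(a, b)
}

check_paired <- function(a, b) {
  if (length(a) == 0) stop("empty series")
  if (length(a) != length(b)) stop("series must have equal length")
  invisible(TRUE)
}

#' 95% limits of agreement from a bias and SD
#'
#' `upper = bias + 1.96 sd`, `lower = bias - 1.96 sd`. The 1.96 multiplier
#' is the standard normal 95% quantile used in Bland-Altman analysis.
#'
#' @param bias_mm Mean difference in mm.
#' @param sd_mm SD of the differences in mm (>= 0).
#' @return Named numeric `c(upper, lower)` in mm.
#' @export
limits_of_agreement <- function(bias_mm, sd_mm) {
  if (sd_mm < 0) stop("sd_mm must be >= 0")
  c(upper = bias_mm + 1.96 * sd_mm, lower = bias_mm - 1.96 * sd_mm)
}

#' Bland-Altman agreement between two measurement systems
#'
#' Differences are taken as `a - b` (first system minus second); bias is
#' their mean, the limits of agreement are `bias +/- 1.96 sd` with the
#' sample SD (n - 1 denominator). The x-axis of the companion plot uses the
#' mean of each pair.
#'
#' @param a,b Paired numeric vectors (mm), n >= 2.
#' @return An object of class `bland_altman_result` with fields `bias_mm`,
#'   `sd_mm`, `loa_upper_mm`, `loa_lower_mm`, `n_pairs`, plus the paired
#'   `means` and `diffs` for plotting.
#' @export
bland_altman <- function(a, b) {
  check_paired(a, b)
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- limits_of_agreement(bias, s)
  structure(list(bias_mm = bias, sd_mm = s,
                 loa_upper_mm = unname(loa["upper"]),
                 loa_lower_mm = unname(loa["lower"]),
                 n_pairs = length(a), means = (a + b) / 2, diffs = d),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f mm, SD %.3f mm, LoA [%.3f, %.3f] mm\n",
              x$n_pairs, x$bias_mm, x$sd_mm, x$loa_lower_mm, x$loa_upper_mm))
  invisible(x)
}

# Extract (t, value) pairs from a motion_trace (TRACKED rows only) or a
# plain data frame with a time column and the requested axis/value column.
trace_xy <- function(x, axis = "y_vert_mm") {
  if (inherits(x, "motion_trace") ||
      (is.data.frame(x) && "status" %in% names(x))) {
    x <- x[x$status == "TRACKED", , drop = FALSE]
  }
  if (is.data.frame(x)) {
    tcol <- if ("t_s" %in% names(x)) "t_s" else names(x)[1]
    vcol <- if (axis %in% names(x)) axis else setdiff(names(x), tcol)[1]
    keep <- is.finite(x[[tcol]]) & is.finite(x[[vcol]])
    return(list(t = x[[tcol]][keep], y = x[[vcol]][keep]))
  }
  stop("expected a motion_trace or a data frame of (time, value)")
}

# Correlation between b and a shifted by s (a delayed by s), for each shift.
shift_correlation <- function(ta, ya, tb, yb, shifts) {
  vapply(shifts, function(s) {
    ai <- stats::approx(ta + s, ya, xout = tb, rule = 1)$y
    ok <- !is.na(ai)
    if (sum(ok) < 3 || stats::sd(ai[ok]) == 0 || stats::sd(yb[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(ai[ok], yb[ok])
  }, numeric(1))
}

#' Align two traces onto common timestamps with phase-shift correction
#'
#' Linearly interpolates trace `a` onto the timestamps of trace `b`
#' restricted to their temporal overlap, after applying the time shift
#' within `+/- max_shift_s` that maximises their cross-correlation
#' (searched on a millisecond grid). This mirrors the pairing of camera
#' data with a reference system sampled on its own clock, where small
#' systematic time offsets must be corrected before agreement analysis.
#'
#' @param trace_a,trace_b `motion_trace` objects or data frames of
#'   (time, value); tracked samples only are used.
#' @param max_shift_s Half-width of the shift search window in seconds
#'   (0 disables the search).
#' @param axis Trace column to align when full traces are given.
#' @return List with `t` (timestamps), `a` (interpolated values of trace
#'   a), `b` (values of trace b), and `applied_shift_s`.
#' @export
align_traces <- function(trace_a, trace_b, max_shift_s = 0.5,
                         axis = "y_vert_mm") {
  A <- trace_xy(trace_a, axis); B <- trace_xy(trace_b, axis)
  if (length(A$t) < 3 || length(B$t) < 3) stop("need >= 3 tracked samples")
  if (min(A$t) > max(B$t) || max(A$t) < min(B$t)) {
    stop("traces have no temporal overlap")
  }
  shift <- 0
  if (max_shift_s > 0) {
    coarse <- seq(-max_shift_s, max_shift_s, by = max(max_shift_s / 50, 0.001))
    cc <- shift_correlation(A$t, A$y, B$t, B$y, coarse)
    if (all(is.na(cc))) stop("traces have no usable overlap")
    s0 <- coarse[which.max(cc)]
    fine <- seq(s0 - 0.01, s0 + 0.01, by = 0.001)
    fine <- fine[abs(fine) <= max_shift_s]
    cf <- shift_correlation(A$t, A$y, B$t, B$y, fine)
    shift <- fine[which.max(cf)]
  }
  ai <- stats::approx(A$t + shift, A$y, xout = B$t, rule = 1)$y
  ok <- !is.na(ai)
  if (sum(ok) < 2) stop("traces have no usable overlap after alignment")
  list(t = B$t[ok], a = ai[ok], b = B$y[ok], applied_shift_s = shift)
}

#' Latency of a measured trace relative to a reference via phase shift
#'
#' Latency is the delay of the fundamental periodic component of the
#' measured signal relative to the reference, found as the location of the
#' cross-correlation peak on a grid upsampled to 1 ms and refined by a
#' parabolic fit. The uncertainty follows from the curvature of the
#' correlation peak and the residual scatter of the parabolic fit. The
#' search window must stay below the half-period of the test signal to
#' avoid phase aliasing; a correlation peak on the window boundary is
#' rejected as ambiguous.
#'
#' @param reference,measured Traces (see [align_traces()]); the reference
#'   should be sampled at least as fast as the measured trace.
#' @param max_shift_s Search half-window in seconds.
#' @param axis Trace column when full traces are given.
#' @return An object of class `latency_estimate` with `latency_ms`,
#'   `uncertainty_ms` and `method = "phase_shift"`.
#' @export
estimate_latency <- function(reference, measured, max_shift_s = 0.5,
                             axis = "y_vert_mm") {
  R <- trace_xy(reference, axis); M <- trace_xy(measured, axis)
  if (length(R$t) < 3 || length(M$t) < 3) stop("need >= 3 samples per trace")
  if (stats::sd(R$y) == 0 || stats::sd(M$y) == 0) {
    stop("latency undefined for a flat signal")
  }
  step <- 0.001
  shifts <- seq(-max_shift_s, max_shift_s, by = step)
  cc <- shift_correlation(R$t, R$y, M$t, M$y, shifts)
  if (all(is.na(cc))) stop("traces have no usable overlap")
  k <- which.max(cc)
  if (k <= 2 || k >= length(shifts) - 1) {
    stop("correlation peak on the search boundary: shift ambiguous, ",
         "increase max_shift_s or shorten the delay")
  }
  # parabolic refinement over the nearest grid points
  span <- max(1, min(5, k - 1, length(shifts) - k))
  idx <- (k - span):(k + span)
  x <- shifts[idx] - shifts[k]
  fit <- stats::lm(cc[idx] ~ x + I(x^2))
  a <- stats::coef(fit)[3]
  b <- stats::coef(fit)[2]
  vertex <- if (is.finite(a) && a < 0) shifts[k] - b / (2 * a) else shifts[k]
  if (abs(vertex - shifts[k]) > step) vertex <- shifts[k]  # keep within cell
  rms <- sqrt(mean(stats::residuals(fit)^2))
  unc_s <- if (is.finite(a) && a < 0) sqrt(max(rms, 1e-12) / abs(a)) else step
  structure(list(latency_ms = vertex * 1000,
                 uncertainty_ms = unc_s * 1000,
                 method = "phase_shift"),
            class = "latency_estimate")
}

#' @export
print.latency_estimate <- function(x, ...) {
  cat(sprintf("latency: %.2f ms (+/- %.2f ms, %s)\n",
              x$latency_ms, x$uncertainty_ms, x$method))
  invisible(x)
}

#' Drift statistics of a static acquisition
#'
#' Standard deviation of the tracked coordinate over the whole trace and
#' within consecutive windows, quantifying slow drift during prolonged
#' static measurements.
#'
#' @param trace A `motion_trace` or data frame of (time, value).
#' @param window_s Window length in seconds; the trace must be at least
#'   this long.
#' @param axis Trace column when a full trace is given; drift is usually
#'   assessed on the depth (longitudinal) coordinate.
#' @return List with `overall_sd_mm` and `windows` (data frame
#'   `start_s`, `end_s`, `sd_mm`).
#' @export
drift_stats <- function(trace, window_s, axis = "z_long_mm") {
  xy <- trace_xy(trace, axis)
  if (length(xy$t) < 2) stop("trace too short")
  dur <- max(xy$t) - min(xy$t)
  if (dur < window_s) stop("trace shorter than the requested window")
  t0 <- min(xy$t)
  bin <- floor((xy$t - t0) / window_s)
  # windows holding fewer than 2 samples have no defined SD and are dropped
  counts <- table(bin)
  keep <- bin %in% as.numeric(names(counts)[counts >= 2])
  stats_by <- tapply(xy$y[keep], bin[keep], stats::sd)
  wins <- data.frame(start_s = t0 + as.numeric(names(stats_by)) * window_s,
                     end_s = t0 + (as.numeric(names(stats_by)) + 1) * window_s,
                     sd_mm = as.numeric(stats_by))
  list(overall_sd_mm = stats::sd(xy$y), windows = wins)
}

#' Full validation report for one tracked axis
#'
#' Bundles the ground-truth comparison statistics: TSR at the clinical
#' thresholds, MAE and Pearson correlation.
#'
#' @param measured,nominal Equal-length numeric vectors in mm.
#' @param thresholds_mm TSR thresholds.
#' @param axis Label recorded in the report.
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(measured, nominal, thresholds_mm = c(1, 1.5, 2),
                        axis = "vertical") {
  r <- if (stats::sd(measured) == 0 || stats::sd(nominal) == 0) NA_real_
       else pearson_r(measured, nominal)
  structure(list(tsr = tsr(measured, nominal, thresholds_mm),
                 mae_mm = mae(measured, nominal),
                 pearson_r = r, n_pairs = length(measured), axis = axis),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report (%s axis, n = %d)\n", x$axis, x$n_pairs))
  for (nm in names(x$tsr)) {
    cat(sprintf("  TSR(<%s mm): %.2f%%\n", nm, x$tsr[[nm]]))
  }
  cat(sprintf("  MAE: %.3f mm\n  Pearson r: %s\n", x$mae_mm,
              ifelse(is.na(x$pearson_r), "undefined (constant series)",
                     sprintf("%.4f", x$pearson_r))))
  invisible(x)
}

#' Fit a sinusoid to a trace
#'
#' Least-squares fit of `offset + A sin(2 pi f t + phase)`. With a known
#' frequency the fit is linear in sine/cosine components; otherwise the
#' frequency is found by a golden-section refinement around the best
#' candidate on a frequency grid. Used to build the fitted nominal series
#' for longitudinal 1D experiments.
#'
#' @param t,y Time (s) and displacement (mm) samples.
#' @param frequency_hz Known frequency, or `NULL` to estimate it.
#' @return List with `amplitude_mm`, `phase_rad`, `offset_mm`,
#'   `frequency_hz` and `fitted` values at `t`.
#' @export
fit_sinusoid <- function(t, y, frequency_hz = NULL) {
  lin_fit <- function(f) {
    s <- sin(2 * pi * f * t); c_ <- cos(2 * pi * f * t)
    fit <- stats::lm(y ~ s + c_)
    list(rss = sum(stats::residuals(fit)^2), coef = stats::coef(fit), f = f)
  }
  if (is.null(frequency_hz)) {
    dur <- max(t) - min(t)
    grid <- seq(1 / dur, min(2, length(t) / (2 * dur)), length.out = 200)
    rss <- vapply(grid, function(f) lin_fit(f)$rss, numeric(1))
    f0 <- grid[which.min(rss)]
    opt <- stats::optimize(function(f) lin_fit(f)$rss,
                           interval = c(f0 * 0.8, f0 * 1.2))
    frequency_hz <- opt$minimum
  }
  fit <- lin_fit(frequency_hz)
  a <- fit$coef[["s"]]; b <- fit$coef[["c_"]]
  amp <- sqrt(a^2 + b^2)
  phase <- atan2(b, a)
  list(amplitude_mm = amp, phase_rad = phase,
       offset_mm = fit$coef[["(Intercept)"]], frequency_hz = frequency_hz,
       fitted = fit$coef[["(Intercept)"]] +
         amp * sin(2 * pi * frequency_hz * t + phase))
}
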