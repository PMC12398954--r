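#' Overlay a measured trace on its reference
#'
#' @param measured,reference Traces (see [align_traces()] for accepted
#'   forms).
#' @param axis Trace column to plot.
#' @return A ggplot object.
#' @export
plot_trace_overlay <- function(measured, reference, axis = "y_vert_mm") {
  M <- trace_xy(measured, axis); R <- trace_xy(reference, axis)
  df <- rbind(data.frame(t = R$t, y = R$y, series = "reference"),
              data.frame(t = M$t, y = M$y, series = "measured"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$y,
                                   color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = paste(axis, "displacement (mm)"),
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Bland-Altman scatter with bias and limits of agreement
#'
#' @param ba A `bland_altman_result`.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba) {
  stopifnot(inherits(ba, "bland_altman_result"))
  df <- data.frame(mean = ba$means, diff = ba$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = ba$bias_mm, color = "blue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower_mm, ba$loa_upper_mm),
                        color = "red", linetype = "dashed") +
    ggplot2::labs(x = "mean of pair (mm)", y = "difference (mm)") +
    ggplot2::theme_minimal()
}
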