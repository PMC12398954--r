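#' Distance-dependent depth noise model
#'
#' Consumer stereo depth cameras lose precision with distance. The model is
#' a table of `(depth_mm, bias_mm, sigma_mm)` anchors with linear
#' interpolation between them; per-pixel depth error is drawn as
#' `N(bias, sigma^2)` at the local true depth. The default anchors are the
#' static precision measured for the target camera over 1-min acquisitions:
#' 0.03 +/- 0.13 mm at 560 mm and 0.65 +/- 0.61 mm at 1120 mm.
#'
#' @param anchors Numeric matrix with columns `depth_mm`, `bias_mm`,
#'   `sigma_mm`, one row per calibration distance; rows need not be sorted.
#' @return An object of class `depth_noise_model`.
#' @examples
#' m <- depth_noise_model()
#' depth_noise_params(840, m)  # midway between the anchors
#' @export
depth_noise_model <- function(anchors = default_noise_anchors()) {
  anchors <- as.matrix(anchors)
  if (nrow(anchors) == 0) stop("noise model needs at least one anchor")
  if (ncol(anchors) != 3) stop("anchors must have columns depth, bias, sigma")
  if (any(anchors[, 3] < 0)) stop("sigma_mm must be >= 0")
  anchors <- anchors[order(anchors[, 1]), , drop = FALSE]
  colnames(anchors) <- c("depth_mm", "bias_mm", "sigma_mm")
  structure(list(anchors = anchors, interpolation = "linear"),
            class = "depth_noise_model")
}

#' @rdname depth_noise_model
#' @export
default_noise_anchors <- function() {
  matrix(c(560, 0.03, 0.13,
           1120, 0.65, 0.61),
         ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("depth_mm", "bias_mm", "sigma_mm")))
}

#' Interpolate depth-noise bias and sigma at given depths
#'
#' Linear interpolation between anchors; depths outside the anchored range
#' are clamped to the nearest anchor.
#'
#' @param depth_mm Numeric vector of depths in mm.
#' @param model A [depth_noise_model()].
#' @return A data frame with columns `bias_mm` and `sigma_mm`.
#' @export
depth_noise_params <- function(depth_mm, model = depth_noise_model()) {
  stopifnot(inherits(model, "depth_noise_model"))
  a <- model$anchors
  if (nrow(a) == 1) {
    return(data.frame(bias_mm = rep(a[1, 2], length(depth_mm)),
                      sigma_mm = rep(a[1, 3], length(depth_mm))))
  }
  bias <- stats::approx(a[, 1], a[, 2], xout = depth_mm, rule = 2)$y
  sigma <- stats::approx(a[, 1], a[, 3], xout = depth_mm, rule = 2)$y
  data.frame(bias_mm = bias, sigma_mm = sigma)
}

#' Add per-sample Gaussian measurement error to a nominal trace
#'
#' Convenience used to emulate tracking a programmed motion with a sensor
#' whose per-frame error is Gaussian with a fixed bias and SD (e.g. the
#' measured static precision at a given camera distance).
#'
#' @param nominal_mm Numeric vector of nominal displacements.
#' @param bias_mm Systematic error in mm.
#' @param sd_mm Random error SD in mm.
#' @param seed Optional integer seed; when given the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return Numeric vector of simulated measurements.
#' @export
simulate_measurement <- function(nominal_mm, bias_mm = 0, sd_mm = 0,
                                 seed = NULL) {
  if (sd_mm < 0) stop("sd_mm must be >= 0")
  draw <- function() nominal_mm + bias_mm + stats::rnorm(length(nominal_mm), 0, sd_mm)
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
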