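## Two-state thermal unfolding: van't Hoff simulation of melt traces
## (nanoDSF-style fluorescence ratio on a fine grid, or single-wavelength
## CD on a coarse grid) and melting-temperature extraction from the first
## derivative peak maximum.

#' Two-state melt model
#'
#' Fraction unfolded follows the van't Hoff form
#' \eqn{\theta(T) = 1/(1 + \exp[(\Delta H_{vH}/R)(1/T - 1/T_m)])} (T in K),
#' and the observable interpolates two linear baselines:
#' `signal = (1 - theta) * folded(T) + theta * unfolded(T)`.
#'
#' @param tm midpoint temperature, °C.
#' @param dh_vh van't Hoff enthalpy, kcal/mol (> 0; sets transition width).
#' @param folded_baseline `c(intercept, slope per °C)` of the folded state.
#' @param unfolded_baseline `c(intercept, slope per °C)` of the unfolded
#'   state.
#' @return Object of class `melt_model`.
#' @export
melt_model <- function(tm, dh_vh = 120, folded_baseline = c(1, 0),
                       unfolded_baseline = c(2, 0)) {
  if (!is.numeric(tm) || length(tm) != 1L || !is.finite(tm))
    stop_invalid("tm must be a finite numeric scalar (°C)")
  check_scalar(dh_vh, "dh_vh")
  if (length(folded_baseline) != 2L || length(unfolded_baseline) != 2L ||
      any(!is.finite(c(folded_baseline, unfolded_baseline))))
    stop_invalid("baselines must be finite (intercept, slope) pairs")
  structure(list(tm = tm, dh_vh = dh_vh,
                 folded_baseline = as.numeric(folded_baseline),
                 unfolded_baseline = as.numeric(unfolded_baseline)),
            class = "melt_model")
}

#' Fraction unfolded of a two-state model
#' @param model a [melt_model()].
#' @param temperature temperatures, °C.
#' @return Fraction unfolded in (0, 1); exactly 0.5 at `tm`.
#' @export
fraction_unfolded <- function(model, temperature) {
  stopifnot(inherits(model, "melt_model"))
  tk <- temperature + 273.15
  tmk <- model$tm + 273.15
  1 / (1 + exp(model$dh_vh / .R_KCAL * (1 / tk - 1 / tmk)))
}

#' Simulate a two-state melt curve
#'
#' @param model a [melt_model()].
#' @param temperatures strictly increasing grid, °C, within 0-120, >= 5
#'   points.
#' @param noise_sd Gaussian noise on the signal (same units as the signal).
#' @param seed optional integer seed.
#' @param channel_label free-text observable label.
#' @return Data frame of class `melt_curve` with columns `temperature`,
#'   `signal` and attribute `channel_label`.
#' @examples
#' m <- melt_model(69.8)
#' curve <- simulate_melt(m, seq(20, 95, by = 0.1))
#' @export
simulate_melt <- function(model, temperatures, noise_sd = 0, seed = NULL,
                          channel_label = "F350/F330") {
  stopifnot(inherits(model, "melt_model"))
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) < 5L || any(diff(temperatures) <= 0))
    stop_invalid("need >= 5 strictly increasing temperatures")
  if (any(temperatures < 0) || any(temperatures > 120))
    stop_invalid("temperature grid must lie within 0-120 °C")
  th <- fraction_unfolded(model, temperatures)
  fb <- model$folded_baseline; ub <- model$unfolded_baseline
  signal <- (1 - th) * (fb[1L] + fb[2L] * temperatures) +
    th * (ub[1L] + ub[2L] * temperatures)
  if (noise_sd > 0)
    signal <- with_seed_or_current(seed,
      signal + rnorm(length(signal), sd = noise_sd))
  out <- data.frame(temperature = temperatures, signal = signal)
  attr(out, "channel_label") <- channel_label
  class(out) <- c("melt_curve", "data.frame")
  out
}

#' Extract Tm from the first-derivative peak maximum
#'
#' Smooths the signal's first derivative with a second-order
#' Savitzky-Golay filter and takes the location of the largest absolute
#' derivative. On coarse grids (step > 1 °C) a quadratic through the
#' peak-adjacent triplet refines the maximum between grid points.
#'
#' @param curve a `melt_curve` (uniform temperature grid, >= 5 points).
#' @param smoothing_window odd window length in points; default 11 for
#'   fine grids (step <= 1 °C), 3 for coarse grids.
#' @return Object of class `melt_fit`: `tm` (°C), `method`,
#'   `smoothing_window`.
#' @examples
#' curve <- simulate_melt(melt_model(69.8), seq(20, 95, by = 0.1))
#' tm_from_derivative(curve)$tm
#' @export
tm_from_derivative <- function(curve, smoothing_window = NULL) {
  stopifnot(inherits(curve, "data.frame"))
  tt <- curve$temperature; y <- curve$signal
  if (length(tt) < 5L) stop_invalid("need >= 5 points")
  steps <- diff(tt)
  step <- median(steps)
  if (max(abs(steps - step)) > 1e-6 * max(step, 1))
    stop_invalid("temperature grid must be uniform")
  coarse <- step > 1
  if (is.null(smoothing_window)) smoothing_window <- if (coarse) 3L else 11L
  if (smoothing_window %% 2L != 1L || smoothing_window < 3L)
    stop_invalid("smoothing_window must be an odd integer >= 3")
  if (smoothing_window >= length(tt))
    stop_invalid("smoothing_window must be smaller than the number of points")
  d <- signal::sgolayfilt(y, p = 2, n = smoothing_window, m = 1, ts = step)
  peak <- which.max(abs(d))
  ## a transition shows as a derivative peak well above the baseline
  ## derivative level; a monotone trace has a flat |derivative|
  if (peak == 1L || peak == length(d) ||
      max(abs(d)) < 2 * median(abs(d)))
    stop_fit_failure("no interior derivative peak: no transition detected in the scanned range")
  tm <- tt[peak]
  if (coarse) {
    ## quadratic through the peak-adjacent triplet of |derivative|
    i <- (peak - 1L):(peak + 1L)
    xx <- tt[i]; yy <- abs(d[i])
    den <- (yy[1L] - 2 * yy[2L] + yy[3L])
    if (den < 0) {                       # concave: interior vertex exists
      tm <- xx[2L] + step * (yy[1L] - yy[3L]) / (2 * den)
    }
  }
  structure(list(tm = tm,
                 method = if (coarse) "derivative_peak_refined" else
                   "derivative_peak",
                 smoothing_window = as.integer(smoothing_window)),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("Tm = %.2f °C (%s, window %d points)\n",
              x$tm, x$method, x$smoothing_window))
  invisible(x)
}

#' Write a melt curve as CSV
#' @param curve a `melt_curve`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_melt_csv <- function(curve, file) {
  df <- as.data.frame(curve)
  df$channel <- attr(curve, "channel_label")
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read a melt curve from CSV
#' @param file CSV with columns `temperature`, `signal` and optionally
#'   `channel`.
#' @return A `melt_curve` data frame.
#' @export
read_melt_csv <- function(file) {
  df <- read.csv(file)
  if (!all(c("temperature", "signal") %in% names(df)))
    stop_invalid("need columns temperature and signal")
  out <- data.frame(temperature = df$temperature, signal = df$signal)
  attr(out, "channel_label") <- if ("channel" %in% names(df))
    as.character(df$channel[1L]) else ""
  class(out) <- c("melt_curve", "data.frame")
  out
}
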