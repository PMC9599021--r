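#' Fit a linear calibration curve
#'
#' Ordinary least-squares fit of signal (absorbance, or percent inhibition
#' for ABTS) against standard concentration. The calibrated concentration
#' range is recorded so that inverse predictions outside it can be flagged.
#'
#' @param concentration numeric vector of standard concentrations (>= 3
#'   distinct values).
#' @param signal numeric vector of measured signals, same length.
#' @param standard name of the reference standard (e.g. "gallic acid",
#'   "rutin", "Trolox").
#' @return a [CalibrationCurve-class] object.
#' @examples
#' fitStandardCurve(c(0, 100, 200), c(0, 0.5, 1.0), "gallic acid")
#' @export
fitStandardCurve <- function(concentration, signal, standard = "standard") {
  concentration <- as.numeric(concentration)
  signal <- as.numeric(signal)
  if (length(concentration) != length(signal))
    stop("'concentration' and 'signal' must have the same length")
  if (length(concentration) < 3L)
    stop("at least 3 standard points are required")
  if (any(!is.finite(concentration)) || any(!is.finite(signal)))
    stop("non-finite values in standard points")
  if (any(concentration < 0))
    stop("standard concentrations must be non-negative")
  if (sd(concentration) == 0)
    stop("standard concentrations are all equal: cannot fit a curve")
  if (sd(signal) == 0)
    stop("standards show no signal response: degenerate curve")
  fit <- lm(signal ~ concentration)
  sstot <- sum((signal - mean(signal))^2)
  rsq <- if (sstot == 0) 1 else 1 - sum(residuals(fit)^2) / sstot
  new("CalibrationCurve",
      standard = as.character(standard),
      slope = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]),
      range = range(concentration),
      r.squared = rsq,
      n = length(concentration))
}

#' Construct a calibration curve from known coefficients
#'
#' Convenience constructor for a curve with known slope and intercept
#' (e.g. a previously fitted curve read back from a file).
#'
#' @param slope,intercept line coefficients (signal = slope * conc + intercept).
#' @param range concentration range \code{c(low, high)}.
#' @param standard standard name.
#' @param r.squared optional fit quality, defaults to \code{NA_real_}-free 1.
#' @return a [CalibrationCurve-class] object.
#' @export
calibrationCurve <- function(slope, intercept = 0, range = c(0, Inf),
                             standard = "standard", r.squared = 1) {
  new("CalibrationCurve", standard = as.character(standard),
      slope = as.numeric(slope), intercept = as.numeric(intercept),
      range = as.numeric(range), r.squared = as.numeric(r.squared),
      n = 0L)
}

#' Inverse-predict concentration from a calibration curve
#'
#' @param curve a [CalibrationCurve-class].
#' @param signal measured signal (absorbance or percent inhibition),
#'   vectorised.
#' @param warn emit a warning when a prediction falls outside the calibrated
#'   concentration range (extrapolation). The value is still returned.
#' @return numeric vector of concentrations in the standard's units.
#' @export
predictConcentration <- function(curve, signal, warn = TRUE) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (curve@slope == 0) stop("calibration slope is zero: curve is not invertible")
  conc <- (signal - curve@intercept) / curve@slope
  out <- conc < curve@range[1] | conc > curve@range[2]
  if (warn && any(out, na.rm = TRUE))
    warning(sprintf("%d prediction(s) outside the calibrated range [%g, %g] of the %s curve (extrapolation)",
                    sum(out, na.rm = TRUE), curve@range[1], curve@range[2],
                    curve@standard))
  conc
}
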