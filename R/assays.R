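## Antioxidant endpoints: radical scavenging percentages, IC50 estimation
## (bracketing interpolation by default, optional 4-parameter logistic
## fit), and FRAP calibration / unit conversion.

#' Radical scavenging activity from absorbances
#'
#' `scavenging (%) = (1 - A_sample / A_0) * 100`. Values below 0%
#' (pro-oxidant readings) or above 100% are passed through unchanged but
#' flagged with a warning, so raw assay pathology stays visible.
#'
#' @param a_sample Sample absorbance(s), >= 0.
#' @param a_0 Control absorbance(s), > 0.
#' @return Scavenging percentage(s).
#' @export
scavenging_activity <- function(a_sample, a_0) {
  if (any(!is.finite(a_0) | a_0 <= 0)) {
    fm_stop("control absorbance 'a_0' must be > 0", "invalid_input")
  }
  if (any(!is.finite(a_sample) | a_sample < 0)) {
    fm_stop("'a_sample' must be >= 0", "invalid_input")
  }
  out <- 100 * (1 - a_sample / a_0)
  if (any(out < 0 | out > 100)) {
    warning("scavenging_activity: value(s) outside [0, 100] (kept unclipped)")
  }
  out
}

#' Estimate the 50% scavenging concentration (IC50)
#'
#' Default method: linear interpolation on the concentration axis between
#' the two measured points bracketing 50% scavenging (a point at exactly
#' 50% is returned as is). The `fourPL` method fits a four-parameter
#' logistic curve by nonlinear least squares and reports the concentration
#' at which the fitted curve crosses 50%.
#'
#' @param curve An `assay_curve` or data.frame with a `concentration`
#'   column and either a `scavenging` column or `a_sample`/`a_0` columns
#'   (scavenging is then recomputed via [scavenging_activity()]).
#' @param method `"interpolation"` (default) or `"fourPL"` (needs >= 4
#'   points).
#' @return An `ic50_result`: `ic50` (same concentration units as the
#'   input), `method`, `bracket` (bracketing concentrations), and for
#'   `fourPL` the fitted coefficients.
#' @export
estimate_ic50 <- function(curve, method = c("interpolation", "fourPL")) {
  method <- match.arg(method)
  fm_assert(is.data.frame(curve) && "concentration" %in% names(curve),
            "'curve' needs a concentration column")
  conc <- curve$concentration
  fm_assert(all(diff(order(conc)) > 0) || !is.unsorted(conc),
            "concentrations must be increasing")
  scav <- if ("scavenging" %in% names(curve)) curve$scavenging
          else scavenging_activity(curve$a_sample, curve$a_0)

  if (method == "interpolation") {
    exact <- which(scav == 50)
    if (length(exact)) {
      return(structure(list(ic50 = conc[exact[1]], method = method,
                            bracket = rep(conc[exact[1]], 2)),
                       class = "ic50_result"))
    }
    above <- which(scav > 50)
    below <- which(scav < 50)
    if (!length(above) || !length(below) || min(above) <= min(below)) {
      j_ok <- length(above) && length(below) && any(above > min(below))
      if (!j_ok) {
        fm_stop(sprintf("50%% scavenging not bracketed: attained range [%.3g%%, %.3g%%]",
                        min(scav), max(scav)), "not_estimable")
      }
    }
    j <- min(above[above > min(below)])
    i <- max(below[below < j])
    ic50 <- conc[i] + (50 - scav[i]) * (conc[j] - conc[i]) /
      (scav[j] - scav[i])
    return(structure(list(ic50 = ic50, method = method,
                          bracket = c(conc[i], conc[j])),
                     class = "ic50_result"))
  }

  # four-parameter logistic: s(c) = lower + (upper - lower)/(1 + (e/c)^h)
  fm_assert(length(conc) >= 4, "the 4PL fit needs >= 4 points")
  start <- list(lower = max(min(scav), 0), upper = min(max(scav), 100),
                e = conc[which.min(abs(scav - 50))], h = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      scav ~ lower + (upper - lower) / (1 + (e / conc)^h),
      start = start, data = data.frame(conc = conc, scav = scav),
      lower = c(-50, 0, min(conc) / 100, 0.05),
      upper = c(50, 200, max(conc) * 100, 20),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) fm_stop(paste("4PL fit failed:",
                                      conditionMessage(e)), "not_estimable"))
  cf <- stats::coef(fit)
  if (!(cf["lower"] < 50 && cf["upper"] > 50)) {
    fm_stop(sprintf("fitted curve does not cross 50%% (asymptotes %.3g%%, %.3g%%)",
                    cf["lower"], cf["upper"]), "not_estimable")
  }
  ic50 <- cf[["e"]] / ((cf[["upper"]] - 50) / (50 - cf[["lower"]]))^(1 / cf[["h"]])
  structure(list(ic50 = unname(ic50), method = method,
                 bracket = range(conc), coefficients = cf),
            class = "ic50_result")
}

#' @export
print.ic50_result <- function(x, ...) {
  cat(sprintf("<ic50_result> IC50 = %.4g (method: %s)\n", x$ic50, x$method))
  invisible(x)
}

#' Fit a linear calibration line
#'
#' Ordinary least squares of absorbance on concentration, as used for the
#' FRAP Fe(II) standard series.
#'
#' @param concentrations Standard concentrations (mmol/L), >= 3 distinct
#'   values.
#' @param absorbances Measured absorbances, same length.
#' @return A `calibration_line`: `slope` (absorbance per mmol/L),
#'   `intercept`, `r_squared`, `range` (calibrated concentration span).
#' @export
fit_calibration <- function(concentrations, absorbances) {
  fm_assert(length(concentrations) >= 3 &&
              length(absorbances) == length(concentrations),
            "calibration needs >= 3 (concentration, absorbance) points")
  fm_assert(length(unique(concentrations)) >= 3,
            "calibration concentrations must be distinct")
  fit <- stats::lm(absorbances ~ concentrations)
  tss <- sum((absorbances - mean(absorbances))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 range = range(concentrations)),
            class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("<calibration_line> y = %.4gx %+.4g (R2 = %.4f) over [%g, %g] mmol/L\n",
              x$slope, x$intercept, x$r_squared, x$range[1], x$range[2]))
  invisible(x)
}

#' FRAP value from absorbance via a calibration line
#'
#' Inverts the calibration line (`concentration = (absorbance -
#' intercept) / slope`, mmol/L Fe2+ equivalents) and scales by the assay
#' volume over the sample dry mass, yielding mmol Fe2+ per g dry weight.
#' Absorbances outside the calibrated span trigger a warning.
#'
#' @param absorbance Measured absorbance(s).
#' @param line A `calibration_line` from [fit_calibration()].
#' @param sample_mass Sample dry mass in g.
#' @param volume Assay volume in L.
#' @return FRAP value(s) in mmol Fe2+ per g dry weight.
#' @export
frap_value <- function(absorbance, line, sample_mass = 1, volume = 1) {
  fm_assert(inherits(line, "calibration_line"),
            "'line' must come from fit_calibration()")
  if (line$slope == 0) fm_stop("calibration slope is zero", "invalid_input")
  fm_assert(sample_mass > 0 && volume > 0,
            "'sample_mass' and 'volume' must be positive")
  cal_span <- sort(line$slope * line$range + line$intercept)
  if (any(absorbance < cal_span[1] | absorbance > cal_span[2])) {
    warning("frap_value: absorbance outside the calibrated span")
  }
  conc <- (absorbance - line$intercept) / line$slope
  conc * volume / sample_mass
}

#' Read an assay table from CSV
#'
#' Expected columns: `assay`, `concentration`, `a_sample`, `a_0`.
#'
#' @param path CSV file path.
#' @return An `assay_curve` data.frame with scavenging recomputed.
#' @export
read_assay_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("assay", "concentration", "a_sample", "a_0")
  fm_assert(all(need %in% names(df)),
            paste("assay CSV needs columns:", paste(need, collapse = ", ")),
            "invalid_input")
  df$scavenging <- scavenging_activity(df$a_sample, df$a_0)
  class(df) <- c("assay_curve", "data.frame")
  df
}
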