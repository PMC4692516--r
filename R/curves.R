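#' Signal-time curve for one ROI or vessel voxel
#'
#' Container for a dynamic series of scanner signal intensities together with
#' the pre-contrast baseline signal \eqn{S_0} (acquired at the high flip
#' angle before injection).
#'
#' @param times Numeric vector, seconds since injection start, strictly
#'   increasing.
#' @param values Numeric vector of signal intensities (arbitrary scanner
#'   units), same length as `times`.
#' @param baseline Pre-contrast signal \eqn{S_0} (> 0). May be `NA` for
#'   curves (e.g. sham acquisitions) where only drift is of interest.
#' @return An object of class `signal_curve` with elements `times`, `values`
#'   and `baseline`.
#' @seealso [conc_curve()], [enhancement()]
#' @export
signal_curve <- function(times, values, baseline = NA_real_) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    dce_stop("times and values must have equal length", "dce_invalid_parameter")
  }
  if (length(times) && any(diff(times) <= 0)) {
    dce_stop("times must be strictly increasing", "dce_invalid_parameter")
  }
  if (!all(is.finite(values))) {
    dce_stop("signal values must be finite", "dce_invalid_parameter")
  }
  if (!is.na(baseline) && baseline <= 0) {
    dce_stop("baseline signal must be positive", "dce_invalid_parameter")
  }
  structure(list(times = times, values = values, baseline = baseline),
            class = "signal_curve")
}

#' Concentration-time curve
#'
#' Contrast-agent concentration (mM) sampled at given times. Negative values
#' are permitted: noise and scanner drift can drive the *apparent*
#' concentration below zero, and clipping would bias kinetic parameters.
#'
#' @param times Numeric vector, seconds, strictly increasing.
#' @param values Numeric vector, concentrations in mM.
#' @return An object of class `conc_curve`.
#' @export
conc_curve <- function(times, values) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    dce_stop("times and values must have equal length", "dce_invalid_parameter")
  }
  if (length(times) && any(diff(times) <= 0)) {
    dce_stop("times must be strictly increasing", "dce_invalid_parameter")
  }
  if (!all(is.finite(values))) {
    dce_stop("concentration values must be finite", "dce_invalid_parameter")
  }
  structure(list(times = times, values = values), class = "conc_curve")
}

#' @export
print.signal_curve <- function(x, ...) {
  cat(sprintf("<signal_curve> %d frames, t = %.1f..%.1f s, baseline = %s\n",
              length(x$times), min(x$times), max(x$times),
              format(x$baseline)))
  invisible(x)
}

#' @export
print.conc_curve <- function(x, ...) {
  cat(sprintf("<conc_curve> %d frames, t = %.1f..%.1f s, peak = %.4g mM\n",
              length(x$times), min(x$times), max(x$times), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.signal_curve <- function(x, ...) {
  data.frame(time_s = x$times, signal = x$values)
}

#' @export
as.data.frame.conc_curve <- function(x, ...) {
  data.frame(time_s = x$times, conc_mM = x$values)
}
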