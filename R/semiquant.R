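# Semi-quantitative enhancement-curve metrics: the model-free comparison arm.

#' Normalised area under the enhancement curve
#'
#' Trapezoidal area under the tissue enhancement curve divided by the area
#' under the vascular enhancement curve, both computed over the included
#' frames (the first `exclude_first` post-contrast frames are dropped, as
#' for model fitting).
#'
#' @param E_tissue,E_vif Enhancement series on a shared time grid.
#' @param times Frame times (s).
#' @param exclude_first Number of initial frames to drop.
#' @return Dimensionless area ratio.
#' @export
auc_norm <- function(E_tissue, E_vif, times, exclude_first = 3) {
  if (length(E_tissue) != length(times) || length(E_vif) != length(times)) {
    dce_stop("series and times must share a grid", "dce_invalid_parameter")
  }
  incl <- (exclude_first + 1L):length(times)
  if (length(incl) < 2L) dce_stop("need >= 2 included frames", "dce_invalid_parameter")
  t <- times[incl]
  a_t <- pracma::trapz(t, E_tissue[incl])
  a_v <- pracma::trapz(t, E_vif[incl])
  if (a_v <= 0) {
    dce_stop("VIF enhancement area must be positive", "dce_undefined_ratio")
  }
  a_t / a_v
}

#' Late slope of the enhancement curve
#'
#' Ordinary-least-squares slope of enhancement versus time in minutes over
#' the included frames.
#'
#' @param E Enhancement series.
#' @param times Frame times (s).
#' @param exclude_first Number of initial frames to drop.
#' @return Slope in enhancement fraction per minute.
#' @export
late_slope <- function(E, times, exclude_first = 3) {
  if (length(E) != length(times)) {
    dce_stop("series and times must share a grid", "dce_invalid_parameter")
  }
  incl <- (exclude_first + 1L):length(times)
  if (length(incl) < 2L) dce_stop("need >= 2 included frames", "dce_invalid_parameter")
  tm <- times[incl] / 60
  unname(stats::coef(stats::lm.fit(cbind(1, tm), E[incl]))[2])
}
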