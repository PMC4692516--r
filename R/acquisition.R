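#' Acquisition parameters for the dynamic SPGR protocol
#'
#' Bundles the spoiled-gradient-echo sequence settings and contrast-agent
#' relaxivities used throughout the signal model. Defaults correspond to a
#' 1.5 T low-temporal-resolution brain protocol: TR/TE = 8.24/3.1 ms,
#' pre-contrast flip angles 2 deg / 12 deg for variable-flip-angle T1
#' estimation, 20 post-contrast frames every 73 s, and gadoterate relaxivities
#' r1/r2 = 4.2/6.7 /s/mM.
#'
#' @param TR Repetition time (s).
#' @param TE Echo time (s).
#' @param alpha_low,alpha_high Flip angles in degrees of the two pre-contrast
#'   acquisitions; `alpha_high` is also the dynamic-series flip angle.
#' @param r1,r2 Longitudinal and transverse relaxivities (/s/mM).
#' @param dt Temporal resolution of the dynamic series (s).
#' @param n_frames Number of post-contrast frames.
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(TR = 8.24e-3, TE = 3.1e-3,
                       alpha_low = 2, alpha_high = 12,
                       r1 = 4.2, r2 = 6.7,
                       dt = 73, n_frames = 20) {
  for (nm in c("TR", "TE", "alpha_low", "alpha_high", "r1", "r2", "dt")) {
    if (!is_number(get(nm))) {
      dce_stop(sprintf("%s must be a single finite number", nm),
               "dce_invalid_parameter")
    }
  }
  if (TR <= 0) dce_stop("TR must be > 0", "dce_invalid_parameter")
  if (TE < 0) dce_stop("TE must be >= 0", "dce_invalid_parameter")
  if (!(alpha_low > 0 && alpha_low < alpha_high && alpha_high <= 90)) {
    dce_stop("require 0 < alpha_low < alpha_high <= 90 degrees",
             "dce_invalid_parameter")
  }
  if (r1 <= 0 || r2 <= 0) dce_stop("relaxivities must be > 0", "dce_invalid_parameter")
  if (dt <= 0) dce_stop("dt must be > 0", "dce_invalid_parameter")
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 4) {
    dce_stop("n_frames must be >= 4 (at least one frame must survive the 3-point exclusion)",
             "dce_invalid_parameter")
  }
  structure(list(TR = TR, TE = TE, alpha_low = alpha_low,
                 alpha_high = alpha_high, r1 = r1, r2 = r2,
                 dt = dt, n_frames = n_frames),
            class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf(
    "<acq_params> TR/TE = %.3g/%.3g ms, alpha = %g/%g deg, r1/r2 = %g/%g /s/mM, %d frames @ %g s\n",
    x$TR * 1e3, x$TE * 1e3, x$alpha_low, x$alpha_high, x$r1, x$r2,
    x$n_frames, x$dt))
  invisible(x)
}
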