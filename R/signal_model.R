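# Spoiled-gradient-echo signal model: forward signal synthesis, VFA and IR
# T1 estimation, enhancement, and enhancement -> concentration inversion.

#' Steady-state SPGR signal for a given contrast-agent concentration
#'
#' Forward model
#' \deqn{S = M_0 \sin\alpha \frac{1 - e^{-TR \cdot R_1}}{1 - \cos\alpha \, e^{-TR \cdot R_1}} e^{-TE \, r_2 C}}
#' with \eqn{R_1 = 1/T_{10} + r_1 C}. The transverse relaxation of the
#' pre-contrast tissue is absorbed into `M0`; only the concentration-dependent
#' part of the T2* decay is modelled.
#'
#' @param C Concentration (mM); vectorised.
#' @param T10 Pre-contrast longitudinal relaxation time (s), > 0.
#' @param M0 Equilibrium signal scale, > 0.
#' @param alpha Flip angle in degrees.
#' @param acq [acq_params()].
#' @return Signal in the same (arbitrary) units as `M0`.
#' @export
spgr_signal <- function(C, T10, M0 = 1, alpha = acq$alpha_high, acq = acq_params()) {
  if (!is_number(T10) || T10 <= 0) {
    dce_stop("T10 must be a single positive number", "dce_invalid_parameter")
  }
  if (!is_number(M0) || M0 <= 0) {
    dce_stop("M0 must be a single positive number", "dce_invalid_parameter")
  }
  a <- alpha * pi / 180
  R1 <- 1 / T10 + acq$r1 * C
  E1 <- exp(-acq$TR * R1)
  M0 * sin(a) * (1 - E1) / (1 - cos(a) * E1) * exp(-acq$TE * acq$r2 * C)
}

#' Variable-flip-angle T1 estimate from two pre-contrast SPGR signals
#'
#' Inverts the SPGR signal equation for two acquisitions sharing TR but
#' differing in flip angle:
#' \deqn{\frac{1}{T_{10}} = \frac{1}{TR}\ln\frac{S_R \sin\alpha_b \cos\alpha_a - \sin\alpha_a \cos\alpha_b}{S_R \sin\alpha_b - \sin\alpha_a}}
#' with signal ratio \eqn{S_R = S_a/S_b}.
#'
#' @param S_a Signal at `acq$alpha_low`.
#' @param S_b Signal at `acq$alpha_high`.
#' @param acq [acq_params()].
#' @return T10 in seconds.
#' @export
vfa_t1 <- function(S_a, S_b, acq = acq_params()) {
  if (!is_number(S_a) || !is_number(S_b) || S_a <= 0 || S_b <= 0) {
    dce_stop("signals must be single positive numbers", "dce_invalid_parameter")
  }
  aa <- acq$alpha_low * pi / 180
  ab <- acq$alpha_high * pi / 180
  SR <- S_a / S_b
  num <- SR * sin(ab) * cos(aa) - sin(aa) * cos(ab)
  den <- SR * sin(ab) - sin(aa)
  # E1 = den/num must lie in (0, 1); den -> 0 is the T1 -> Inf limit.
  if (!is.finite(num) || !is.finite(den) || den <= 0 || num <= den) {
    dce_stop(sprintf(
      "signal ratio S_R = %.6g is outside the physically valid range for these flip angles",
      SR), "dce_nonphysical_signal_ratio")
  }
  acq$TR / log(num / den)
}

#' Fractional signal enhancement above baseline
#'
#' \eqn{E_i = (S_i - S_0)/S_0}. Negative enhancement is preserved, not
#' clipped.
#'
#' @param curve A [signal_curve()] with a positive `baseline`.
#' @return Numeric vector of per-frame enhancement values.
#' @export
enhancement <- function(curve) {
  if (!inherits(curve, "signal_curve")) {
    dce_stop("curve must be a signal_curve", "dce_invalid_parameter")
  }
  if (is.na(curve$baseline) || curve$baseline <= 0) {
    dce_stop("curve baseline S0 must be positive", "dce_invalid_parameter")
  }
  (curve$values - curve$baseline) / curve$baseline
}

#' Theoretical SPGR enhancement at a given concentration
#'
#' Forward evaluation of the enhancement equation: the fractional change of
#' the SPGR signal at the dynamic flip angle when concentration rises from 0
#' to `C`, including the \eqn{e^{-r_2 C \cdot TE}} transverse term. This is
#' the function whose numerical inversion yields concentration from measured
#' enhancement.
#'
#' @inheritParams spgr_signal
#' @return Enhancement (dimensionless), vectorised over `C`.
#' @seealso [concentration_from_enhancement()]
#' @export
enhancement_from_concentration <- function(C, T10, acq = acq_params()) {
  spgr_signal(C, T10, 1, acq$alpha_high, acq) /
    spgr_signal(0, T10, 1, acq$alpha_high, acq) - 1
}

#' Concentration from measured enhancement by numerical inversion
#'
#' Solves the SPGR enhancement equation for concentration by bracketed
#' root-finding on the monotone increasing branch. The bracket defaults to
#' \[-1, 20\] mM; its upper end is shrunk to the concentration at which the
#' enhancement-concentration relation peaks (T1 saturation and T2* decay make
#' it non-monotone at high concentration). Small negative enhancements map to
#' small negative concentrations on the continuation of the same branch; no
#' clipping is applied.
#'
#' @param E Enhancement value(s), dimensionless.
#' @param T10 Pre-contrast T1 (s).
#' @param acq [acq_params()].
#' @param bracket Length-2 concentration bracket (mM).
#' @param tol Absolute tolerance on the enhancement residual.
#' @return Concentration(s) in mM.
#' @export
concentration_from_enhancement <- function(E, T10, acq = acq_params(),
                                           bracket = c(-1, 20), tol = 1e-9) {
  if (!is_number(T10) || T10 <= 0) {
    dce_stop("T10 must be a single positive number", "dce_invalid_parameter")
  }
  # Restrict to the monotone increasing branch. Below C = -1/(r1*T10) the
  # apparent R1 turns negative and the SPGR expression is unphysical (it has
  # a pole where the denominator vanishes), so the lower end of the bracket
  # is clamped just above that; the upper end is the peak of E(C), beyond
  # which T1 saturation and T2* decay make the relation decreasing.
  lo <- max(bracket[1], -1 / (acq$r1 * T10) * (1 - 1e-6))
  grid <- seq(lo, bracket[2], length.out = 801L)
  Eg <- enhancement_from_concentration(grid, T10, acq)
  upper <- grid[which.max(Eg)]
  f <- function(C, target) enhancement_from_concentration(C, T10, acq) - target
  vapply(E, function(e) {
    if (!is.finite(e)) {
      dce_stop("enhancement must be finite", "dce_invalid_parameter")
    }
    flo <- f(lo, e)
    fhi <- f(upper, e)
    if (flo > 0 || fhi < 0) {
      dce_stop(sprintf(
        "no concentration in [%.3g, %.3g] mM reproduces enhancement E = %.6g",
        lo, upper, e), "dce_no_solution")
    }
    r <- stats::uniroot(f, c(lo, upper), target = e, tol = .Machine$double.eps^0.75)
    if (abs(f(r$root, e)) > tol) {
      dce_stop(sprintf("inversion residual %.3g exceeds tolerance for E = %.6g",
                       f(r$root, e), e), "dce_no_solution")
    }
    r$root
  }, numeric(1))
}

#' Convert a measured signal curve to a concentration curve
#'
#' Convenience wrapper: computes the per-frame enhancement from the baseline
#' then inverts the SPGR enhancement equation frame by frame.
#'
#' @param curve A [signal_curve()].
#' @param T10 Pre-contrast T1 (s).
#' @param acq [acq_params()].
#' @return A [conc_curve()].
#' @export
signal_to_concentration <- function(curve, T10, acq = acq_params()) {
  E <- enhancement(curve)
  conc_curve(curve$times, concentration_from_enhancement(E, T10, acq))
}

#' Three-parameter inversion-recovery T1 fit
#'
#' Fits \eqn{SI = A + B \exp(-TI/T_1)} to signed inversion-recovery signal
#' intensities by Levenberg-Marquardt least squares, with starting values
#' from a grid search over T1 (linear in A, B at fixed T1).
#'
#' @param TI Inversion times (s), at least 4 distinct values.
#' @param SI Signal intensities at each TI.
#' @return List with elements `A`, `B`, `T1` (s), `ss` (residual sum of
#'   squares) and `converged`.
#' @export
ir_t1_fit <- function(TI, SI) {
  TI <- as.numeric(TI); SI <- as.numeric(SI)
  if (length(TI) != length(SI) || length(unique(TI)) < 4L) {
    dce_stop("need >= 4 distinct inversion times", "dce_invalid_parameter")
  }
  if (stats::sd(SI) < 1e-12 * (abs(mean(SI)) + 1e-300)) {
    dce_stop("flat signal: T1 is unidentifiable", "dce_fit_failure")
  }
  # Grid search over T1 with linear solve for (A, B) to seed the optimiser.
  t1_grid <- exp(seq(log(0.05), log(8), length.out = 60L))
  best <- NULL
  for (t1 in t1_grid) {
    X <- cbind(1, exp(-TI / t1))
    fit <- stats::lm.fit(X, SI)
    ss <- sum(fit$residuals^2)
    if (is.null(best) || ss < best$ss) {
      best <- list(A = unname(fit$coefficients[1]),
                   B = unname(fit$coefficients[2]), T1 = t1, ss = ss)
    }
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(SI ~ A + B * exp(-TI / T1),
                      start = list(A = best$A, B = best$B, T1 = best$T1),
                      lower = c(-Inf, -Inf, 1e-4),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    dce_stop(paste("inversion-recovery fit failed:", conditionMessage(fit)),
             "dce_fit_failure")
  }
  cf <- stats::coef(fit)
  if (abs(cf[["B"]]) < 1e-9 * (abs(cf[["A"]]) + 1e-300)) {
    dce_stop("fitted recovery amplitude B ~ 0: T1 is unidentifiable",
             "dce_fit_failure")
  }
  list(A = unname(cf[["A"]]), B = unname(cf[["B"]]), T1 = unname(cf[["T1"]]),
       ss = sum(stats::residuals(fit)^2), converged = TRUE)
}
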