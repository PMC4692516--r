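# Forward tissue-concentration models: steady-state, Patlak, modified Tofts
# and the two-compartment exchange model (2CXM) used for simulation.

#' Ground-truth tissue physiology for simulation
#'
#' @param Fp Plasma flow in ml/100 g/min (> 0). Converted internally to /min
#'   assuming tissue density 1 g/ml, so 10 ml/100 g/min corresponds to
#'   0.1 /min.
#' @param PS Permeability-surface area product (/min), >= 0.
#' @param vp Fractional plasma volume, in \[0, 1\].
#' @param ve Fractional interstitial volume, in \[0, 1\]; `vp + ve <= 1`.
#' @param T10 Pre-contrast T1 (s). Default 0.969 s, a typical
#'   normal-appearing-white-matter value in mild stroke patients at 1.5 T.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(Fp = 10, PS = 3e-4, vp = 0.006, ve = 0.2, T10 = 0.969) {
  for (nm in c("Fp", "PS", "vp", "ve", "T10")) {
    if (!is_number(get(nm))) {
      dce_stop(sprintf("%s must be a single finite number", nm), "dce_invalid_parameter")
    }
  }
  if (Fp <= 0) dce_stop("Fp must be > 0", "dce_invalid_parameter")
  if (PS < 0) dce_stop("PS must be >= 0", "dce_invalid_parameter")
  if (vp < 0 || vp > 1 || ve < 0 || ve > 1 || vp + ve > 1) {
    dce_stop("require 0 <= vp, ve and vp + ve <= 1", "dce_invalid_parameter")
  }
  if (T10 <= 0) dce_stop("T10 must be > 0", "dce_invalid_parameter")
  structure(list(Fp = Fp, PS = PS, vp = vp, ve = ve, T10 = T10),
            class = "tissue_params")
}

# Exact convolution of a piecewise-linear input C(t) (t in minutes, C assumed
# 0 for t < 0) with exp(a*t): returns int_0^{t_i} exp(a*(t_i - tau)) C(tau) dtau.
# Exponential integration is unconditionally stable, which matters for the
# stiff fast eigenvalue of the 2CXM when flow is high.
expconv_pl <- function(a, t, C) {
  prepended <- FALSE
  if (t[1] > 0) {
    t <- c(0, t); C <- c(0, C); prepended <- TRUE
  }
  n <- length(t)
  if (n < 2L) return(if (prepended) numeric(0) else 0)
  dt <- diff(t)
  x <- a * dt
  small <- abs(x) < 1e-5
  I0 <- ifelse(small, dt * (1 + x / 2 + x^2 / 6), (exp(x) - 1) / a)
  I1 <- ifelse(small, dt * (0.5 + x / 6 + x^2 / 24), (exp(x) - 1 - x) / (a^2 * dt))
  contrib <- C[-n] * (I0 - I1) + C[-1] * I1
  decay <- exp(x)
  if (all(abs(dt - dt[1]) < 1e-9 * dt[1])) {
    y <- as.numeric(stats::filter(contrib, decay[1], method = "recursive"))
  } else {
    y <- numeric(n - 1L)
    acc <- 0
    for (i in seq_len(n - 1L)) {
      acc <- acc * decay[i] + contrib[i]
      y[i] <- acc
    }
  }
  y <- c(0, y)
  if (prepended) y[-1] else y
}

check_shared_grid <- function(t, Cp) {
  if (!inherits(Cp, "conc_curve")) dce_stop("Cp must be a conc_curve", "dce_invalid_parameter")
  if (length(t) != length(Cp$times) || any(abs(t - Cp$times) > 1e-9)) {
    dce_stop("t must equal the sampling grid of Cp", "dce_invalid_parameter")
  }
}

#' Steady-state (intravascular-only) tissue model
#'
#' \eqn{C_t(t) = v_p C_p(t)}: no transfer of contrast agent to the
#' extravascular extracellular space.
#'
#' @param t Sampling times (s), identical to `Cp$times`.
#' @param Cp Plasma input function as a [conc_curve()].
#' @param vp Fractional plasma volume.
#' @return A [conc_curve()] of tissue concentration.
#' @export
steady_state_ct <- function(t, Cp, vp) {
  check_shared_grid(t, Cp)
  conc_curve(t, vp * Cp$values)
}

#' Patlak tissue model
#'
#' \eqn{C_t(t) = v_p C_p(t) + K^{Trans} \int_0^t C_p(\tau)\,d\tau}: the
#' unidirectional-uptake special case of the modified Tofts model that
#' ignores back-flux from the interstitium to plasma. The integral is the
#' cumulative trapezoid on the sampling grid with \eqn{C_p = 0} for
#' \eqn{t < 0}.
#'
#' @inheritParams steady_state_ct
#' @param KTrans Volume transfer constant (/min).
#' @return A [conc_curve()].
#' @export
patlak_ct <- function(t, Cp, vp, KTrans) {
  check_shared_grid(t, Cp)
  intCp <- cumtrapz_from_zero(t / 60, Cp$values)
  conc_curve(t, vp * Cp$values + KTrans * intCp)
}

#' Modified Tofts tissue model
#'
#' \eqn{C_t(t) = v_p C_p(t) + K^{Trans} \int_0^t C_p(\tau) e^{-K^{Trans}(t-\tau)/v_e}\,d\tau}:
#' bidirectional exchange between plasma and a well-mixed interstitium in a
#' highly perfused tissue. The convolution is evaluated on the sampling grid
#' assuming `Cp` piecewise linear (and 0 before the first sample).
#'
#' @inheritParams patlak_ct
#' @param ve Fractional interstitial volume (> 0 when `KTrans > 0`).
#' @return A [conc_curve()].
#' @export
mtofts_ct <- function(t, Cp, vp, KTrans, ve) {
  check_shared_grid(t, Cp)
  if (KTrans == 0) return(steady_state_ct(t, Cp, vp))
  if (ve <= 0) {
    dce_stop("ve must be > 0 when KTrans > 0", "dce_invalid_parameter")
  }
  kep <- KTrans / ve
  conv <- expconv_pl(-kep, t / 60, Cp$values)
  conc_curve(t, vp * Cp$values + KTrans * conv)
}

#' Two-compartment exchange model (2CXM)
#'
#' Solves the mass-balance system
#' \deqn{v_p \frac{dC_{cap}}{dt} = F_p (C_a - C_{cap}) + PS (C_e - C_{cap}), \qquad v_e \frac{dC_e}{dt} = PS (C_{cap} - C_e)}
#' and returns \eqn{C_t = v_p C_{cap} + v_e C_e}. The implementation uses the
#' analytic bi-exponential impulse response (eigen-decomposition of the 2x2
#' system) convolved with the input by exact piecewise-linear exponential
#' integration; this is stable even in the effectively-infinite-flow limit
#' where the fast eigenvalue makes naive discrete convolution fail.
#'
#' @param t Sampling times (s), identical to `Ca$times`; intended for a fine
#'   grid (0.1 s) when generating simulated data.
#' @param Ca Input (arterial/venous plasma) concentration as a [conc_curve()].
#' @param p A [tissue_params()] object.
#' @return A [conc_curve()] of tissue concentration.
#' @export
twocxm_ct <- function(t, Ca, p) {
  check_shared_grid(t, Ca)
  if (!inherits(p, "tissue_params")) p <- do.call(tissue_params, as.list(p))
  Fp <- p$Fp / 100  # ml/100g/min -> /min at unit density
  if (p$vp == 0) {
    dce_stop("vp must be > 0 for a nonzero plasma flow", "dce_invalid_parameter")
  }
  if (p$ve == 0 && p$PS > 0) {
    dce_stop("ve must be > 0 when PS > 0", "dce_invalid_parameter")
  }
  tm <- t / 60
  if (p$PS == 0) {
    # One-compartment limit: impulse response Fp * exp(-Fp t / vp).
    return(conc_curve(t, Fp * expconv_pl(-Fp / p$vp, tm, Ca$values)))
  }
  m11 <- -(Fp + p$PS) / p$vp
  m12 <- p$PS / p$vp
  m21 <- p$PS / p$ve
  m22 <- -p$PS / p$ve
  tr <- m11 + m22
  det <- m11 * m22 - m12 * m21
  disc <- sqrt(max(tr^2 - 4 * det, 0))
  lam1 <- (tr + disc) / 2
  lam2 <- (tr - disc) / 2
  if (abs(lam1 - lam2) < 1e-12 * max(abs(lam1), 1)) {
    lam2 <- lam2 * (1 + 1e-9) - 1e-15  # split a (measure-zero) repeated root
  }
  b <- c(Fp / p$vp, 0)
  cc <- c(p$vp, p$ve)
  # exp(Mt) = ((M - lam2 I) e^{lam1 t} - (M - lam1 I) e^{lam2 t}) / (lam1 - lam2)
  M <- matrix(c(m11, m21, m12, m22), 2, 2)
  w1 <- drop(cc %*% (M - diag(lam2, 2)) %*% b) / (lam1 - lam2)
  w2 <- -drop(cc %*% (M - diag(lam1, 2)) %*% b) / (lam1 - lam2)
  ct <- w1 * expconv_pl(lam1, tm, Ca$values) + w2 * expconv_pl(lam2, tm, Ca$values)
  conc_curve(t, ct)
}
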