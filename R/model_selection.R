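# AICc computation and Akaike weights for ranking the nested kinetic models.

#' Small-sample-corrected Akaike information criterion
#'
#' For a least-squares fit with residual sum of squares `ss` over `n` points
#' and `k` free model parameters,
#' \deqn{AIC = N \ln(SS/N) + 2(K+1), \qquad AICc = AIC + \frac{2K(K+1)}{N-K-1}.}
#' Under the default `"k_plus_one"` convention the additive constant counts
#' the residual variance as an estimated parameter (2(K+1)); the alternative
#' `"two_k_plus_one"` convention uses 2K + 1. The two differ by a constant
#' per extra parameter, which does shift the deltas between models of
#' different K, so the convention is explicit and configurable.
#'
#' @param ss Residual sum of squares (> 0).
#' @param n Number of residual-contributing data points.
#' @param k Number of free model parameters.
#' @param convention `"k_plus_one"` (default) or `"two_k_plus_one"`.
#' @return AICc value.
#' @export
aicc <- function(ss, n, k, convention = c("k_plus_one", "two_k_plus_one")) {
  convention <- match.arg(convention)
  if (!is_number(ss) || ss <= 0) dce_stop("ss must be > 0", "dce_invalid_input")
  if (!is_number(n) || !is_number(k)) dce_stop("n and k must be numbers", "dce_invalid_input")
  if (n <= k + 1) {
    dce_stop("need n > k + 1 for the small-sample correction", "dce_invalid_input")
  }
  const <- if (convention == "k_plus_one") 2 * (k + 1) else 2 * k + 1
  n * log(ss / n) + const + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#'
#' \eqn{AW_m = \exp(-\Delta_m/2) / \sum_i \exp(-\Delta_i/2)} with
#' \eqn{\Delta_m = AICc_m - \min_i AICc_i}: the probability that model `m`
#' is the best of the compared set.
#'
#' @param aicc_values Numeric vector (>= 2 finite values).
#' @return Weights in \[0, 1\] summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) < 2L || !all(is.finite(aicc_values))) {
    dce_stop("need >= 2 finite AICc values", "dce_invalid_input")
  }
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  w / sum(w)
}

MODEL_K <- c(steady_state = 1L, patlak = 2L, mtofts = 3L)

#' Rank fitted nested models by AICc
#'
#' Computes per-model AICc (free-parameter counts: steady-state 1, Patlak 2,
#' modified Tofts 3), deltas, Akaike weights and the best model. All fits
#' must come from the same data (identical residual point counts). Ties are
#' broken toward the model with fewer parameters.
#'
#' @param fits List of `dce_fit` objects (see [fit_model()]).
#' @param convention AICc constant convention, see [aicc()].
#' @return An object of class `model_comparison` with elements `models`,
#'   `aicc`, `delta`, `weights` and `best_model`.
#' @export
compare_models <- function(fits, convention = c("k_plus_one", "two_k_plus_one")) {
  convention <- match.arg(convention)
  if (!length(fits)) dce_stop("need at least one fit", "dce_invalid_input")
  models <- vapply(fits, function(f) f$model, character(1))
  if (anyDuplicated(models)) dce_stop("duplicate models in fits", "dce_invalid_input")
  ns <- vapply(fits, function(f) f$n_included, integer(1))
  if (length(unique(ns)) != 1L) {
    dce_stop("all fits must share the same number of residual points", "dce_invalid_input")
  }
  k <- MODEL_K[models]
  ic <- mapply(function(f, ki) aicc(f$ss, f$n_included, ki, convention),
               fits, k)
  if (length(fits) == 1L) {
    delta <- 0
    w <- 1
  } else {
    delta <- ic - min(ic)
    w <- akaike_weights(ic)
  }
  # argmin AICc; on ties prefer fewer parameters
  ord <- order(ic, k)
  structure(list(models = unname(models), k = unname(k),
                 aicc = unname(ic), delta = unname(delta),
                 weights = unname(w), best_model = unname(models[ord[1]]),
                 convention = convention),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  df <- data.frame(model = x$models, k = x$k,
                   AICc = round(x$aicc, 3), delta = round(x$delta, 3),
                   weight = round(x$weights, 4))
  print(df, row.names = FALSE)
  cat("best model:", x$best_model, "\n")
  invisible(x)
}
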