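# Internal helpers shared across modules.

dce_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "dcebbb_error")))
}

#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Cumulative trapezoidal integral of y over x, anchored so the
# integral at x[1] is (x[1] - 0) * y[1] / 2 when `from_zero` is TRUE,
# i.e. the curve is taken to be 0 for t < 0 and linear between samples.
cumtrapz_from_zero <- function(x, y) {
  if (x[1] > 0) {
    x <- c(0, x)
    y <- c(0, y)
    drop(pracma::cumtrapz(x, y))[-1]
  } else {
    drop(pracma::cumtrapz(x, y))
  }
}

# Evaluate a local RNG stream: runs `expr` with the given seed (if non-NULL)
# and restores the caller's RNG state afterwards, so seeded operations do not
# disturb the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is_number(seed)) dce_stop("seed must be a single finite number", "dce_invalid_parameter")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a reproducible child seed below 2^31 from a parent seed and an index.
child_seed <- function(seed, i) {
  (as.double(seed) * 48271 + i * 16807) %% 2147483647
}
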