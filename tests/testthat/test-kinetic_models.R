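# Forward tissue models: closed forms, nesting, and the 2CXM against an
# independent ODE oracle.

test_that("steady_state_ct is the intravascular scaling of the input", {
  Cp <- make_const_cp(2)
  expect_equal(steady_state_ct(const_grid, Cp, 0)$values,
               rep(0, length(const_grid)))
  expect_equal(steady_state_ct(const_grid, Cp, 1)$values, Cp$values)
  expect_equal(steady_state_ct(const_grid, Cp, 0.006)$values,
               rep(0.012, length(const_grid)))
})

test_that("patlak_ct matches the analytic constant-input solution exactly", {
  c0 <- 2; vp <- 0.006; KT <- 3e-4
  Cp <- make_const_cp(c0)
  ct <- patlak_ct(const_grid, Cp, vp, KT)
  expect_equal(ct$values, vp * c0 + KT * c0 * const_grid / 60,
               tolerance = 1e-12)
  # KTrans = 0 collapses to the steady-state model
  expect_equal(patlak_ct(const_grid, Cp, vp, 0)$values,
               steady_state_ct(const_grid, Cp, vp)$values)
})

test_that("patlak_ct agrees with adaptive-quadrature integration of the VIF", {
  p <- vif_params()
  fine <- make_fine_vif(dt = 0.1, t_end = 1200)
  ct <- patlak_ct(fine$times, fine, 0.006, 3e-4)
  # independent oracle: adaptive quadrature of the analytic VIF
  int20 <- stats::integrate(function(u) extended_parker_vif(u, p), 0, 20,
                            rel.tol = 1e-10, subdivisions = 2000L)$value
  expected <- 0.006 * extended_parker_vif(20, p) + 3e-4 * int20
  expect_equal(ct$values[length(ct$values)], expected, tolerance = 1e-3)
})

test_that("mtofts_ct matches the analytic constant-input solution", {
  c0 <- 2; vp <- 0.01; KT <- 0.01; ve <- 0.2
  Cp <- make_const_cp(c0)
  ct <- mtofts_ct(const_grid, Cp, vp, KT, ve)
  tm <- const_grid / 60
  expect_equal(ct$values, vp * c0 + ve * c0 * (1 - exp(-KT * tm / ve)),
               tolerance = 1e-9)
  expect_equal(mtofts_ct(const_grid, Cp, vp, 0, ve)$values,
               steady_state_ct(const_grid, Cp, vp)$values)
  expect_error(mtofts_ct(const_grid, Cp, vp, 0.1, 0),
               class = "dce_invalid_parameter")
})

test_that("mtofts_ct reduces to patlak_ct as kep * t -> 0", {
  # series expansion: the leakage term of the modified Tofts model falls
  # short of the Patlak term by a factor bounded to first order by
  # kep * t, with kep = KTrans/ve
  fine <- make_fine_vif(dt = 0.5)
  vp <- 0.006; ve <- 0.2
  deficit <- function(KT) {
    mt <- mtofts_ct(fine$times, fine, vp, KT, ve)$values
    pk <- patlak_ct(fine$times, fine, vp, KT)$values
    leak <- pk - vp * fine$values
    i <- leak > 1e-6
    max(abs(mt[i] - pk[i]) / leak[i])
  }
  d1 <- deficit(3e-4)
  expect_lt(d1, (3e-4 / ve) * max(fine$times) / 60)  # first-order bound
  expect_gt(d1, 0)
  # the deficit is first-order in KTrans: halving KTrans about halves it
  expect_equal(deficit(1.5e-4) / d1, 0.5, tolerance = 0.05)
  # and the modified Tofts curve never exceeds the Patlak curve
  mt <- mtofts_ct(fine$times, fine, vp, 3e-4, ve)$values
  pk <- patlak_ct(fine$times, fine, vp, 3e-4)$values
  expect_true(all(mt <= pk + 1e-15))
})

test_that("twocxm_ct matches the one-compartment closed form when PS = 0", {
  c0 <- 2
  Cp <- make_const_cp(c0)
  p <- tissue_params(Fp = 10, PS = 0, vp = 0.006, ve = 0.2)
  ct <- twocxm_ct(const_grid, Cp, p)
  tm <- const_grid / 60
  expect_equal(ct$values, 0.006 * c0 * (1 - exp(-0.1 * tm / 0.006)),
               tolerance = 1e-9)
})

test_that("twocxm_ct approaches the modified Tofts model at very high flow", {
  fine <- make_fine_vif(dt = 0.1)
  p <- tissue_params(Fp = 1e4, PS = 3e-4, vp = 0.006, ve = 0.2)
  tw <- twocxm_ct(fine$times, fine, p)$values
  mt <- mtofts_ct(fine$times, fine, 0.006, 3e-4, 0.2)$values
  i <- fine$times > 60
  expect_lt(max(abs(tw[i] - mt[i]) / pmax(mt[i], 1e-12)), 0.005)
})

test_that("twocxm_ct handles zero input and validates parameters", {
  t <- seq(0, 600, by = 1)
  zero <- conc_curve(t, rep(0, length(t)))
  p <- tissue_params()
  expect_equal(twocxm_ct(t, zero, p)$values, rep(0, length(t)))
  expect_error(twocxm_ct(t, zero, tissue_params(vp = 0)),
               class = "dce_invalid_parameter")
  fine <- make_fine_vif(dt = 1, t_end = 600)
  expect_true(all(twocxm_ct(fine$times, fine, p)$values >= 0))
})

test_that("analytic 2CXM convolution matches stiff ODE integration", {
  # independent oracle: deSolve integration of the mass-balance system
  t <- seq(0, 600, by = 1)
  fine <- make_fine_vif(dt = 1, t_end = 600)
  ca_fun <- stats::approxfun(t, fine$values, rule = 2)
  set.seed(42)
  worst <- 0
  for (i in 1:20) {
    p <- tissue_params(Fp = runif(1, 5, 50), PS = 10^runif(1, -4, -2),
                       vp = runif(1, 0.003, 0.05), ve = runif(1, 0.1, 0.4))
    Fp_min <- p$Fp / 100
    rhs <- function(tt, y, parms) {
      tmin <- tt  # integrate in minutes
      ca <- ca_fun(tmin * 60)
      dcap <- (Fp_min * (ca - y[1]) + p$PS * (y[2] - y[1])) / p$vp
      dce <- p$PS * (y[1] - y[2]) / p$ve
      list(c(dcap, dce))
    }
    sol <- deSolve::lsoda(c(0, 0), t / 60, rhs, NULL, rtol = 1e-8, atol = 1e-12)
    ct_ode <- p$vp * sol[, 2] + p$ve * sol[, 3]
    ct_ana <- twocxm_ct(t, fine, p)$values
    worst <- max(worst, max(abs(ct_ana - ct_ode)) / max(abs(ct_ode)))
  }
  expect_lt(worst, 1e-3)
})

test_that("tissue_params enforces physical ranges", {
  expect_error(tissue_params(Fp = 0), class = "dce_invalid_parameter")
  expect_error(tissue_params(PS = -1e-4), class = "dce_invalid_parameter")
  expect_error(tissue_params(vp = 0.5, ve = 0.6), class = "dce_invalid_parameter")
})
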