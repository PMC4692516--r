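# SPGR forward model, VFA/IR T1 estimation, enhancement <-> concentration.

test_that("spgr_signal basic properties and input validation", {
  acq <- default_acq
  expect_equal(spgr_signal(1.3, 0.969, 500, alpha = 0, acq = acq), 0)
  expect_equal(spgr_signal(0.7, 2.1, 500, alpha = 0, acq = acq), 0)
  # signal increases with concentration at C = 0 (r1 shortening dominates)
  h <- 1e-6
  dS <- (spgr_signal(h, 0.969, 1, acq = acq) -
           spgr_signal(-h, 0.969, 1, acq = acq)) / (2 * h)
  expect_gt(dS, 0)
  expect_error(spgr_signal(0, -1, 1, acq = acq), class = "dce_invalid_parameter")
  expect_error(spgr_signal(0, 1, 0, acq = acq), class = "dce_invalid_parameter")
})

test_that("vfa_t1 inverts the SPGR forward model across the T1 range", {
  acq <- default_acq
  for (T10 in c(0.3, 0.5, 0.68, 0.903, 0.969, 1.4, 2.0)) {
    S_a <- spgr_signal(0, T10, 750, acq$alpha_low, acq)
    S_b <- spgr_signal(0, T10, 750, acq$alpha_high, acq)
    expect_equal(vfa_t1(S_a, S_b, acq), T10, tolerance = 1e-9)
  }
})

test_that("vfa_t1 rejects non-physical signal ratios", {
  acq <- default_acq
  aa <- acq$alpha_low * pi / 180
  ab <- acq$alpha_high * pi / 180
  # infinite-T1 limit of the signal ratio: log argument reaches 1
  SR_inf <- sin(aa) * (1 - cos(ab)) / (sin(ab) * (1 - cos(aa)))
  expect_error(vfa_t1(SR_inf * 1.01 * 100, 100, acq),
               class = "dce_nonphysical_signal_ratio")
  expect_error(vfa_t1(100, -1, acq), class = "dce_invalid_parameter")
})

test_that("enhancement is the fractional change from baseline, unclipped", {
  sc <- signal_curve(c(73, 146, 219), c(100, 105, 98), baseline = 100)
  expect_equal(enhancement(sc), c(0, 0.05, -0.02))
  no_base <- signal_curve(c(1, 2), c(1, 2))
  expect_error(enhancement(no_base), class = "dce_invalid_parameter")
})

test_that("concentration_from_enhancement inverts the forward relation", {
  acq <- default_acq
  expect_equal(concentration_from_enhancement(0, 0.969, acq), 0,
               tolerance = 1e-8)
  E <- enhancement_from_concentration(0.5, 0.969, acq)
  expect_equal(concentration_from_enhancement(E, 0.969, acq), 0.5,
               tolerance = 1e-9)
  # negative enhancement continues the same monotone branch below zero
  Cneg <- concentration_from_enhancement(-0.005, 0.969, acq)
  expect_lt(Cneg, 0)
  expect_gt(Cneg, -0.05)
  expect_equal(enhancement_from_concentration(Cneg, 0.969, acq), -0.005,
               tolerance = 1e-9)
})

test_that("enhancement inversion round-trips over the invertible branch", {
  acq <- default_acq
  for (T10 in c(0.3, 0.5, 0.969, 1.4, 2.0)) {
    g <- seq(0, 20, by = 0.01)
    Eg <- enhancement_from_concentration(g, T10, acq)
    cpk <- g[which.max(Eg)]
    # relation must be strictly monotone below its peak
    below <- g < cpk
    expect_true(all(diff(Eg[below]) > 0))
    # stay on the physical branch: above the R1 = 0 pole at C = -1/(r1*T10),
    # below the saturation peak
    Cs <- seq(max(-0.2, -0.8 / (acq$r1 * T10)), min(4.2, 0.9 * cpk),
              length.out = 25)
    E <- enhancement_from_concentration(Cs, T10, acq)
    back <- concentration_from_enhancement(E, T10, acq)
    expect_lt(max(abs(back - Cs)), 1e-6)
  }
})

test_that("enhancement values beyond the saturation peak are rejected", {
  acq <- default_acq
  Emax <- max(enhancement_from_concentration(seq(0, 20, by = 0.01), 0.969, acq))
  expect_error(concentration_from_enhancement(Emax * 1.05, 0.969, acq),
               class = "dce_no_solution")
})

test_that("signal_to_concentration chains enhancement and inversion", {
  acq <- default_acq
  C_true <- c(0.02, 0.05, 0.04, 0.03)
  t <- c(73, 146, 219, 292)
  E <- enhancement_from_concentration(C_true, 0.969, acq)
  sc <- make_signal_from_enh(t, E, S0 = 480)
  cc <- signal_to_concentration(sc, 0.969, acq)
  expect_s3_class(cc, "conc_curve")
  expect_equal(cc$values, C_true, tolerance = 1e-7)
})

test_that("ir_t1_fit recovers the generating parameters exactly without noise", {
  TI <- c(100, 340, 580, 820, 1060, 1300, 2000, 3000) / 1000
  A <- 100; B <- -200; T1 <- 0.903
  SI <- A + B * exp(-TI / T1)
  fit <- ir_t1_fit(TI, SI)
  expect_equal(fit$A, A, tolerance = 1e-6)
  expect_equal(fit$B, B, tolerance = 1e-6)
  expect_equal(fit$T1, T1, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("ir_t1_fit flags degenerate flat input", {
  TI <- c(0.1, 0.34, 0.58, 0.82, 1.06, 1.3, 2, 3)
  expect_error(ir_t1_fit(TI, rep(42, length(TI))), class = "dce_fit_failure")
  expect_error(ir_t1_fit(c(0.1, 0.1, 0.2), c(1, 2, 3)),
               class = "dce_invalid_parameter")
})

test_that("ir_t1_fit is accurate under 1% noise (Monte Carlo)", {
  TI <- c(100, 340, 580, 820, 1060, 1300, 2000, 3000) / 1000
  A <- 100; B <- -200; T1 <- 0.903
  clean <- A + B * exp(-TI / T1)
  set.seed(11)
  t1s <- replicate(100, ir_t1_fit(TI, clean + rnorm(length(TI), 0, 1))$T1)
  expect_lt(abs(stats::median(t1s) / T1 - 1), 0.02)
})
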