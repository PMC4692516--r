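# Simulation engine: clean pairs, noise calibration, drift injection,
# experiment drivers.

test_that("simulate_clean_pair trivial and linearity properties", {
  cfg0 <- sim_config(tissue = tissue_params(PS = 0, vp = 1e-12, ve = 0.2))
  pair0 <- simulate_clean_pair(cfg0)
  expect_lt(max(abs(pair0$Ct$values)), 1e-10)

  cfg <- sim_config()
  pair <- simulate_clean_pair(cfg)
  expect_length(pair$Ct$values, 20)
  expect_equal(pair$Ct$times, seq_len(20) * 73)
  # doubling all VIF amplitudes doubles both outputs (linear system)
  p <- cfg$vif
  cfg2 <- sim_config(vif = vif_params(A1 = 2 * p$A1, A2 = 2 * p$A2,
                                      alpha1 = 2 * p$alpha1,
                                      alpha2 = 2 * p$alpha2))
  pair2 <- simulate_clean_pair(cfg2)
  expect_equal(pair2$Cp$values, 2 * pair$Cp$values, tolerance = 1e-10)
  expect_equal(pair2$Ct$values, 2 * pair$Ct$values, tolerance = 1e-10)
})

test_that("clean-pair Patlak fit returns KTrans close to the generating PS", {
  cfg <- sim_config()  # NAWM-like: Fp 10, PS 3e-4, vp 0.006, ve 0.2
  pair <- simulate_clean_pair(cfg)
  f <- fit_model(pair$Ct, pair$Cp, "patlak", fit_config(seed = 1))
  expect_lt(abs(f$params$KTrans / cfg$tissue$PS - 1), 0.10)
})

test_that("point down-sampling is available and loses first-pass mass", {
  cfg <- sim_config()
  avg <- simulate_clean_pair(cfg, downsample = "average")
  pnt <- simulate_clean_pair(cfg, downsample = "point")
  # the first averaged VIF frame contains the bolus, the point sample does not
  expect_gt(avg$Cp$values[1], pnt$Cp$values[1])
})

test_that("add_noise_to_cnr calibration closes the loop with estimate_cnr", {
  cfg <- sim_config()
  pair <- simulate_clean_pair(cfg)
  expect_identical(add_noise_to_cnr(pair$Ct, Inf), pair$Ct)
  n1 <- add_noise_to_cnr(pair$Ct, 8, seed = 1)
  n1b <- add_noise_to_cnr(pair$Ct, 8, seed = 1)
  n2 <- add_noise_to_cnr(pair$Ct, 8, seed = 2)
  expect_identical(n1$values, n1b$values)
  expect_false(identical(n1$values, n2$values))

  cnrs <- vapply(1:200, function(s) {
    Ctn <- add_noise_to_cnr(pair$Ct, 8, seed = s)
    estimate_cnr(Ctn, fit_model(Ctn, pair$Cp, "patlak", fit_config(seed = s)))
  }, numeric(1))
  expect_lt(abs(mean(cnrs) / 8 - 1), 0.15)
})

test_that("add_drift is the identity at zero drift and injects monotone error", {
  cfg <- sim_config()
  pair <- simulate_clean_pair(cfg)
  back <- add_drift(pair$Ct, 0, cfg$tissue$T10, cfg$acq)
  expect_lt(max(abs(back$values - pair$Ct$values)), 1e-9)
  # positive drift on a zero-concentration curve: strictly increasing
  zero <- conc_curve(pair$Ct$times, rep(0, 20))
  drifted <- add_drift(zero, 8e-4, cfg$tissue$T10, cfg$acq)
  expect_true(all(diff(drifted$values) > 0))
  expect_true(all(drifted$values > 0))
})

test_that("KTrans drift bias grows about linearly with the drift rate", {
  rates <- c(4e-4, 8e-4, 16e-4)
  bias <- vapply(rates, function(dr) {
    out <- run_drift_experiment(sim_config(n_reps = 40, seed = 21,
                                           drift_rate = dr))
    out$bias[["KTrans"]]
  }, numeric(1))
  expect_true(all(diff(bias) > 0))
  # linearity: doubling the rate about doubles the bias
  expect_equal(bias[2] / bias[1], 2, tolerance = 0.35)
  expect_equal(bias[3] / bias[2], 2, tolerance = 0.35)
})

test_that("experiment driver is deterministic and reports coherent summaries", {
  cfg <- sim_config(n_reps = 1, seed = 123, drift_rate = 8e-4)
  b1 <- run_drift_experiment(cfg)
  b2 <- run_drift_experiment(cfg)
  expect_identical(b1$estimates, b2$estimates)
  expect_identical(b1$n_reps, 1L)
  expect_equal(unname(b1$bias), unname(b1$mean - b1$truth))
})

test_that("KTrans underestimation grows with PS and is robust to flow", {
  ratio <- vapply(c(1e-4, 3e-4, 1e-3, 3e-3), function(ps) {
    cfg <- sim_config(tissue = tissue_params(PS = ps))
    pair <- simulate_clean_pair(cfg)
    f <- fit_model(pair$Ct, pair$Cp, "patlak", fit_config(seed = 1))
    f$params$KTrans / ps
  }, numeric(1))
  expect_true(all(diff(ratio) < 0))  # monotone growth of underestimation
  # flow robustness at low PS: Fp = 10 vs 50 ml/100 g/min
  kt <- vapply(c(10, 50), function(fp) {
    cfg <- sim_config(tissue = tissue_params(Fp = fp))
    pair <- simulate_clean_pair(cfg)
    fit_model(pair$Ct, pair$Cp, "patlak", fit_config(seed = 1))$params$KTrans
  }, numeric(1))
  expect_lt(abs(kt[2] - kt[1]) / 3e-4, 0.1)
})

test_that("volunteer_drift_rate recovers a constructed linear drift", {
  t <- seq(0, 1387, by = 73)
  sc <- signal_curve(t, 100 * (1 + 0.001 * t / 60))
  # slightly below 0.1: the denominator is the time-averaged (drifted)
  # signal, not the baseline
  expect_equal(volunteer_drift_rate(sc), 0.1, tolerance = 0.02)
  expect_equal(volunteer_drift_rate(signal_curve(t, rep(50, length(t)))), 0)
  down <- signal_curve(t, 100 * (1 - 0.002 * t / 60))
  expect_lt(volunteer_drift_rate(down), 0)
})
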