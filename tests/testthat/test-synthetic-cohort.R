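test_that("mechanistic simulation has the protocol's exact cell counts", {
  cfg <- protocol_config(seed = 11)
  sim <- simulate_mechanistic(cfg)
  expect_equal(nrow(sim$trials), 18 * 2 * 20 * 2 * 2 * 3)  # 8640
  expect_equal(nrow(sim$melatonin), 18 * 2 * 39)
  counts <- table(sim$trials$subject_id, sim$trials$cr)
  expect_true(all(counts == 20 * 2 * 2 * 3))
  expect_true(all(sim$trials$response_s > 0))
})

test_that("same seed gives identical synthetic tables", {
  cfg <- protocol_config(seed = 5, n_subjects = 3)
  s1 <- simulate_mechanistic(cfg)
  s2 <- simulate_mechanistic(cfg)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$melatonin, s2$melatonin)
  l1 <- simulate_from_lmm(cfg)
  l2 <- simulate_from_lmm(cfg)
  expect_identical(l1$occasions, l2$occasions)
})

test_that("noise-free unmodulated mechanistic responses equal their targets", {
  cfg <- protocol_config(seed = 2, n_subjects = 2)
  pop <- pacemaker_params(h_amp = 0, c_amp = 0, leak_kappa = 0)
  sim <- simulate_mechanistic(cfg, pop = pop, sd_h = 0, sd_c = 0, sd_phase = 0,
                              sdlog_by_cell = c(estimation.10 = 0,
                                                estimation.40 = 0,
                                                production.10 = 0,
                                                production.40 = 0))
  expect_equal(sim$trials$response_s, as.numeric(sim$trials$stimulus_s),
               tolerance = 1e-12)
})

test_that("model-based simulation with zero variability is the exact design surface", {
  cfg <- protocol_config(seed = 9, n_subjects = 2, sampling_interval_h = 19)
  beta0 <- c(100, rep(0, 14)); names(beta0) <- full_fixed_terms()
  sim0 <- simulate_from_lmm(cfg, beta = beta0, re_sd = c(0, 0, 0),
                            sigma_by_cell = c(estimation.10 = 0,
                                              estimation.40 = 0,
                                              production.10 = 0,
                                              production.40 = 0))
  expect_equal(sim0$occasions$ratio, rep(100, nrow(sim0$occasions)))

  # hand-computed X beta oracle on a nontrivial coefficient vector
  sim <- simulate_from_lmm(cfg, beta = reference_beta(), re_sd = c(0, 0, 0),
                           sigma_by_cell = c(estimation.10 = 0,
                                             estimation.40 = 0,
                                             production.10 = 0,
                                             production.40 = 0))
  expect_equal(sim$occasions$ratio,
               surface_by_hand(sim$occasions, reference_beta()),
               tolerance = 1e-12)
})

test_that("beta length is checked against the term order contract", {
  cfg <- protocol_config(seed = 1, n_subjects = 2)
  expect_error(simulate_from_lmm(cfg, beta = c(100, 0)), "length 15")
})

test_that("noiseless melatonin crosses 10 pg/ml upward exactly at the true DLMO", {
  cfg <- protocol_config()
  m <- simulate_melatonin(12.4, cfg, melatonin_params(sdlog = 0))
  # raw-curve crossing, independent of the cosinor machinery
  f <- stats::approxfun(m$time_h, m$conc_pgml - 10)
  root <- stats::uniroot(f, c(10, 14), tol = 1e-8)$root
  expect_equal(root, 12.4, tolerance = 0.02)
  expect_true(all(m$conc_pgml >= 2.8))
})

test_that("a flat sub-threshold profile yields an explicit no-DLMO result", {
  tt <- seq(0, 38, by = 1)
  conc <- 4 + 0.5 * cos(2 * pi * tt / 24)  # never reaches 10 pg/ml
  fit <- fit_composite_cosinor(tt, conc)
  d <- compute_dlmo(fit)
  expect_true(is.na(d))
  expect_identical(attr(d, "reason"), "no-upward-crossing")
})

test_that("mechanistic data fitted with the trajectory model shows opposing task trends", {
  cfg <- protocol_config(seed = 31)
  sim <- simulate_mechanistic(cfg, pop = pacemaker_params(h_amp = 0.15,
                                                          c_amp = 0.03,
                                                          leak_kappa = 0.01))
  occ <- aggregate_and_ratio(sim$trials)
  occ <- filter_outliers(occ)$kept
  occ <- align_to_dlmo(occ, estimate_dlmo_table(sim$melatonin))
  fit <- fit_trajectory_model(occ, method = "ML")
  # estimation (coded 0) rises with time awake: negative coefficient on the
  # decaying exponential; production is reciprocal, so the task interaction
  # flips the sign
  expect_lt(fit$beta[["exp"]], 0)
  expect_gt(fit$beta[["exp"]] + fit$beta[["task:exp"]], 0)
})
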