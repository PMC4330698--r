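test_that("the design matrix follows the documented coding and term order", {
  occ <- data.frame(subject_id = c("S01", "S01", "S02"),
                    cr = c("CR1", "CR2", "CR1"),
                    task = c("estimation", "production", "estimation"),
                    stimulus_s = c(10, 40, 10),
                    t_dlmo_h = c(0, 6, -2), ratio = 100)
  des <- build_design(occ)
  expect_equal(ncol(des$X), 15)
  expect_identical(colnames(des$X), full_fixed_terms())
  # (estimation, 10 s, CR1, t = 0): exp term e^0 = 1, cos = 1, all else 0
  expect_equal(unname(des$X[1, ]),
               c(1, 0, 0, 0, 1, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0))
  # t = 6 h: sin(pi/2) = 1
  expect_equal(unname(des$X[2, "sin"]), 1)
  expect_equal(unname(des$X[2, "exp"]), exp(-6 / 18.2))
  # production/40/CR2 row activates the factor columns
  expect_equal(unname(des$X[2, c("task", "stim", "cr", "task:stim")]),
               c(1, 1, 1, 1))
  expect_identical(colnames(des$Z), c("intercept", "task", "stim"))
  expect_error(build_design(transform(occ, task = "reproduction")),
               "unknown task")
})

test_that("noise-free data is interpolated with coefficients exact to 1e-6", {
  cfg <- protocol_config(seed = 9, n_subjects = 3, sampling_interval_h = 6)
  zero_sig <- c(estimation.10 = 0, estimation.40 = 0,
                production.10 = 0, production.40 = 0)
  sim <- simulate_from_lmm(cfg, re_sd = c(0, 0, 0), sigma_by_cell = zero_sig)
  fit <- fit_trajectory_model(sim$occasions)
  expect_true(fit$perfect_fit)
  expect_equal(unname(fit$beta), unname(reference_beta()), tolerance = 1e-6)
})

test_that("profiled likelihood equals a dense joint-Gaussian oracle", {
  sim <- small_cohort(seed = 6)
  occ <- sim$occasions
  expect_lte(nrow(occ), 200)
  spec <- timing_model_spec()
  des <- build_design(occ, spec)
  fit <- fit_lmm(des$X, des$Z, occ$ratio, des$subject, des$vargroup,
                 method = "ML", spec = spec)
  ll_dense <- dense_loglik(des$X, des$Z, occ$ratio, des$subject, des$vargroup,
                           fit$beta, fit$sigma, fit$re_cov,
                           fit$var_multipliers)
  expect_equal(fit$loglik, ll_dense, tolerance = 1e-6)
  # beta equals closed-form dense GLS at the fitted variance parameters
  beta_gls <- dense_gls(des$X, des$Z, occ$ratio, des$subject, des$vargroup,
                        fit$sigma, fit$re_cov, fit$var_multipliers)
  expect_equal(unname(fit$beta), unname(beta_gls), tolerance = 1e-6)
})

test_that("optimizer trace is monotone and the fit converges", {
  sim <- small_cohort(seed = 12)
  fit <- fit_trajectory_model(sim$occasions, method = "ML")
  expect_true(fit$converged)
  expect_true(all(diff(fit$deviance_trace) <= 0))
})

test_that("Wald table arithmetic follows the containment rule", {
  sim <- small_cohort(seed = 3, n_subjects = 5)
  fit <- fit_trajectory_model(sim$occasions, method = "ML")
  tab <- wald_table(fit)
  # all 15 terms vary within subjects: a single shared denominator df
  expect_equal(unique(tab$df), fit$n_obs - fit$n_subjects - 15)
  expect_equal(tab$t, tab$value / tab$se, tolerance = 1e-12)
  expect_equal(tab$p, 2 * pt(abs(tab$t), tab$df, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(all(fit$var_multipliers > 0))
  expect_equal(unname(fit$var_multipliers["estimation.10"]), 1)
  # random-effect covariance is symmetric positive definite
  expect_equal(fit$re_cov, t(fit$re_cov))
  expect_true(all(eigen(fit$re_cov, symmetric = TRUE)$values > 0))
})

test_that("amplitude/acrophase conversion matches the sinusoid identity", {
  expect_equal(amplitude_phase(0, 1),
               c(amplitude = 1, acrophase = 0))
  expect_equal(amplitude_phase(1, 0),
               c(amplitude = 1, acrophase = 6))
  # hand-computed: 2.64^2 + 0.92^2 = 7.816, sqrt = 2.7957112...
  ap <- amplitude_phase(2.64, -0.92)
  expect_equal(unname(ap["amplitude"]), 2.7957112, tolerance = 1e-6)
  # the converted form reproduces the original sinusoid pointwise
  tt <- seq(0, 48, by = 0.5)
  lhs <- ap["amplitude"] * cos(2 * pi / 24 * (tt - ap["acrophase"]))
  rhs <- 2.64 * sin(2 * pi * tt / 24) - 0.92 * cos(2 * pi * tt / 24)
  expect_equal(unname(lhs), rhs, tolerance = 1e-10)
})

test_that("homoscedastic random-intercept reduction matches nlme", {
  skip_if_not_installed("nlme")
  sim <- small_cohort(seed = 15, n_subjects = 6)
  occ <- sim$occasions
  spec0 <- timing_model_spec(variance_groups = "none")
  des <- build_design(occ, spec0)
  ours <- fit_lmm(des$X, des$Z[, "intercept", drop = FALSE], occ$ratio,
                  des$subject, NULL, method = "ML", spec = spec0)
  d <- data.frame(y = occ$ratio, subj = des$subject)
  d <- cbind(d, as.data.frame(des$X[, -1]))
  names(d) <- make.names(names(d))
  form <- stats::as.formula(paste("y ~", paste(make.names(colnames(des$X)[-1]),
                                               collapse = " + ")))
  ref <- nlme::lme(form, random = ~ 1 | subj, data = d, method = "ML")
  expect_equal(ours$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
  expect_equal(unname(ours$beta), unname(nlme::fixef(ref)), tolerance = 1e-4)
  expect_equal(unname(sqrt(ours$re_cov[1, 1])),
               as.numeric(nlme::VarCorr(ref)[1, 2]), tolerance = 1e-3)
})

test_that("the full heteroscedastic fit agrees with an nlme cross-check", {
  skip_if_not_installed("nlme")
  cfg <- protocol_config(seed = 7, n_subjects = 10)
  sim <- simulate_from_lmm(cfg)
  occ <- sim$occasions
  des <- build_design(occ)
  ours <- fit_trajectory_model(occ, method = "ML")
  d <- data.frame(y = occ$ratio, subj = des$subject, vg = des$vargroup)
  d <- cbind(d, as.data.frame(des$X[, -1]))
  names(d) <- make.names(names(d))
  form <- stats::as.formula(paste("y ~", paste(make.names(colnames(des$X)[-1]),
                                               collapse = " + ")))
  ref <- suppressWarnings(
    nlme::lme(form, random = ~ task + stim | subj,
              weights = nlme::varIdent(form = ~ 1 | vg), data = d,
              method = "ML",
              control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                         msMaxIter = 200)))
  # our optimum should be at least as good, and nearly identical
  expect_gte(ours$loglik, as.numeric(stats::logLik(ref)) - 1e-3)
  expect_lt(abs(ours$loglik - as.numeric(stats::logLik(ref))), 0.5)
  expect_equal(unname(ours$beta), unname(nlme::fixef(ref)), tolerance = 0.05)
})

test_that("REML deviance matches nlme's REML log-likelihood", {
  skip_if_not_installed("nlme")
  sim <- small_cohort(seed = 19, n_subjects = 6)
  occ <- sim$occasions
  spec0 <- timing_model_spec(variance_groups = "none")
  des <- build_design(occ, spec0)
  ours <- fit_lmm(des$X, des$Z[, "intercept", drop = FALSE], occ$ratio,
                  des$subject, NULL, method = "REML", spec = spec0)
  d <- data.frame(y = occ$ratio, subj = des$subject)
  d <- cbind(d, as.data.frame(des$X[, -1]))
  names(d) <- make.names(names(d))
  form <- stats::as.formula(paste("y ~", paste(make.names(colnames(des$X)[-1]),
                                               collapse = " + ")))
  ref <- nlme::lme(form, random = ~ 1 | subj, data = d, method = "REML")
  expect_equal(ours$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
})

test_that("predictions recover the population surface and subject trajectories", {
  beta0 <- c(100, rep(0, 14)); names(beta0) <- full_fixed_terms()
  cfg <- protocol_config(seed = 25, n_subjects = 3, sampling_interval_h = 6)
  zero_sig <- c(estimation.10 = 0, estimation.40 = 0,
                production.10 = 0, production.40 = 0)
  sim <- simulate_from_lmm(cfg, beta = beta0, re_sd = c(0, 0, 0),
                           sigma_by_cell = zero_sig)
  fit <- fit_trajectory_model(sim$occasions)
  expect_equal(predict(fit, sim$occasions, level = "population"),
               rep(100, nrow(sim$occasions)))

  # near-zero residual noise: subject-level predictions reproduce the data
  tiny_sig <- c(estimation.10 = 1e-3, estimation.40 = 1e-3,
                production.10 = 1e-3, production.40 = 1e-3)
  sim2 <- simulate_from_lmm(cfg, re_sd = c(10, 5, 5), sigma_by_cell = tiny_sig)
  fit2 <- fit_trajectory_model(sim2$occasions, method = "ML")
  pred2 <- predict(fit2, sim2$occasions, level = "subject")
  expect_lt(max(abs(pred2 - sim2$occasions$ratio)), 0.05)
  expect_error(predict(fit2, transform(sim2$occasions, subject_id = "S99"),
                       level = "subject"), "unknown subject")

  # under the default generating coefficients the two tasks have
  # opposite-signed wake-dependent trends; the task carrying the large
  # negative exponential interaction trends upward
  b <- reference_beta()
  dsurf <- function(task01, t) {
    e_coef <- b[["exp"]] + task01 * b[["task:exp"]]
    s_coef <- b[["sin"]] + task01 * b[["task:sin"]]
    c_coef <- b[["cos"]] + task01 * b[["task:cos"]]
    -e_coef / 18.2 * exp(-t / 18.2) +
      2 * pi / 24 * (s_coef * cos(2 * pi * t / 24) - c_coef * sin(2 * pi * t / 24))
  }
  # averaged over a circadian cycle, only the exponential trend survives
  ts <- seq(2, 26, by = 0.1)
  expect_gt(mean(dsurf(1, ts)), 0)
  expect_lt(mean(dsurf(0, ts)), 0)
})
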