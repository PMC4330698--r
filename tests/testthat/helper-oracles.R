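# Independent oracles and small fixtures shared across test files.

# Dense joint-Gaussian log-likelihood: builds each subject's full marginal
# covariance V_i = Z_i Psi Z_i' + sigma^2 diag(w_g^2) and evaluates the
# multivariate-normal log-density directly (dense Cholesky), independently of
# the Woodbury/cross-product path used by fit_lmm().
dense_loglik <- function(X, Z, y, subject, vargroup, beta, sigma, Psi,
                         var_multipliers) {
  ll <- 0
  for (s in unique(subject)) {
    idx <- subject == s
    Xi <- X[idx, , drop = FALSE]; Zi <- Z[idx, , drop = FALSE]
    yi <- y[idx]
    w <- var_multipliers[as.character(vargroup[idx])]
    Vi <- Zi %*% Psi %*% t(Zi) + diag(sigma^2 * w^2, length(yi))
    cV <- chol(Vi)
    ri <- yi - drop(Xi %*% beta)
    u <- forwardsolve(t(cV), ri)
    ll <- ll - 0.5 * (length(yi) * log(2 * pi) +
                        2 * sum(log(diag(cV))) + sum(u^2))
  }
  ll
}

# Dense generalized-least-squares solution at given variance parameters.
dense_gls <- function(X, Z, y, subject, vargroup, sigma, Psi,
                      var_multipliers) {
  A <- matrix(0, ncol(X), ncol(X)); b <- numeric(ncol(X))
  for (s in unique(subject)) {
    idx <- subject == s
    Xi <- X[idx, , drop = FALSE]; Zi <- Z[idx, , drop = FALSE]
    yi <- y[idx]
    w <- var_multipliers[as.character(vargroup[idx])]
    Vi <- Zi %*% Psi %*% t(Zi) + diag(sigma^2 * w^2, length(yi))
    Vinv <- solve(Vi)
    A <- A + t(Xi) %*% Vinv %*% Xi
    b <- b + t(Xi) %*% Vinv %*% yi
  }
  drop(solve(A, b))
}

# Row-by-row evaluation of the 15-term fixed-effect surface, coded
# independently of build_design(): every regressor is written out by hand.
surface_by_hand <- function(occ, beta, tau = 18.2, period = 24) {
  vapply(seq_len(nrow(occ)), function(i) {
    ta <- as.numeric(occ$task[i] == "production")
    stm <- as.numeric(occ$stimulus_s[i] == 40)
    cr <- as.numeric(occ$cr[i] == "CR2")
    t <- occ$t_dlmo_h[i]
    e <- exp(-t / tau); sn <- sin(2 * pi * t / period)
    cs <- cos(2 * pi * t / period)
    sum(beta * c(1, ta, stm, cr, e, sn, cs, ta * stm, ta * cr, ta * e,
                 ta * sn, ta * cs, stm * e, stm * sn, stm * cs))
  }, numeric(1))
}

# A small simulated cohort for engine tests (few subjects, coarse sampling).
small_cohort <- function(seed = 1, n_subjects = 4, sampling = 8,
                         re_sd = c(6, 3, 3),
                         sigma_by_cell = c(estimation.10 = 5,
                                           estimation.40 = 8,
                                           production.10 = 6,
                                           production.40 = 9)) {
  cfg <- protocol_config(n_subjects = n_subjects, n_crs = 2,
                         sampling_interval_h = sampling, seed = seed)
  simulate_from_lmm(cfg, re_sd = re_sd, sigma_by_cell = sigma_by_cell)
}
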