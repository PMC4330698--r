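#' Trajectory model specification
#'
#' Defines the fixed-effect terms, random-effect structure, residual variance
#' grouping and time-transform constants of the random-coefficient trajectory
#' model for response-to-target ratios. The full model has 15 fixed terms in a
#' fixed, documented order:
#'
#' `intercept, task, stim, cr, exp, sin, cos, task:stim, task:cr, task:exp,
#' task:sin, task:cos, stim:exp, stim:sin, stim:cos`
#'
#' where `exp` is the sleep-homeostatic regressor `exp(-t/tau_h)`, and `sin`,
#' `cos` are the circadian regressors `sin(2*pi*t/period)`,
#' `cos(2*pi*t/period)`, with `t` the time from DLMO in hours. Factors are
#' treatment-coded: task (estimation = 0, production = 1), stimulus
#' (10 s = 0, 40 s = 1), constant routine (CR1 = 0, CR2 = 1).
#'
#' @param fixed_terms Character vector of term names, a subset of the full
#'   15-term vocabulary above, always including `"intercept"`.
#' @param random_terms Random-effect columns per subject; any of
#'   `"intercept"`, `"task"`, `"stim"` (unstructured covariance).
#' @param variance_groups `"cell"` for one residual variance multiplier per
#'   task-by-stimulus cell (reference cell estimation/10 s fixed at 1),
#'   `"none"` for homoscedastic residuals.
#' @param tau_h Homeostatic time constant in hours (default 18.2).
#' @param period Circadian period in hours (default 24).
#' @return An object of class `timing_model_spec`.
#' @export
timing_model_spec <- function(fixed_terms = full_fixed_terms(),
                              random_terms = c("intercept", "task", "stim"),
                              variance_groups = c("cell", "none"),
                              tau_h = 18.2, period = 24) {
  variance_groups <- match.arg(variance_groups)
  bad <- setdiff(fixed_terms, full_fixed_terms())
  if (length(bad))
    stop("unknown fixed terms: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!"intercept" %in% fixed_terms)
    stop("'fixed_terms' must include the intercept", call. = FALSE)
  bad <- setdiff(random_terms, c("intercept", "task", "stim"))
  if (length(bad))
    stop("unknown random terms: ", paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(tau_h > 0, period > 0)
  # keep canonical ordering regardless of input order
  fixed_terms <- intersect(full_fixed_terms(), fixed_terms)
  random_terms <- intersect(c("intercept", "task", "stim"), random_terms)
  structure(list(fixed_terms = fixed_terms, random_terms = random_terms,
                 variance_groups = variance_groups,
                 tau_h = tau_h, period = period),
            class = "timing_model_spec")
}

#' Full fixed-term vocabulary, in canonical order
#' @return Character vector of the 15 term names.
#' @export
full_fixed_terms <- function() {
  c("intercept", "task", "stim", "cr", "exp", "sin", "cos",
    "task:stim", "task:cr", "task:exp", "task:sin", "task:cos",
    "stim:exp", "stim:sin", "stim:cos")
}

code_task <- function(task) {
  task <- as.character(task)
  bad <- setdiff(unique(task), c("estimation", "production"))
  if (length(bad)) stop("unknown task level(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  as.numeric(task == "production")
}

code_stim <- function(stimulus_s) {
  s <- as.numeric(as.character(stimulus_s))
  bad <- setdiff(unique(s), c(10, 40))
  if (length(bad)) stop("unknown stimulus level(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  as.numeric(s == 40)
}

code_cr <- function(cr) {
  cr <- as.character(cr)
  bad <- setdiff(unique(cr), c("CR1", "CR2"))
  if (length(bad)) stop("unknown CR level(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  as.numeric(cr == "CR2")
}

#' Build the fixed and random design matrices
#'
#' Expands an occasion-level table into the fixed-effect design matrix `X`
#' (one column per term of the spec, in canonical order), the per-subject
#' random-effect design `Z`, the subject grouping vector, and the residual
#' variance-group labels.
#'
#' @param occasions A data.frame with columns `subject_id`, `cr`, `task`,
#'   `stimulus_s`, `t_dlmo_h` (and usually `ratio`).
#' @param spec A [timing_model_spec()].
#' @return A list with elements `X`, `Z`, `subject`, `vargroup`, `terms`.
#' @export
build_design <- function(occasions, spec = timing_model_spec()) {
  stopifnot(inherits(spec, "timing_model_spec"))
  need <- c("subject_id", "cr", "task", "stimulus_s", "t_dlmo_h")
  miss <- setdiff(need, names(occasions))
  if (length(miss))
    stop("occasion table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  t <- as.numeric(occasions$t_dlmo_h)
  if (any(!is.finite(t))) stop("non-finite t_dlmo_h", call. = FALSE)
  base <- list(
    intercept = rep(1, nrow(occasions)),
    task = code_task(occasions$task),
    stim = code_stim(occasions$stimulus_s),
    cr = code_cr(occasions$cr),
    exp = exp(-t / spec$tau_h),
    sin = sin(2 * pi * t / spec$period),
    cos = cos(2 * pi * t / spec$period))
  col_for <- function(term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    Reduce(`*`, base[parts])
  }
  X <- vapply(spec$fixed_terms, col_for, numeric(nrow(occasions)))
  dimnames(X) <- list(NULL, spec$fixed_terms)
  Z <- vapply(spec$random_terms, col_for, numeric(nrow(occasions)))
  dimnames(Z) <- list(NULL, spec$random_terms)
  vargroup <- if (spec$variance_groups == "cell") {
    factor(paste(occasions$task, occasions$stimulus_s, sep = "."),
           levels = c("estimation.10", "estimation.40",
                      "production.10", "production.40"))
  } else {
    factor(rep("all", nrow(occasions)))
  }
  list(X = X, Z = Z, subject = as.character(occasions$subject_id),
       vargroup = vargroup, terms = spec$fixed_terms)
}

## ---- internal likelihood machinery -------------------------------------

# Lower-triangular log-Cholesky factor from unconstrained parameters:
# first q entries are log-diagonals, remaining q(q-1)/2 fill the strict lower
# triangle column-wise.
lambda_from_theta <- function(theta_chol, q) {
  L <- matrix(0, q, q)
  diag(L) <- exp(theta_chol[seq_len(q)])
  if (q > 1) L[lower.tri(L)] <- theta_chol[-seq_len(q)]
  L
}

# Per subject-by-group sufficient statistics; everything the profiled
# deviance needs, so each objective evaluation is O(#subjects * #groups * p^2)
# regardless of the number of observations.
lmm_suffstats <- function(X, Z, y, subject, vargroup) {
  subjects <- unique(subject)
  groups <- levels(vargroup)
  stats_list <- vector("list", length(subjects))
  names(stats_list) <- subjects
  for (s in subjects) {
    per_group <- vector("list", length(groups))
    names(per_group) <- groups
    for (g in groups) {
      idx <- which(subject == s & vargroup == g)
      if (!length(idx)) next
      Xi <- X[idx, , drop = FALSE]; Zi <- Z[idx, , drop = FALSE]
      yi <- y[idx]
      per_group[[g]] <- list(
        XtX = crossprod(Xi), ZtX = crossprod(Zi, Xi), ZtZ = crossprod(Zi),
        Xty = crossprod(Xi, yi)[, 1], Zty = crossprod(Zi, yi)[, 1],
        yty = sum(yi^2), n = length(idx))
    }
    stats_list[[s]] <- per_group[!vapply(per_group, is.null, logical(1))]
  }
  list(stats = stats_list, subjects = subjects, groups = groups,
       p = ncol(X), q = ncol(Z), n = length(y))
}

# Profiled quantities at variance parameters theta.
# Returns accumulated A = X'V0^-1 X, c = X'V0^-1 y, s = y'V0^-1 y and
# logdet = sum_i log|V0_i|, where V = sigma^2 * V0.
lmm_profile <- function(theta, ss) {
  q <- ss$q; G <- length(ss$groups); p <- ss$p
  n_chol <- q * (q + 1) / 2
  L <- lambda_from_theta(theta[seq_len(n_chol)], q)
  w2 <- c(1, exp(2 * theta[n_chol + seq_len(G - 1)]))
  names(w2) <- ss$groups
  a <- 1 / w2
  A <- matrix(0, p, p); cc <- numeric(p); sq <- 0; logdet <- 0
  Iq <- diag(q)
  for (st in ss$stats) {
    XtWX <- matrix(0, p, p); ZtWX <- matrix(0, q, p); ZtWZ <- matrix(0, q, q)
    XtWy <- numeric(p); ZtWy <- numeric(q); ytWy <- 0
    for (g in names(st)) {
      ag <- a[[g]]; cell <- st[[g]]
      XtWX <- XtWX + ag * cell$XtX
      ZtWX <- ZtWX + ag * cell$ZtX
      ZtWZ <- ZtWZ + ag * cell$ZtZ
      XtWy <- XtWy + ag * cell$Xty
      ZtWy <- ZtWy + ag * cell$Zty
      ytWy <- ytWy + ag * cell$yty
      logdet <- logdet + cell$n * log(w2[[g]])
    }
    M <- Iq + crossprod(L, ZtWZ %*% L)
    cM <- chol(M)
    B <- crossprod(L, ZtWX)          # q x p
    bz <- crossprod(L, ZtWy)[, 1]    # q
    MiB <- backsolve(cM, forwardsolve(t(cM), B))
    Mib <- backsolve(cM, forwardsolve(t(cM), bz))
    A <- A + XtWX - crossprod(B, MiB)
    cc <- cc + XtWy - crossprod(B, Mib)[, 1]
    sq <- sq + ytWy - sum(bz * Mib)
    logdet <- logdet + 2 * sum(log(diag(cM)))
  }
  list(A = A, c = cc, s = sq, logdet = logdet, L = L, w2 = w2)
}

lmm_deviance <- function(theta, ss, method) {
  pr <- lmm_profile(theta, ss)
  cA <- tryCatch(chol(pr$A), error = function(e) NULL)
  if (is.null(cA)) return(1e10)
  beta <- backsolve(cA, forwardsolve(t(cA), pr$c))
  rss0 <- max(pr$s - sum(pr$c * beta), 1e-300)
  n <- ss$n; p <- ss$p
  if (method == "ML") {
    n * log(2 * pi * rss0 / n) + pr$logdet + n
  } else {
    (n - p) * log(2 * pi * rss0 / (n - p)) + pr$logdet +
      2 * sum(log(diag(cA))) + (n - p)
  }
}

#' Fit the heteroscedastic random-coefficient model
#'
#' Maximum-likelihood (or REML) estimation of the linear mixed model
#' \deqn{y_{ij} = x_{ij}'\beta + z_{ij}' b_i + \epsilon_{ij},\quad
#'       b_i \sim N(0, \Psi),\quad
#'       \epsilon_{ij} \sim N(0, \sigma^2 w^2_{g(ij)})}
#' with an unstructured random-effect covariance \eqn{\Psi} (log-Cholesky
#' parameterised, relative to \eqn{\sigma}) and one residual variance
#' multiplier per variance group, the reference group fixed at 1. \eqn{\beta}
#' and \eqn{\sigma^2} are profiled out of the marginal Gaussian likelihood by
#' generalised least squares; the remaining variance parameters are optimised
#' by quasi-Newton iteration from several documented starting points, using
#' a Woodbury decomposition of each subject's marginal covariance so that one
#' objective evaluation costs O(subjects x groups x terms^2).
#'
#' @param X Fixed-effect design matrix (full column rank).
#' @param Z Random-effect design matrix (columns per random term).
#' @param y Response vector.
#' @param subject Subject identifier per row (>= 2 distinct values).
#' @param vargroup Factor of residual variance groups per row, or `NULL` for
#'   homoscedastic residuals. The first level is the reference (multiplier 1).
#' @param method `"ML"` or `"REML"`.
#' @param spec Optional [timing_model_spec()] recorded for prediction.
#' @param starts Optional list of numeric starting vectors for the variance
#'   parameters (log-Cholesky entries, then log residual-SD multipliers).
#' @param control Passed to [stats::nlminb()]; defaults to a 1e-8 relative
#'   tolerance.
#' @return An object of class `lmm_fit`; see [wald_table()] and
#'   [predict.lmm_fit()].
#' @export
fit_lmm <- function(X, Z, y, subject, vargroup = NULL,
                    method = c("ML", "REML"), spec = NULL,
                    starts = NULL, control = list(rel.tol = 1e-8)) {
  method <- match.arg(method)
  X <- as.matrix(X); Z <- as.matrix(Z); y <- as.numeric(y)
  subject <- as.character(subject)
  n <- length(y); p <- ncol(X); q <- ncol(Z)
  stopifnot(nrow(X) == n, nrow(Z) == n, length(subject) == n)
  if (length(unique(subject)) < 2)
    stop("need at least 2 subjects", call. = FALSE)
  if (qr(X)$rank < p) stop("fixed-effect design is rank deficient", call. = FALSE)
  if (is.null(vargroup)) vargroup <- factor(rep("all", n))
  vargroup <- droplevels(as.factor(vargroup))
  G <- nlevels(vargroup)

  # perfect-fit short circuit: y exactly in the column span of X
  ols <- qr.solve(X, y)
  if (sum((y - X %*% ols)^2) <= 1e-16 * max(1, sum(y^2))) {
    beta <- ols; names(beta) <- colnames(X)
    fit <- structure(list(
      beta = beta, se = rep(0, p), df = rep(NA_real_, p),
      t_stat = rep(NA_real_, p), p_value = rep(NA_real_, p),
      re_cov = matrix(0, q, q, dimnames = list(colnames(Z), colnames(Z))),
      sigma = 0, var_multipliers = stats::setNames(rep(1, G), levels(vargroup)),
      loglik = NA_real_, deviance = NA_real_, n_obs = n,
      n_subjects = length(unique(subject)), n_params = p + 1,
      converged = TRUE, perfect_fit = TRUE, method = method,
      theta = NULL, terms = colnames(X), spec = spec,
      blups = NULL, vcov_beta = matrix(0, p, p),
      deviance_trace = numeric(0)), class = "lmm_fit")
    return(fit)
  }

  ss <- lmm_suffstats(X, Z, y, subject, vargroup)
  n_theta <- q * (q + 1) / 2 + (G - 1)
  if (is.null(starts)) {
    # documented defaults: unit-scale, small, and large relative RE SDs
    starts <- list(rep(0, n_theta),
                   c(rep(log(0.2), q), rep(0, n_theta - q)),
                   c(rep(log(2), q), rep(0, n_theta - q)))
  }
  trace_env <- new.env(); trace_env$vals <- numeric(0)
  obj <- function(th) {
    d <- lmm_deviance(th, ss, method)
    trace_env$vals <- c(trace_env$vals, d)
    d
  }
  best <- NULL
  for (st in starts) {
    opt <- stats::nlminb(st, obj, control = control)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  theta <- best$par
  pr <- lmm_profile(theta, ss)
  cA <- chol(pr$A)
  beta <- backsolve(cA, forwardsolve(t(cA), pr$c))
  rss0 <- max(pr$s - sum(pr$c * beta), 0)
  sigma2 <- rss0 / if (method == "ML") n else (n - p)
  Ainv <- chol2inv(cA)
  vcov_beta <- sigma2 * Ainv
  se <- sqrt(pmax(diag(vcov_beta), 0))
  names(beta) <- colnames(X); names(se) <- colnames(X)
  Psi <- sigma2 * tcrossprod(pr$L)
  dimnames(Psi) <- list(colnames(Z), colnames(Z))
  loglik <- -best$objective / 2

  # containment denominator df: count fixed terms that vary within subjects
  varies_within <- vapply(seq_len(p), function(j) {
    any(tapply(X[, j], subject, function(v) length(unique(v)) > 1))
  }, logical(1))
  # intercept column (constant 1) counts toward the within-subject total
  p_within <- sum(varies_within) + sum(!varies_within & colnames(X) == "intercept")
  n_subj <- length(unique(subject))
  df_within <- n - n_subj - p_within
  df <- ifelse(varies_within | colnames(X) == "intercept",
               df_within, max(n_subj - sum(!varies_within), 1))
  t_stat <- beta / se
  p_value <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)

  # empirical BLUPs: b_i = Psi Z_i' V_i^-1 (y_i - X_i beta) = L L' Z'V0^-1 r
  blups <- matrix(NA_real_, n_subj, q,
                  dimnames = list(unique(subject), colnames(Z)))
  a <- 1 / pr$w2
  for (s in rownames(blups)) {
    st <- ss$stats[[s]]
    ZtWr <- numeric(q); ZtWZ <- matrix(0, q, q)
    for (g in names(st)) {
      cell <- st[[g]]
      ZtWr <- ZtWr + a[[g]] * (cell$Zty - cell$ZtX %*% beta)[, 1]
      ZtWZ <- ZtWZ + a[[g]] * cell$ZtZ
    }
    M <- diag(q) + crossprod(pr$L, ZtWZ %*% pr$L)
    ZtVr <- ZtWr - (ZtWZ %*% pr$L) %*% solve(M, crossprod(pr$L, ZtWr))
    blups[s, ] <- (tcrossprod(pr$L) %*% ZtVr)[, 1]
  }

  structure(list(
    beta = beta, se = se, df = df, t_stat = t_stat, p_value = p_value,
    re_cov = Psi, sigma = sqrt(sigma2),
    var_multipliers = stats::setNames(sqrt(pr$w2), levels(vargroup)),
    loglik = loglik, deviance = best$objective, n_obs = n,
    n_subjects = n_subj, n_params = p + n_theta + 1,
    converged = best$convergence == 0, perfect_fit = FALSE,
    convergence_message = best$message, method = method,
    theta = theta, terms = colnames(X), spec = spec,
    blups = blups, vcov_beta = vcov_beta,
    deviance_trace = cummin(trace_env$vals)), class = "lmm_fit")
}

#' Fit the trajectory model to an occasion table
#'
#' Convenience wrapper: builds the design with [build_design()] and fits it
#' with [fit_lmm()].
#'
#' @inheritParams build_design
#' @inheritParams fit_lmm
#' @param ... Passed on to [fit_lmm()].
#' @return An `lmm_fit` object.
#' @export
fit_trajectory_model <- function(occasions, spec = timing_model_spec(),
                                 method = c("ML", "REML"), ...) {
  method <- match.arg(method)
  des <- build_design(occasions, spec)
  fit <- fit_lmm(des$X, des$Z, occasions$ratio, des$subject, des$vargroup,
                 method = method, spec = spec, ...)
  fit
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-coefficient trajectory model (", x$method, ")\n", sep = "")
  cat("  observations:", x$n_obs, " subjects:", x$n_subjects, "\n")
  if (!is.na(x$loglik)) cat("  log-likelihood:", format(x$loglik), "\n")
  cat("  residual SD:", format(x$sigma), "\n")
  if (length(x$var_multipliers) > 1) {
    cat("  residual SD multipliers:\n")
    print(round(x$var_multipliers, 4))
  }
  cat("\nFixed effects:\n")
  print(wald_table(x), digits = 4)
  invisible(x)
}

#' Wald table of fixed effects
#'
#' Per-term estimate, standard error (from the GLS covariance of the
#' coefficients), containment denominator degrees of freedom, t statistic and
#' two-sided p value.
#'
#' @param fit An `lmm_fit` object.
#' @return A data.frame with columns `term`, `value`, `se`, `df`, `t`, `p`.
#' @export
wald_table <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  data.frame(term = fit$terms, value = unname(fit$beta), se = unname(fit$se),
             df = unname(fit$df), t = unname(fit$t_stat),
             p = unname(fit$p_value), row.names = NULL)
}

#' Amplitude and acrophase from sine/cosine coefficients
#'
#' Converts the coefficients of `sin(2*pi*t/period)` and `cos(2*pi*t/period)`
#' to the amplitude/acrophase form `A * cos(2*pi/period * (t - P))` using
#' `A = sqrt(s^2 + c^2)` and `P = period/(2*pi) * atan2(s, c)` reduced to
#' `[0, period)`.
#'
#' @param s_coef Coefficient of the sine term.
#' @param c_coef Coefficient of the cosine term.
#' @param period Period in hours (default 24).
#' @return A named numeric vector `c(amplitude, acrophase)`.
#' @export
amplitude_phase <- function(s_coef, c_coef, period = 24) {
  amp <- sqrt(s_coef^2 + c_coef^2)
  phase <- (period / (2 * pi)) * atan2(s_coef, c_coef)
  phase <- phase %% period
  c(amplitude = amp, acrophase = phase)
}

#' Predictions from a fitted trajectory model
#'
#' Population-level predictions are the fixed-effect surface `X %*% beta`;
#' subject-level predictions add each subject's empirical best linear
#' unbiased predictors of the random effects.
#'
#' @param object An `lmm_fit` fitted via [fit_trajectory_model()] (so that the
#'   model spec is stored).
#' @param newdata An occasion-level data.frame (see [build_design()]).
#' @param level `"population"` or `"subject"`.
#' @param ... Unused.
#' @return Numeric vector of predicted ratios.
#' @export
predict.lmm_fit <- function(object, newdata,
                            level = c("population", "subject"), ...) {
  level <- match.arg(level)
  if (is.null(object$spec))
    stop("fit carries no model spec; refit via fit_trajectory_model()",
         call. = FALSE)
  des <- build_design(newdata, object$spec)
  pred <- drop(des$X %*% object$beta)
  if (level == "subject") {
    if (is.null(object$blups))
      stop("no random-effect predictions available for a perfect fit",
           call. = FALSE)
    unknown <- setdiff(unique(des$subject), rownames(object$blups))
    if (length(unknown))
      stop("unknown subject(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    pred <- pred + rowSums(des$Z * object$blups[des$subject, , drop = FALSE])
  }
  pred
}

#' Model degrees of freedom and information criteria
#' @param fit An `lmm_fit`.
#' @return AIC value (`-2 logLik + 2 k`, k = fixed + variance parameters).
#' @export
aic_lmm <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  fit$deviance + 2 * fit$n_params
}
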