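#' The ladder of candidate trajectory models
#'
#' Named reduced versions of the full 15-term model, each expressing an
#' alternative hypothesis about the shape of the timing trajectory:
#' * `constant` — no change across time (factors and their interactions only);
#' * `sinusoid_only` — circadian oscillation, no wake-dependent trend;
#' * `exponential_only` — saturating wake-dependent trend, no oscillation;
#' * `sin_exp` — oscillation plus trend, identical across tasks and stimuli;
#' * `equal_exponentials` — the full model minus the stimulus-by-exponential
#'    interaction (one shared wake-dependent trend across target durations);
#' * `full` — all 15 terms.
#'
#' The random-effect structure and residual variance grouping are held fixed
#' across candidates; only fixed effects differ, so ML likelihood-ratio tests
#' of the recorded nestings are valid.
#'
#' @param variance_groups Passed to each [timing_model_spec()].
#' @return Named list with `specs` (list of `timing_model_spec`) and
#'   `nestings` (data.frame of reduced/full pairs).
#' @export
candidate_specs <- function(variance_groups = "cell") {
  base <- c("intercept", "task", "stim", "cr", "task:stim", "task:cr")
  sinus <- c("sin", "cos", "task:sin", "task:cos", "stim:sin", "stim:cos")
  expo <- c("exp", "task:exp", "stim:exp")
  mk <- function(terms) timing_model_spec(fixed_terms = terms,
                                          variance_groups = variance_groups)
  specs <- list(
    constant = mk(base),
    sinusoid_only = mk(c(base, sinus)),
    exponential_only = mk(c(base, expo)),
    sin_exp = mk(c(base, "exp", "sin", "cos")),
    equal_exponentials = mk(setdiff(full_fixed_terms(), "stim:exp")),
    full = mk(full_fixed_terms()))
  nestings <- data.frame(
    reduced = c("constant", "constant", "constant", "constant", "constant",
                "sinusoid_only", "exponential_only", "sin_exp", "sin_exp",
                "equal_exponentials"),
    full = c("sinusoid_only", "exponential_only", "sin_exp",
             "equal_exponentials", "full",
             "full", "full", "full", "equal_exponentials", "full"),
    stringsAsFactors = FALSE)
  list(specs = specs, nestings = nestings)
}

#' Likelihood-ratio test between nested ML fits
#'
#' `statistic = 2 * (logLik(full) - logLik(reduced))`, degrees of freedom the
#' difference in parameter counts, p value from the chi-square distribution.
#' Both fits must be ML fits of nested fixed-effect specifications on the
#' same data.
#'
#' @param fit_reduced,fit_full `lmm_fit` objects fitted by ML.
#' @return A list with `statistic`, `df`, `p`.
#' @export
lrt <- function(fit_reduced, fit_full) {
  stopifnot(inherits(fit_reduced, "lmm_fit"), inherits(fit_full, "lmm_fit"))
  if (fit_reduced$method != "ML" || fit_full$method != "ML")
    stop("likelihood-ratio tests require ML fits", call. = FALSE)
  if (fit_reduced$n_obs != fit_full$n_obs)
    stop("fits are not on identical data", call. = FALSE)
  if (!all(fit_reduced$terms %in% fit_full$terms))
    stop("models are not nested (reduced terms not a subset)", call. = FALSE)
  stat <- 2 * (fit_full$loglik - fit_reduced$loglik)
  df <- fit_full$n_params - fit_reduced$n_params
  if (df <= 0) {
    if (identical(sort(fit_reduced$terms), sort(fit_full$terms)))
      return(list(statistic = max(stat, 0), df = 0, p = 1))
    stop("parameter counts do not increase from reduced to full", call. = FALSE)
  }
  if (stat < -1e-6)
    warning("negative LRT statistic beyond tolerance (", format(stat),
            "); the full model may not have converged")
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Fit and compare the candidate ladder
#'
#' Fits every candidate of [candidate_specs()] by ML on the same occasion
#' table and reports log-likelihood, parameter count and AIC per candidate
#' plus likelihood-ratio tests for every recorded nesting. Candidates that
#' fail to converge are reported but excluded from the ranking.
#'
#' @param occasions Preprocessed occasion table (with `t_dlmo_h`).
#' @param candidates Output of [candidate_specs()].
#' @return A list with `fits`, `table` (one row per candidate, AIC-ranked)
#'   and `tests` (one row per nesting).
#' @export
compare_ladder <- function(occasions, candidates = candidate_specs()) {
  fits <- lapply(candidates$specs, function(sp) {
    tryCatch(fit_trajectory_model(occasions, sp, method = "ML"),
             error = function(e) e)
  })
  ok <- vapply(fits, inherits, logical(1), what = "lmm_fit") &
    vapply(fits, function(f) isTRUE(f$converged), logical(1))
  tab <- data.frame(
    model = names(fits),
    converged = ok,
    n_params = vapply(fits, function(f)
      if (inherits(f, "lmm_fit")) f$n_params else NA_real_, numeric(1)),
    loglik = vapply(fits, function(f)
      if (inherits(f, "lmm_fit")) f$loglik else NA_real_, numeric(1)),
    stringsAsFactors = FALSE)
  tab$aic <- -2 * tab$loglik + 2 * tab$n_params
  tab <- tab[order(!tab$converged, tab$aic), ]
  rownames(tab) <- NULL
  tests <- candidates$nestings
  res <- lapply(seq_len(nrow(tests)), function(i) {
    r <- tests$reduced[i]; f <- tests$full[i]
    if (!ok[[r]] || !ok[[f]]) return(c(NA_real_, NA_real_, NA_real_))
    lt <- lrt(fits[[r]], fits[[f]])
    c(lt$statistic, lt$df, lt$p)
  })
  res <- do.call(rbind, res)
  tests$statistic <- res[, 1]; tests$df <- res[, 2]; tests$p <- res[, 3]
  list(fits = fits, table = tab, tests = tests)
}
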