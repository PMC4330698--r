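#' Constant-routine protocol configuration
#'
#' Geometry of the simulated study: a cohort of subjects measured across two
#' constant-routine (CR) epochs of sustained wakefulness, with interval-timing
#' sessions every 2 h and hourly melatonin sampling. Defaults reproduce the
#' reference protocol: 18 subjects, two 38.67-h CRs, 20 two-hourly timing
#' occasions per CR (t = 0, 2, ..., 38 h after CR start), both tasks
#' (estimation, production) at both targets (10 s, 40 s), three trials per
#' task-by-stimulus cell per occasion.
#'
#' @param n_subjects Number of subjects (default 18).
#' @param n_crs Number of constant-routine epochs (default 2).
#' @param cr_length_h CR length in hours (default 38.67).
#' @param sampling_interval_h Hours between timing occasions (default 2).
#' @param melatonin_interval_h Hours between melatonin samples (default 1).
#' @param stimuli_s Target durations in seconds (default c(10, 40)).
#' @param tasks Task names (default estimation, production).
#' @param trials_per_cell Trials per task-by-stimulus cell per occasion
#'   (default 3).
#' @param dlmo_mean_h Population mean DLMO, in hours after CR start
#'   (default 12.4, i.e. late evening for a morning CR start).
#' @param dlmo_sd_between_h Between-subject SD of DLMO (hours).
#' @param dlmo_sd_within_h Epoch-to-epoch SD of a subject's DLMO (hours).
#' @param seed Integer seed used by the simulators; `NULL` leaves the RNG
#'   state untouched.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(n_subjects = 18, n_crs = 2, cr_length_h = 38.67,
                            sampling_interval_h = 2, melatonin_interval_h = 1,
                            stimuli_s = c(10, 40),
                            tasks = c("estimation", "production"),
                            trials_per_cell = 3,
                            dlmo_mean_h = 12.4, dlmo_sd_between_h = 0.75,
                            dlmo_sd_within_h = 0.3, seed = NULL) {
  stopifnot(n_subjects >= 1, n_crs >= 1, trials_per_cell >= 1,
            cr_length_h > sampling_interval_h, sampling_interval_h > 0,
            melatonin_interval_h > 0)
  structure(list(n_subjects = n_subjects, n_crs = n_crs,
                 cr_length_h = cr_length_h,
                 sampling_interval_h = sampling_interval_h,
                 melatonin_interval_h = melatonin_interval_h,
                 stimuli_s = stimuli_s, tasks = tasks,
                 trials_per_cell = trials_per_cell,
                 dlmo_mean_h = dlmo_mean_h,
                 dlmo_sd_between_h = dlmo_sd_between_h,
                 dlmo_sd_within_h = dlmo_sd_within_h,
                 seed = seed), class = "protocol_config")
}

occasion_times <- function(cfg) {
  seq(0, cfg$cr_length_h, by = cfg$sampling_interval_h)
}

melatonin_times <- function(cfg) {
  seq(0, cfg$cr_length_h, by = cfg$melatonin_interval_h)
}

cr_labels <- function(cfg) paste0("CR", seq_len(cfg$n_crs))

subject_ids <- function(cfg) sprintf("S%02d", seq_len(cfg$n_subjects))

draw_dlmo_table <- function(cfg) {
  ids <- subject_ids(cfg)
  subj_mean <- cfg$dlmo_mean_h + stats::rnorm(cfg$n_subjects, 0, cfg$dlmo_sd_between_h)
  out <- expand.grid(subject_id = ids, cr = cr_labels(cfg),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$cr), , drop = FALSE]
  out$dlmo_h <- subj_mean[match(out$subject_id, ids)] +
    stats::rnorm(nrow(out), 0, cfg$dlmo_sd_within_h)
  rownames(out) <- NULL
  out
}

#' Melatonin profile parameters
#'
#' Shape of the simulated plasma melatonin rhythm: a 24-h cosine with mesor
#' `mesor`, amplitude `amplitude` and peak 6 h after DLMO, so that the rising
#' limb crosses 10 pg/ml exactly at the true DLMO. Multiplicative lognormal
#' noise with log-SD `sdlog`; concentrations are floored at the assay
#' sensitivity (2.8 pg/ml). The default amplitude keeps the noiseless curve
#' above the floor, so the floor acts only as a guard under noise.
#'
#' @param mesor Rhythm-adjusted mean (pg/ml).
#' @param amplitude 24-h amplitude (pg/ml); `mesor - amplitude` should stay
#'   at or above `floor_pgml` if an exactly sinusoidal noiseless profile is
#'   wanted.
#' @param peak_offset_h Hours after DLMO at which melatonin peaks (default 6;
#'   with `mesor = 10` this puts the upward 10 pg/ml crossing at DLMO).
#' @param sdlog Log-SD of the multiplicative noise (default 0.03, in the
#'   few-percent range typical of radioimmunoassay replicates, and small
#'   enough that the cosinor threshold crossing recovers the true DLMO
#'   within the generator's stated 0.25 h contract).
#' @param floor_pgml Assay sensitivity floor (default 2.8 pg/ml).
#' @return An object of class `melatonin_params`.
#' @export
melatonin_params <- function(mesor = 10, amplitude = 7, peak_offset_h = 6,
                             sdlog = 0.03, floor_pgml = 2.8) {
  stopifnot(mesor > 0, amplitude > 0, sdlog >= 0, floor_pgml >= 0)
  structure(list(mesor = mesor, amplitude = amplitude,
                 peak_offset_h = peak_offset_h, sdlog = sdlog,
                 floor_pgml = floor_pgml), class = "melatonin_params")
}

#' Simulate one melatonin series
#'
#' Hourly melatonin concentrations across one constant routine for one
#' subject-epoch with known DLMO.
#'
#' @param dlmo_h True DLMO, in hours after CR start (same time base as the
#'   returned `time_h`).
#' @param cfg A [protocol_config()].
#' @param mel A [melatonin_params()].
#' @return A data.frame with columns `time_h` and `conc_pgml`.
#' @export
simulate_melatonin <- function(dlmo_h, cfg = protocol_config(),
                               mel = melatonin_params()) {
  tt <- melatonin_times(cfg)
  if (dlmo_h < min(tt) || dlmo_h > max(tt))
    warning("true DLMO lies outside the sampled window")
  curve <- mel$mesor +
    mel$amplitude * cos(2 * pi * (tt - (dlmo_h + mel$peak_offset_h)) / 24)
  conc <- curve * if (mel$sdlog > 0) exp(stats::rnorm(length(tt), 0, mel$sdlog)) else 1
  conc <- pmax(conc, mel$floor_pgml)
  data.frame(time_h = tt, conc_pgml = conc)
}

occasion_grid <- function(cfg) {
  g <- expand.grid(trial_index = seq_len(cfg$trials_per_cell),
                   stimulus_s = cfg$stimuli_s, task = cfg$tasks,
                   occasion_time_h = occasion_times(cfg),
                   cr = cr_labels(cfg), subject_id = subject_ids(cfg),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[, c("subject_id", "cr", "occasion_time_h", "task", "stimulus_s",
        "trial_index")]
}

#' Simulate a cohort from the mechanistic clock model
#'
#' Generates a full synthetic study — trial-level timing responses plus
#' hourly melatonin series — by driving the pacemaker-accumulator model of
#' [expected_responses()] with subject-specific modulation parameters and
#' known DLMOs. Trial noise is multiplicative lognormal on the response so
#' responses stay positive. Subject parameter draws that violate the model's
#' validity constraints (negative amplitudes, `h_amp + c_amp >= 1`) are
#' redrawn; the number of redraws is recorded in the truth record.
#'
#' @param cfg A [protocol_config()].
#' @param pop Population-level [pacemaker_params()].
#' @param sd_h,sd_c,sd_phase Between-subject SDs of `h_amp`, `c_amp`
#'   (dimensionless) and `c_phase` (hours).
#' @param sdlog_by_cell Named lognormal trial-noise SDs per task-by-stimulus
#'   cell (`estimation.10`, `estimation.40`, `production.10`,
#'   `production.40`).
#' @param mel A [melatonin_params()].
#' @return A list with `trials` (data.frame: subject_id, cr,
#'   occasion_time_h, task, stimulus_s, trial_index, response_s), `melatonin`
#'   (data.frame: subject_id, cr, time_h, conc_pgml) and `truth` (generating
#'   parameters, per-subject draws and true DLMOs).
#' @export
simulate_mechanistic <- function(cfg = protocol_config(),
                                 pop = pacemaker_params(),
                                 sd_h = 0.03, sd_c = 0.01, sd_phase = 1,
                                 sdlog_by_cell = c(estimation.10 = 0.10,
                                                   estimation.40 = 0.12,
                                                   production.10 = 0.10,
                                                   production.40 = 0.12),
                                 mel = melatonin_params()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  dlmo <- draw_dlmo_table(cfg)
  ids <- subject_ids(cfg)
  n_redraws <- 0L
  subj_params <- lapply(ids, function(s) {
    for (attempt in 1:100) {
      h <- pop$h_amp + stats::rnorm(1, 0, sd_h)
      cc <- pop$c_amp + stats::rnorm(1, 0, sd_c)
      ph <- pop$c_phase + stats::rnorm(1, 0, sd_phase)
      ok <- h >= 0 && cc >= 0 && h + cc < 1
      if (ok) {
        return(pacemaker_params(r_ref = pop$r_ref, h_amp = h, tau_h = pop$tau_h,
                                c_amp = cc, c_phase = ph, period = pop$period,
                                leak_kappa = pop$leak_kappa,
                                t_wake_offset = pop$t_wake_offset))
      }
      n_redraws <<- n_redraws + 1L
    }
    stop("could not draw valid pacemaker parameters for subject ", s,
         call. = FALSE)
  })
  names(subj_params) <- ids

  trials <- occasion_grid(cfg)
  key <- paste(trials$subject_id, trials$cr)
  dl_key <- paste(dlmo$subject_id, dlmo$cr)
  t_dlmo <- trials$occasion_time_h - dlmo$dlmo_h[match(key, dl_key)]
  expected <- numeric(nrow(trials))
  for (s in ids) {
    idx <- trials$subject_id == s
    er <- expected_responses(t_dlmo[idx], trials$stimulus_s[idx],
                             subj_params[[s]])
    expected[idx] <- ifelse(trials$task[idx] == "estimation",
                            er$estimate, er$production)
  }
  cell <- paste(trials$task, trials$stimulus_s, sep = ".")
  sdlog <- sdlog_by_cell[cell]
  if (any(is.na(sdlog)))
    stop("sdlog_by_cell lacks entries for: ",
         paste(unique(cell[is.na(sdlog)]), collapse = ", "), call. = FALSE)
  trials$response_s <- expected * exp(stats::rnorm(nrow(trials), 0, sdlog))

  melatonin <- do.call(rbind, lapply(seq_len(nrow(dlmo)), function(i) {
    m <- simulate_melatonin(dlmo$dlmo_h[i], cfg, mel)
    data.frame(subject_id = dlmo$subject_id[i], cr = dlmo$cr[i], m)
  }))

  list(trials = trials, melatonin = melatonin,
       truth = list(backend = "mechanistic", config = cfg, pop = pop,
                    sd_h = sd_h, sd_c = sd_c, sd_phase = sd_phase,
                    sdlog_by_cell = sdlog_by_cell, mel = mel,
                    subject_params = subj_params, dlmo = dlmo,
                    n_redraws = n_redraws))
}

#' Default generating coefficients for recovery simulations
#'
#' A 15-coefficient vector (ratio units, canonical term order of
#' [timing_model_spec()]) representative of an entrained young-adult cohort:
#' slight overall overestimation, a wake-dependent exponential trend that
#' rises for estimation and falls for production, a circadian oscillation of
#' a few ratio points whose amplitude and phase differ by task and target
#' duration, and weaker trends for the longer target. Used as the default
#' generating truth of [simulate_from_lmm()] and the recovery pipeline.
#'
#' @return Named numeric vector of length 15.
#' @export
reference_beta <- function() {
  stats::setNames(
    c(102.13, -2.38, -4.72, 0.19, 2.24, 2.64, -0.92,
      -2.84, 2.66, -17.19, -3.28, -0.63, 13.29, -2.05, 2.20),
    full_fixed_terms())
}

#' Default residual SDs by task-by-stimulus cell (ratio units)
#' @return Named numeric vector over the four cells.
#' @export
reference_sigma_by_cell <- function() {
  c(estimation.10 = 8, estimation.40 = 12,
    production.10 = 10, production.40 = 15)
}

#' Simulate occasion-level outcomes directly from the trajectory model
#'
#' Uses the random-coefficient trajectory model generatively: builds the
#' full-protocol occasion grid, draws subject random effects
#' `b_i ~ N(0, diag(re_sd) %*% re_cor %*% diag(re_sd))`, and sets
#' `y = X beta + Z b + eps` with heteroscedastic residuals by
#' task-by-stimulus cell. Times are referenced to drawn (or supplied) true
#' DLMOs, so the returned table is ready for [fit_trajectory_model()].
#'
#' @param cfg A [protocol_config()].
#' @param beta Generating fixed effects: length-15 vector in the canonical
#'   term order (see [timing_model_spec()]).
#' @param re_sd SDs of the random intercept, task slope and stimulus slope
#'   (default c(10, 5, 5) ratio units).
#' @param re_cor 3x3 correlation matrix of the random effects (default
#'   identity).
#' @param sigma_by_cell Named residual SDs per task-by-stimulus cell.
#' @param dlmo_times Optional data.frame (subject_id, cr, dlmo_h) of true
#'   DLMOs; drawn from the protocol defaults when `NULL`.
#' @param spec [timing_model_spec()] used to build the design (must list all
#'   15 terms when `beta` has length 15).
#' @return A list with `occasions` (data.frame: subject_id, cr, task,
#'   stimulus_s, occasion_time_h, t_dlmo_h, ratio) and `truth` (generating
#'   parameters and the drawn random effects).
#' @export
simulate_from_lmm <- function(cfg = protocol_config(),
                              beta = reference_beta(),
                              re_sd = c(10, 5, 5),
                              re_cor = diag(3),
                              sigma_by_cell = reference_sigma_by_cell(),
                              dlmo_times = NULL,
                              spec = timing_model_spec()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (length(beta) != length(spec$fixed_terms))
    stop("'beta' must have length ", length(spec$fixed_terms),
         " (one per fixed term, in canonical order)", call. = FALSE)
  q <- length(spec$random_terms)
  if (length(re_sd) != q || !all(dim(re_cor) == q))
    stop("'re_sd'/'re_cor' dimensions must match the random terms",
         call. = FALSE)
  if (any(re_sd < 0)) stop("'re_sd' must be >= 0", call. = FALSE)
  if (is.null(dlmo_times)) dlmo_times <- draw_dlmo_table(cfg)

  occ <- occasion_grid(cfg)
  occ <- unique(occ[, c("subject_id", "cr", "occasion_time_h", "task",
                        "stimulus_s")])
  key <- paste(occ$subject_id, occ$cr)
  dl_key <- paste(dlmo_times$subject_id, dlmo_times$cr)
  occ$t_dlmo_h <- occ$occasion_time_h - dlmo_times$dlmo_h[match(key, dl_key)]
  rownames(occ) <- NULL

  des <- build_design(occ, spec)
  ids <- unique(occ$subject_id)
  # draw standard normals through the correlation Cholesky, then scale;
  # zero SDs degenerate cleanly to zero columns
  b <- matrix(stats::rnorm(length(ids) * q), length(ids), q) %*%
    chol(re_cor) %*% diag(re_sd, q)
  rownames(b) <- ids; colnames(b) <- spec$random_terms

  cell <- paste(occ$task, occ$stimulus_s, sep = ".")
  sig <- sigma_by_cell[cell]
  if (any(is.na(sig)))
    stop("sigma_by_cell lacks entries for: ",
         paste(unique(cell[is.na(sig)]), collapse = ", "), call. = FALSE)
  eps <- if (all(sig == 0)) 0 else stats::rnorm(nrow(occ), 0, sig)
  occ$ratio <- drop(des$X %*% beta) +
    rowSums(des$Z * b[occ$subject_id, , drop = FALSE]) + eps

  list(occasions = occ,
       truth = list(backend = "lmm", config = cfg, beta = beta,
                    re_sd = re_sd, re_cor = re_cor,
                    sigma_by_cell = sigma_by_cell,
                    dlmo = dlmo_times, b = b, spec = spec))
}
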