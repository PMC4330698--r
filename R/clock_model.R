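#' Pacemaker parameters for the internal-clock model
#'
#' Constructs and validates the parameter set of the pacemaker-accumulator
#' mechanism: a reference pulse rate modulated multiplicatively around 1 by a
#' saturating-exponential sleep-homeostatic term and a 24-h sinusoidal
#' circadian term, plus an attentional leakage rate that grows with stimulus
#' duration.
#'
#' The instantaneous pacemaker rate is
#' \deqn{r(t) = r_{ref} [1 + h (1 - e^{-t_+/\tau}) + c \cos(2\pi (t - \phi)/T)]}
#' with \eqn{t} the time from dim-light melatonin onset (DLMO) in hours and
#' \eqn{t_+ = \max(t - t_{wake}, 0)} the clamped homeostatic time. The
#' constraint \eqn{h + c < 1} keeps the rate strictly positive.
#'
#' @param r_ref Reference pulse rate (pulses/s) underlying reference-memory
#'   associations; must be positive.
#' @param h_amp Dimensionless amplitude of the homeostatic (time-awake)
#'   modulation; non-negative.
#' @param tau_h Homeostatic time constant in hours (default 18.2, the standard
#'   Process-S buildup constant).
#' @param c_amp Dimensionless amplitude of the circadian modulation;
#'   non-negative, with `h_amp + c_amp < 1`.
#' @param c_phase Circadian acrophase in hours relative to DLMO (time at which
#'   the circadian term peaks).
#' @param period Circadian period in hours (default 24).
#' @param leak_kappa Attentional leakage growth rate per second of stimulus
#'   duration (1/s); non-negative. Zero disables leakage.
#' @param t_wake_offset Offset (hours from DLMO) at which homeostatic buildup
#'   starts; times before it contribute the t = 0 homeostatic level.
#'
#' @return An object of class `pacemaker_params` (a named list).
#' @examples
#' p <- pacemaker_params(h_amp = 0.15, c_amp = 0.03)
#' pacemaker_rate(6, p)
#' @export
pacemaker_params <- function(r_ref = 1, h_amp = 0.15, tau_h = 18.2,
                             c_amp = 0.03, c_phase = 16, period = 24,
                             leak_kappa = 0.01, t_wake_offset = 0) {
  stopifnot(is.numeric(r_ref), length(r_ref) == 1L, is.finite(r_ref))
  if (r_ref <= 0) stop("'r_ref' must be positive", call. = FALSE)
  if (!is.finite(tau_h) || tau_h <= 0) stop("'tau_h' must be positive", call. = FALSE)
  if (!is.finite(period) || period <= 0) stop("'period' must be positive", call. = FALSE)
  if (!is.finite(h_amp) || h_amp < 0) stop("'h_amp' must be >= 0", call. = FALSE)
  if (!is.finite(c_amp) || c_amp < 0) stop("'c_amp' must be >= 0", call. = FALSE)
  if (h_amp + c_amp >= 1)
    stop("'h_amp' + 'c_amp' must be < 1 to keep the pacemaker rate positive",
         call. = FALSE)
  if (!is.finite(leak_kappa) || leak_kappa < 0)
    stop("'leak_kappa' must be >= 0", call. = FALSE)
  if (!is.finite(c_phase) || !is.finite(t_wake_offset))
    stop("'c_phase' and 't_wake_offset' must be finite", call. = FALSE)
  structure(list(r_ref = r_ref, h_amp = h_amp, tau_h = tau_h,
                 c_amp = c_amp, c_phase = c_phase, period = period,
                 leak_kappa = leak_kappa, t_wake_offset = t_wake_offset),
            class = "pacemaker_params")
}

as_pacemaker_params <- function(p) {
  if (inherits(p, "pacemaker_params")) return(p)
  do.call(pacemaker_params, as.list(p))
}

#' Instantaneous pacemaker rate
#'
#' Rate at which the pacemaker emits pulses at time `t` (hours from DLMO):
#' the reference rate modulated additively (on a dimensionless scale) by a
#' saturating-exponential homeostatic term and a cosine circadian term.
#'
#' @param t Time from DLMO in hours (vectorised).
#' @param p A [pacemaker_params()] object.
#' @return Pacemaker rate in pulses/s, strictly positive.
#' @export
pacemaker_rate <- function(t, p) {
  p <- as_pacemaker_params(p)
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("'t' must be finite numeric", call. = FALSE)
  t_pos <- pmax(t - p$t_wake_offset, 0)
  homeo <- p$h_amp * (1 - exp(-t_pos / p$tau_h))
  circ <- p$c_amp * cos(2 * pi / p$period * (t - p$c_phase))
  p$r_ref * (1 + homeo + circ)
}

#' Attentional leakage gain
#'
#' Fraction of emitted pulses that survive the attention-gated switch for a
#' stimulus of duration `d`: `exp(-leak_kappa * d)`. Longer stimuli lose
#' proportionally more pulses, so the gain decreases monotonically in `d`.
#'
#' @param d Stimulus duration in seconds; must be positive (vectorised).
#' @inheritParams pacemaker_rate
#' @return Gain in (0, 1]; exactly 1 when `leak_kappa = 0`.
#' @export
leakage_gain <- function(d, p) {
  p <- as_pacemaker_params(p)
  if (!is.numeric(d) || any(!is.finite(d)) || any(d <= 0))
    stop("'d' must be positive and finite", call. = FALSE)
  exp(-p$leak_kappa * d)
}

#' Expected estimation and production responses
#'
#' Maps the effective pacemaker rate at a given time and stimulus duration to
#' the expected behavioural responses of the two classical timing tasks.
#' Leakage attenuates the rate *deviation* from the reference rate,
#' `R_eff = r_ref + gain(d) * (r(t) - r_ref)`, so unmodulated timing is
#' veridical at every duration. Estimates scale directly with the effective
#' rate (more pulses accumulated during the stimulus) and productions
#' reciprocally (the criterion pulse count is reached sooner):
#' `estimate = d * R_eff / r_ref`, `production = d * r_ref / R_eff`, hence
#' `estimate * production = d^2` exactly.
#'
#' @param t Time from DLMO in hours (scalar or vector).
#' @param d Stimulus duration in seconds (scalar or vector, recycled).
#' @inheritParams pacemaker_rate
#' @return A data.frame with columns `t`, `d`, `estimate`, `production`
#'   (seconds).
#' @export
expected_responses <- function(t, d, p) {
  p <- as_pacemaker_params(p)
  n <- max(length(t), length(d))
  t <- rep_len(t, n); d <- rep_len(d, n)
  gain <- leakage_gain(d, p)
  r_eff <- p$r_ref + gain * (pacemaker_rate(t, p) - p$r_ref)
  if (any(r_eff <= 0))
    stop("effective pacemaker rate is non-positive; model degenerate",
         call. = FALSE)
  data.frame(t = t, d = d,
             estimate = d * r_eff / p$r_ref,
             production = d * p$r_ref / r_eff)
}

#' Clock state at a time point
#'
#' Convenience snapshot of the mechanism: instantaneous rate and the
#' effective (post-leakage) rate for each stimulus duration of interest.
#'
#' @param t Time from DLMO in hours (scalar).
#' @param p A [pacemaker_params()] object.
#' @param durations Stimulus durations (s) for which to report effective rates.
#' @return A list with `t`, `rate`, and `eff_rate_by_duration` (named vector).
#' @export
clock_state <- function(t, p, durations = c(10, 40)) {
  p <- as_pacemaker_params(p)
  stopifnot(length(t) == 1L, is.finite(t))
  rate <- pacemaker_rate(t, p)
  eff <- p$r_ref + leakage_gain(durations, p) * (rate - p$r_ref)
  names(eff) <- as.character(durations)
  list(t = t, rate = rate, eff_rate_by_duration = eff)
}
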