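---
title: "Modelling circadian and wake-dependent trajectories of interval timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling circadian and wake-dependent trajectories of interval timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronotimer)
```

## The scientific problem

Under sustained wakefulness, human timing of seconds-range intervals drifts:
estimates and productions of the same physical duration change with time
awake and with circadian phase. The classical information-processing account
is an internal clock whose pacemaker emits pulses at a rate controlled by the
sleep homeostat (rising, saturating with time awake) and the circadian
oscillator (a near-24-h rhythm). More pulses during a stimulus means longer
*estimates*; the same criterion pulse count is reached sooner, so
*productions* shorten — the two tasks respond reciprocally to rate changes.
Attention gates the pulses: holding attention is harder for longer stimuli,
so a growing fraction of pulses is lost for longer targets, which damps the
behavioural expression of rate changes for those targets.

`chronotimer` implements this account twice over, deliberately:

* a **mechanistic generator** (`pacemaker_params()`, `expected_responses()`,
  `simulate_mechanistic()`) that produces trial-level data from the clock
  mechanism, and
* a **statistical trajectory model** (`fit_trajectory_model()`) of
  occasion-level response-to-target ratios, which is what an analyst can
  actually estimate from such data.

The package's central validation is the loop between the two: simulate with
known truth, analyse, and check what comes back.

## The trajectory model

The outcome is `100 * mean(response)/target` per subject, epoch, occasion,
task and stimulus. The fixed-effect surface has 15 terms in a fixed,
documented order — intercept; task, stimulus and constant-routine factors;
`exp(-t/18.2)`, `sin(2*pi*t/24)`, `cos(2*pi*t/24)`; and the task and
stimulus interactions with each — where `t` is time from that epoch's DLMO
in hours (signed; occasions before melatonin onset have negative `t`).
Random intercepts plus task and stimulus slopes per subject carry the
pronounced individual differences such data show; residual SDs differ by
task-by-stimulus cell because variability grows with target duration and
differs between tasks.

Assumptions worth stating: Gaussian residuals on the ratio scale;
within-subject errors independent given the random effects (no residual
autocorrelation); the homeostatic time constant is fixed at 18.2 h, the
standard Process-S buildup value, rather than estimated; the circadian
period is fixed at 24 h. These mirror how the design is analysed in
practice; none are relaxed here.

### Factor coding

Factors are treatment-coded with reference levels estimation, 10 s, CR1, so
main time terms describe the estimation/10 s/CR1 cell and interactions are
differences from it. The coding is a genuine free choice — published
analyses of this design do not always state theirs, and narrative
descriptions of task effects can correspond to either reference. All sign
interpretations in this package are documented against the coding above.
One consequence for the bundled `reference_beta()` coefficient set: its
large negative `task:exp` value attaches the *rising* wake-dependent trend
to the task coded 1. The surface's shape — one task rising exponentially
while the other falls, opposing and duration-specific oscillations — is
what matters for simulation and recovery, and that is preserved under any
0/1 relabelling.

### Estimation

The marginal likelihood is maximised with `beta` and the base residual
variance profiled out by generalised least squares at every variance
parameter value. The 3×3 random-effect covariance is parameterised by the
log-Cholesky factor of its ratio to the residual variance (positive
definiteness by construction); variance multipliers are log-parameterised
with the estimation/10 s cell fixed at 1. Each subject's marginal covariance
is handled by the Woodbury identity, so one objective evaluation reduces to
cross-products accumulated once per subject and variance group — evaluation
cost is independent of the number of observations. Optimisation is
quasi-Newton (`nlminb`) with numerical gradients from three documented
starts (unit, small and large relative random-effect scale), relative
tolerance 1e-8. Data lying exactly in the fixed-effect column span
short-circuit to an ordinary least-squares perfect fit rather than chasing a
degenerate variance estimate. Negative-definite or rank-deficient iterates
are impossible by parameterisation; a non-convergent `nlminb` status is
carried on the fit object, never silently dropped.

Wald tables use the GLS covariance of `beta` and containment denominator
degrees of freedom: every term in the full design varies within subjects, so
all 15 share `df = n_obs - n_subjects - 15`. ML is used wherever fits are
compared by likelihood ratio; REML is available for final reporting.
Correctness is pinned by two independent routes in the test suite: a dense
joint-Gaussian log-density on small instances (agreement to 1e-6) and
`nlme::lme` on the homoscedastic random-intercept reduction (1e-4) plus the
full heteroscedastic model (loose tolerance; the two optimisers stop at
slightly different points).

### Model comparison

`candidate_specs()` fixes a six-model ladder of trajectory shapes —
constant, sinusoid-only, exponential-only, sinusoid+exponential without
task/stimulus time interactions, full-minus-`stim:exp` ("equal
exponentials"), and full — with the random-effect structure and variance
groups held constant, so ML likelihood-ratio tests address the fixed-effect
shape alone. Degrees of freedom are parameter-count differences; AIC uses
fixed plus variance parameters. Tests of variance components against a
boundary (dropping a random slope) are not chi-square in the usual sense;
where users make such comparisons, halving the p-value is the standard
correction, and the package leaves that to the analyst rather than applying
it implicitly.

## The synthetic cohort

`protocol_config()` defaults encode the study conditions the package
targets: 18 subjects, two 38.67-h constant routines, timing occasions every
2 h (20 per epoch at t = 0, 2, ..., 38 h — the 38.67-h window admits exactly
20 two-hourly points), both tasks at both targets with 3 trials per cell
(8640 trials in all), hourly melatonin sampling (39 samples per epoch).
DLMOs are drawn about 12.4 h after the (morning) start of each epoch,
SD 0.75 h between subjects and 0.3 h between epochs within a subject.

The model-based backend (`simulate_from_lmm()`) needs variability magnitudes
the fitted-model literature does not report; the defaults — random-effect
SDs (10, 5, 5) ratio units with independent effects, residual SDs 8–15 by
cell (8 and 12 for estimation of 10 and 40 s, 10 and 15 for production) —
were chosen once to give trajectory spreads of the size seen in published
individual-trajectory figures, and are overridable. The mechanistic backend
applies lognormal noise to responses (keeping them positive) with
cell-specific log-SDs, and redraws any subject-level parameter set that
violates model validity, counting redraws in the truth record.

Melatonin profiles are a 24-h cosine with mesor 10 pg/ml and amplitude
7 pg/ml peaking 6 h after DLMO, so the rising limb crosses the 10 pg/ml
threshold exactly at the true DLMO; multiplicative lognormal noise
(log-SD 0.03, the few-percent precision typical of radioimmunoassay
replicates) and a 2.8 pg/ml assay-sensitivity floor are applied. The
amplitude was chosen to keep the noiseless curve above the floor: the
noiseless profile is then an exact sinusoid, the cosinor round-trip is exact
up to the 0.01-h root tolerance, and the generator's recovery contract
(0.25 h under default noise, measured well inside that) holds. Real
melatonin profiles are *not* sinusoidal — daytime levels sit at the assay
floor and onset is abrupt — so the generator validates the estimation
machinery, not the biological realism of the profile shape.

What passing tests therefore show: the pipeline recovers what it planted,
under Gaussian/lognormal noise, sinusoidal melatonin and exactly the assumed
trajectory form. What they cannot show: robustness to profile shapes,
strategy shifts (counting), non-Gaussian outliers or model misspecification
in real cohorts.

## DLMO estimation

The composite cosinor is fit to z-scored concentrations (linear least
squares on the 5-column harmonic design; rank checked). Thresholding happens
on the **back-transformed** fitted curve in pg/ml — fitting on z-scores and
thresholding at 10 pg/ml are only mutually consistent if the fitted curve is
returned to concentration units first, which is the reading adopted here
(an alternative — using the fit only to guide a threshold crossing in the
raw data — cannot be excluded, but is not implemented). DLMO is the earliest
upward crossing within the observed span (no extrapolation), refined by
bisection to 0.01 h, and required to follow at least 1 h below threshold so
descending-limb artifacts near the window edge are not mistaken for onset.
Series that never rise through the threshold return an explicit no-DLMO
result, distinct from numerical failure; affected subject-epochs are dropped
from alignment with a warning.

## Preprocessing

Occasion means use the arithmetic mean of available trials. The outlier rule
removes occasion records with standardised outcome at or above 250 *before*
any model fitting; since the ratio outcome is already standardised to its
target, the default reads the rule as `ratio >= 250` (response at least 2.5
times the target). A within-cell z-score reading (`rule = "zscore"`) is
provided because "standardised" is ambiguous; the ratio reading is the
default as the more literal one for an outcome already on a standard scale.
The boundary is sharp: 249.9 is kept, 250 is removed.

## Validation problem sizes

The package validates itself at three scales, chosen to make each check
sharp rather than large: parameter recovery uses 20 full-design cohorts
(2880 occasions each) with per-replicate seeds, requiring every term's
replicate mean within 2 Monte-Carlo SEs of truth and ±2 SE coverage of at
least 0.85; likelihood-ratio null calibration uses 200 replicates of a
12-subject, 4-h-sampling cohort simulated under the
sinusoid+exponential-only truth, requiring the 5% rejection rate to lie in
the binomial band [0.023, 0.088]; and the dense-likelihood oracle runs on
cohorts of at most 200 observations where an n×n Cholesky is trivially
affordable. The reduced calibration cohort keeps the 2-CR structure (a
single epoch would make the CR factor inestimable).

## Known limitations

* No residual autocorrelation or non-Gaussian response options; the
  occasion mean is the unit of analysis, trials are never modelled.
* The candidate ladder covers the named trajectory shapes only; it is not an
  all-subsets search.
* Attentional leakage is a fixed exponential gain `exp(-kappa d)` applied to
  the rate *deviation* (so unmodulated timing is veridical at every
  duration); the functional form is a modelling choice, constrained only by
  monotonicity, and a time-varying leakage hook is left unimplemented
  because no default behaviour can be defended from available evidence.
* Homeostatic buildup before DLMO is clamped at its onset value
  (configurable via `t_wake_offset`); the true wake-time origin of each
  subject is not modelled.
* DLMO accuracy degrades if melatonin noise departs strongly from the
  lognormal few-percent regime; the estimator itself is unchanged from the
  standard composite-cosinor practice.
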