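# chronotimer

Tools for studying how the circadian clock and the sleep homeostat shape
human short-term interval timing — the perception and production of durations
in the seconds range — across constant-routine protocols of sustained
wakefulness.

The package is aimed at chronobiologists and psychophysicists who want to
(i) simulate realistic constant-routine timing studies, either from an
explicit pacemaker-accumulator mechanism or directly from a fitted-model
surface, and (ii) analyse such data with the trajectory model the field uses
for this design, implemented here from scratch and validated by parameter
recovery.

## The model

Behaviour is summarised per measurement occasion as a response-to-target
ratio, `100 * mean(response) / target` (100 = veridical timing). Each
subject's trajectory across sustained wakefulness is modelled as the sum of a
sleep-homeostatic and a circadian component,

```
y_ij = x_ij' beta + b_0i + b_1i TASK_ij + b_2i STIM_ij + e_ij
```

where the fixed-effect surface combines task (estimation/production),
stimulus (10/40 s) and constant-routine factors with three time regressors in
`t`, the time from dim-light melatonin onset (DLMO) in hours:

* `exp(-t/18.2)` — the saturating buildup of sleep pressure (Process S,
  time constant 18.2 h),
* `sin(2*pi*t/24)` and `cos(2*pi*t/24)` — the circadian oscillation, via the
  identity `A cos(wt - P) = s sin(wt) + c cos(wt)`,

plus the interactions of each with task and stimulus (15 terms in all).
Random intercepts and task/stimulus slopes have an unstructured 3×3
covariance; residual variances differ by task-by-stimulus cell. Estimation is
profiled ML/REML written for this model (Woodbury factorisation per subject,
log-Cholesky covariance, log-scale variance multipliers), with Wald tables,
likelihood-ratio comparison of a ladder of reduced trajectory shapes, and
empirical-BLUP predictions.

DLMO itself is estimated from hourly melatonin by the standard composite
24 h + 12 h cosinor fit to z-scored concentrations, back-transformed to
pg/ml, with DLMO the earliest upward crossing of 10 pg/ml.

The mechanistic backend ties the statistical shape to an internal-clock
account: a pacemaker whose pulse rate rises with time awake and oscillates
with circadian phase, an attention-gated switch that leaks pulses at a rate
growing with stimulus duration, and reciprocal mappings to behaviour —
estimates scale with the effective rate, productions inversely, so
`estimate * production = d^2` exactly.

## Worked example

Simulate a full 18-subject study from the mechanistic clock model, estimate
each epoch's DLMO from the melatonin series, preprocess, and fit:

```r
library(chronotimer)

cfg  <- protocol_config(seed = 42)
sim  <- simulate_mechanistic(cfg)
dlmo <- estimate_dlmo_table(sim$melatonin)
occ  <- align_to_dlmo(filter_outliers(aggregate_and_ratio(sim$trials))$kept, dlmo)
fit  <- fit_trajectory_model(occ, method = "REML")
fit
```

```
Random-coefficient trajectory model (REML)
  observations: 2880  subjects: 18
  log-likelihood: -9517.78
  residual SD: 6.477404
  residual SD multipliers:
estimation.10 estimation.40 production.10 production.40
       1.0000        1.0965        0.8657        1.1226

Fixed effects:
        term    value     se   df        t          p
1  intercept 110.0631 0.5091 2847 216.1752  0.000e+00
2       task -19.2598 0.6518 2847 -29.5501 1.281e-167
...
5        exp  -6.2719 0.4279 2847 -14.6574  5.944e-47
10  task:exp  12.7191 0.4958 2847  25.6530 9.562e-131
```

The negative `exp` coefficient means the estimation task's ratio *rises* as
sleep pressure saturates (the regressor decays), while the large positive
`task:exp` interaction flips that trend for the other task — the reciprocity
the pacemaker account predicts. Converting the circadian coefficients with
`amplitude_phase(fit$beta[["sin"]], fit$beta[["cos"]])` gives an oscillation
of about 3.1 ratio points peaking ~16 h after DLMO for the reference cell.

Alternative trajectory shapes (constant, sinusoid-only, exponential-only,
shared or duration-specific exponentials) are compared with
`compare_ladder(occ)`, which reports AIC and likelihood-ratio tests for all
recorded nestings.

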