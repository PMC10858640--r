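---
title: "Methods: simulating and analysing a multiparametric remote-monitoring heart-failure score"
author: "hfscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a multiparametric remote-monitoring heart-failure score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfscore)
```

## The problem

Implantable defibrillators with daily remote monitoring measure a set of
physiologic parameters that drift in characteristic ways during cardiac
decompensation: 24 h mean heart rate rises, heart-rate variability (HRV)
and thoracic impedance (TI) fall, nocturnal heart rate becomes unstable,
atrial high-rate episode (AHRE) burden, premature ventricular contractions
(PVC/h) rise, and physical activity declines. Commercial risk algorithms
condense these channels into a single daily composite — here called the
HF Score — and raise an alert when it crosses a programmable threshold
(default 45), clearing it only below a recovery threshold ten points lower
(hysteresis).

`hfscore` reimplements, as a tested pipeline, the retrospective analysis of
such a score: simulate a cohort of device patients with and without
worsening-heart-failure (WHF) hospitalizations, compute daily scores,
apply the cohort's eligibility and windowing rules, and compare 12-week
pre-event score trends between groups with a two-level nested
random-intercept linear mixed model. The reference cohort that calibrates
all defaults comprises 2050 patients pooled from nine trials, 259 of whom
had 369 qualifying WHF hospitalizations.

## The scoring engine

The exact functional forms of the deployed algorithm's components are
proprietary and unpublished; the engine therefore uses simple,
shift-invariant statistics that reproduce the documented qualitative
behaviour, each normalized to $[0,1]$ and scaled by a configurable weight
(the component's maximum contribution in score points):

* **Monotone trends** (24 h HR and PVC/h increase; HRV, TI and activity
  decrease): a Mann–Kendall-type concordance statistic over the trailing
  84-day window, $S/\binom{n}{2}$ with the negative part clipped. It is 1
  for a strictly monotone series in the scored direction, 0 for constant
  or opposing series, and invariant to level shifts and monotone
  rescaling.
* **Nocturnal-HR instability**: the standard deviation of the last 28
  nocturnal means divided by a reference dispersion (default 5 bpm),
  clipped at 1.
* **AHRE burden**: the window-mean burden (percent of 24 h) mapped
  linearly to saturate at 50 %.
* HRV days with AHRE burden above 20 % are excluded from the HRV
  statistic, since HRV is only assessed outside atrial episodes.

Default weights are 20/20/15/15/10/10/10 points for
hr24/hrv/night_hr/ti/activity/ahre/pvc (sum 100), chosen so the simulated
event windows reproduce the reference contribution structure (below).
The composite is the exact component sum; the HF index is the score
divided by 10. Scores start after a 30-day post-implant run-in. A day is
valid only if at least 10 measured days fall in its window (the global
transmission gate, not the detectors, owns missingness policy) and the
trailing 90-day transmission rate is at least 55 %; for series younger
than 90 days the denominator is the series age, so the run-in period is
not penalized.

The alert state machine starts an episode on the first day of
`stable_exceed_days` (default 2) consecutive valid days above the nominal
threshold, and ends it on the first day below the recovery threshold.
"Stably exceeds" is not quantified in the public description, so the
consecutive-day count is explicit configuration. Missing or invalid days
pause the consecutive-day counter without resetting it — a deliberate
choice: a transmission gap carries no evidence against an incipient rise,
whereas a valid sub-threshold day does reset the counter.

## The synthetic cohort

No patient-level data accompany the reference analysis, so the generator
is a first-class, tested module whose defaults *are* the published study
conditions: 259 event patients with 369 admissions and 1791 controls,
allocated exactly over the nine contributing trials; covariate
prevalences per group from the published baseline table; daily
transmission probability 0.9 (typical compliance of these systems);
admissions placed at least 121 days post-implant (30-day run-in plus a
full 91-day window) and at least 91 days apart, with a flag to allow
early/repeat events that exercise the truncation rules.

### Component-score trajectories

For each component, the expected weekly mean in the event group moves
from its published Week −12 value to its published Week 0 value; controls
move between their own (nearly flat) published endpoints. Daily means are
linear in the day offset and anchored at the week-bin midpoints (offsets
87 and 3), so the Week −12 and Week 0 7-day bin averages equal the
configured endpoints *exactly*, not merely in the limit. A per-component
`plateau` shape is available for channels that saturate early. Days more
than 90 days before an anchor sit at the Week −12 baseline.

Noise enters at three levels, matching the model later fitted: a
patient-level random intercept, an anchor-level intercept drawn per event
(so repeat hospitalizations in one patient are correlated but not
identical), and daily residual noise. The three SDs default to
$0.6s$, $0.3s$ and $\sqrt{3.85}\,s$ per component, where $s$ is the
published cross-sectional SD of that component at Week −12 in the event
group; this splits the weekly-mean variance into roughly 36 % patient,
9 % anchor and 55 % residual while keeping the total weekly-mean SD near
$s$. Because component correlations are not published, components are
simulated independently; the composite's cross-sectional SD is therefore
somewhat below the published 26.1 — a documented limitation that does not
affect mean trajectories or contrast calibration.

Component values are floored at zero. Naively flooring Gaussian noise
would inflate the means of small-mean, large-SD components badly (PVC has
mean 1.3 and SD 8.0; the floored mean would exceed 3). The generator
therefore *moment-matches* the floor: for each target daily mean $m$ and
total noise SD $\sigma$ it solves
$\sigma\,[z\Phi(z) + \phi(z)] = m$ for the latent mean $\mu = \sigma z$,
so that $E[\max(0, \mu + \sigma Z)] = m$ exactly. Expected daily values —
and hence weekly bin means — stay on target for every component, at the
price of a right-skewed marginal distribution for the low-mean channels,
which is also what real burden-type measurements look like.

One global seed is split deterministically per patient through a hash of
the patient identifier, so any subset of patients reproduces its series
regardless of cohort size. Identical configuration and seed give
bit-identical output.

### Raw telemetry

`simulate_telemetry()` emulates the upstream measurement layer in raw
units (bpm, ms, %, per hour, ohm): stationary channels for controls and,
for event patients, linear drift over the 240 days before each admission
(rising 24 h HR and PVC/h; falling HRV, TI and activity), nocturnal-HR
noise inflation and an AHRE-burden ramp over the final 12 weeks, with
burden concentrated in AF-history patients. Drift-to-noise ratios were
set by inverting the expected Mann–Kendall statistic under linear drift
so that scored event windows at Week −12 reproduce the reference
contribution shares (≈32 % 24 h HR, 22 % HRV, 17 % TI). The telemetry
route is intentionally simpler than reality: no circadian or seasonal
structure, no medication effects, and control windows score near zero
(the deployed algorithm evidently assigns controls substantial baseline
component values; reproducing that would require the proprietary forms).
The full-cohort trend analysis therefore uses the direct component-score
simulator, and the telemetry route serves as an end-to-end validation of
the engine.

## Cohort pipeline

The eligibility cascade applies the published screening stages in their
printed order — device/monitoring suitability, long-standing AF,
LVEF > 35 %, NYHA class outside II/III, insufficient monitoring data,
short post-run-in follow-up without an event — counting each record at
its first failing stage only. The packaged 5987-record fixture carries
single-reason flags matching the published per-stage counts and leaves
exactly 2050 eligible records.

Event anchors are qualifying admissions (≥30 days post-implant, trailing
transmission rate ≥55 % evaluated at the admission day — the published
rule does not specify the evaluation day; the admission day is the
natural choice). A repeat admission within 90 days is truncated to the
inter-event gap. Control anchors are the last transmitted day, requiring
≥90 days of post-run-in follow-up and the same gate; controls also
respect the 30-day run-in for symmetry, although the published rule is
silent there. Day offsets $d \in [0, 90]$ map to weeks $-\lfloor d/7
\rfloor$, so Week 0 is days 0–6 and Week −12 is days 84–90; a weekly mean
requires at least one observed day (the 55 % gate already bounds
missingness, and the mixed model tolerates unbalanced weeks).

## The trend model

Weekly observations are modelled as
$$y_{ijk} = \beta_0 + \beta_1 t_k + \beta_2 g_i + \beta_3 t_k g_i +
  b_i + b_{ij} + \varepsilon_{ijk},$$
with $t = \text{week} + 12$ (so $\beta_0$ is literally the Week −12
prediction and $\beta_2$, $\beta_3$ are the intercept and slope
contrasts), patient intercepts $b_i$, anchor-within-patient intercepts
$b_{ij}$, and REML estimation by default. Controls form singleton
anchor clusters, so the anchor variance is identified by multi-event
patients; this keeps one model for both groups.

The implementation profiles both the fixed effects and the residual
variance out of the likelihood and optimizes only the two variance
*ratios* on the log scale. The patient-block covariance inverse and
determinant are closed forms via two nested rank-one updates, so one
likelihood evaluation is a handful of grouped sums and the full 28
080-observation cohort fit takes seconds. L-BFGS-B runs from several
starts around a moment-based initializer (ties broken by the smaller
component norm), followed by a Nelder-Mead polish; ratios ending below
$10^{-7}$ are reported as exact zeros, and at zero ratios the fixed
effects reduce to ordinary least squares exactly. Wald contrasts use
normal-approximation p-values without degrees-of-freedom corrections — a
documented limitation for small fixtures, immaterial at the thousands of
observations the design targets.

Validation is dual-route: an exported brute-force oracle
(`lmm_loglik_dense()`) evaluates the same restricted likelihood by
building the dense covariance matrix, and the test suite checks
agreement to $10^{-6}$ on small instances, equivalence with the balanced
nested-ANOVA closed-form estimators, the OLS limit, and agreement with an
independent mixed-model implementation (`lme4`) on betas, variance
components, standard errors and log-likelihood.

## Calibration results the tests compute

With the default (published) trajectory endpoints, the full-size
simulation (2050 patients, 369 event anchors, ~28 000 weekly
observations) recovers an event-group Week 0 model prediction within one
point of the published 51.6, with strongly positive intercept and slope
contrasts. A null simulation with identical group trajectories holds the
slope-contrast type-I error at the nominal 5 % within binomial bounds
(400 replicates of an 80-patient design), and 200 replicated fits at a
~200-patient scale show fixed-effect biases below 2 %. Problem sizes for
the replicated studies were chosen to keep the whole suite comfortably
interactive while leaving Monte-Carlo error well below the tolerances
tested.

## Known limitations

* Component functional forms and weights approximate an unpublished
  proprietary algorithm; only their qualitative behaviour and the
  published contribution structure are reproduced.
* Components are simulated independently; cross-component correlation
  (and hence the composite's cross-sectional SD) is not matched.
* Within-patient day-to-day autocorrelation beyond the random intercepts
  defaults to none; an AR(1) parameter is exposed without any claim of
  fidelity.
* The published real-cohort p-values and SDs cannot be reproduced without
  patient data; the pipeline's claims are calibration and recovery, not
  replication.
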