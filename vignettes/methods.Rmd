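---
title: "Methods: bouted activity outcomes and delay-control effect estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bouted activity outcomes and delay-control effect estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bouted)
```

## Scope

`bouted` implements the analytical pipeline of a two-arm delay-control
(waitlist) randomized trial of a physical-activity intervention in adults
with knee osteoarthritis, measured by a multi-sensor wearable worn 24 h/day
for 7-day windows. It covers four stages: (1) minute-epoch ingestion and
wear-day validation, (2) bout detection and daily/per-assessment activity
outcomes, (3) effect estimation (baseline-adjusted ANCOVA at the primary
endpoint; a longitudinal mixed model separating secular trend from exposure
effects, with cluster-robust standard errors), and (4) intervention-fidelity
scoring. Because participant-level trial data are not publicly available,
the package also contains a first-class synthetic-trial generator with known
ground truth; every statistical property of the pipeline is demonstrated
against that generator.

## Bout detection

A minute *qualifies* under a rule when its MET value satisfies the rule's
comparator and threshold. The standard rules are:

| rule | MET | minimum duration | interruption allowance | waking only |
|---|---|---|---|---|
| mvpa | >= 3.0 | 10 min | runs of <= 2 min | no |
| purposeful | >= 4.0 | 10 min | runs of <= 2 min | no |
| sedentary | <= 1.5 | 20 min | none | yes |

The interruption allowance is read as a *run-length* bound: any single run
of consecutive below-threshold minutes inside a bout may last at most 2
minutes, and several such runs may occur in one bout. This matches the
dominant accelerometry convention for tolerance-based bouts and is the only
reading under which "2 minutes" is naturally a run length. An alternative
*total-budget* reading (at most 2 interruption minutes per bout in total) is
selectable via `bout_rule(..., interruption_mode = "total")`.

Detection is a greedy left-to-right maximal-extension scan over the
run-length encoding of the minute classification (qualifying / eligible
interruption / ineligible). A candidate opens at the first unconsumed
qualifying minute, absorbs subsequent qualifying runs joined by legal
interruption runs, and closes at an ineligible minute (off-body always;
asleep for waking-only rules) or an over-long interruption run; trailing
sub-threshold minutes are trimmed so bout boundaries always meet the
threshold, and the candidate is emitted if its duration reaches the rule
minimum. Because two overlapping valid windows always merge into a valid
window, maximal valid windows are pairwise disjoint, so this greedy
segmentation is the *unique* maximal decomposition — the test suite verifies
exact agreement with an independent brute-force maximal-window enumeration
on a thousand random sequences.

Minutes are half-open 0-based integer intervals `[start, end)` within a
calendar (midnight-to-midnight) day; durations are exact integers. A bout
credits its **full duration** (qualifying plus tolerated interruption
minutes) to "time accumulated in bouts"; `credit = "qualifying_only"` is
available because published outcome definitions are usually silent on this
point.

## Wear-day and assessment validity

Missing minutes in an epoch file are treated as off-body, never as zero-MET
— otherwise gaps would fabricate sedentary bouts. A wear day is valid when
its on-body minutes reach `min_on_body_minutes` (default 1140 = 19 h;
inclusive bound). The protocol prescribes only a 4-day minimum of valid
days per assessment, so the per-day threshold is exposed as configuration
rather than hard-coded; 19 h of a 24-h wear protocol is the package's
default near-complete-day criterion. An assessment with fewer than
`min_valid_days = 4` valid days is flagged invalid and excluded from the
analysis dataset (its means are withheld, not zeroed). Guideline attainment
is mean daily bouted MVPA x 7 >= 150 min/week. Steps recorded while asleep
or off-body are excluded from daily step totals.

## The delay-control design and its estimators

Assessments occur at weeks 0/13/26/39. The immediate group (IG) starts the
12-week program after baseline; the delay group (DG) starts it after the
week-13 assessment. Time since program initiation at each assessment is
therefore 0/12/25/38 weeks (IG) and 0/0/12/25 weeks (DG): exposure is
staggered across arms and occasions, which is what lets a single model
separate occasion effects from exposure effects.

**ANCOVA (primary endpoint).** Endpoint outcome regressed on an IG
indicator and the baseline outcome (optionally randomization-block factors;
off by default, since in this design the block-adjusted arm estimate is
essentially identical). The arm coefficient is the adjusted mean difference
(IG - DG); intervals and p-values use the t distribution with residual
degrees of freedom. Participants missing the endpoint are excluded from
this fit only (complete case at the endpoint); no imputation is attempted,
and the estimand is documented rather than guessed at.

**Longitudinal mixed model.** For participant *i* at occasion *t*:

y_it = b0 + b1·IG_i + sum_w gamma_w·T_w(t) + sum_e delta_e·E_e(i,t) + u_i + e_it

with occasion indicators T13/T26/T39 (secular trend), exposure indicators
E12/E25/E38 (intervention effects), a participant random intercept u_i and
residual e_it. The 8 mean parameters saturate the 2 x 4 cell structure, and
the design is full rank because exposure is staggered. Fitting is REML via
`lme4`; all available rows are used (likelihood-based,
missing-at-random), which together with analysis-by-randomized-arm is the
intention-to-treat posture of the pipeline. Reference levels are week 0 and
exposure 0, so the intercept is the DG baseline mean; contrasts between
follow-up occasions (T26 - T13, T39 - T13) are emitted with delta-method
standard errors because trend effects are conventionally reported relative
to the first follow-up.

**Sandwich standard errors.** The empirical (cluster-robust, clustered by
participant) covariance of the fixed effects is computed in closed form
from the REML variance components: with V_i = sigma^2·I + tau^2·J per
participant, A = sum X_i' V_i^-1 X_i and B = sum X_i' V_i^-1 r_i r_i' V_i^-1 X_i,
the sandwich is A^-1 B A^-1. No installed package provides this estimator
for mixed models, so it is implemented directly (the Woodbury identity
gives V_i^-1 cheaply). The CR0 form is the default; a CR1 correction
(G/(G-1)) is available, default off, because small-sample corrections for
this estimator are not standardized. Sandwich intervals use large-sample
normal quantiles. Passing `variance_components = list(tau2 = 0, sigma2 = 1)`
bypasses REML and performs direct generalized least squares; with zero
random-intercept variance this reproduces OLS on the same design, which the
tests verify to 1e-6.

**Power.** `power_two_sample()` is the standard noncentral-t computation
for the pooled two-sample t test (exact under equal true SDs; an accurate
approximation otherwise, verified against simulation to 0.01). At the
trial's own sample-size inputs (means 75.5 vs 50.0 min/day, SDs 54.3 and
46.8, n = 50, one-sided alpha = 0.1) the standard computation yields about
0.68–0.69 rather than the 74% figure quoted with those inputs; the
computation is implemented as stated and the discrepancy is simply
documented — no attempt is made to reverse-engineer the original
calculation.

## The synthetic-trial generator

The generator emulates the *statistical structure* of the trial, not the
physiology of any device:

* **Randomization**: permuted variable blocks (sizes from `{2, 4}` by
  default), exact 1:1 allocation.
* **Latent activity.** Participant level L_i ~ Gamma(mean
  `baseline_mean_by_arm`, SD `participant_sd`), with an outlier mixture
  (rate `skew_outlier_rate`, mean `outlier_mean` = 320 min/day) mirroring
  the handful of extremely active participants such cohorts contain.
  Assessment-level latent means multiply in mean-one gamma noise scaled to
  `residual_sd`; daily values multiply in mean-one gamma day noise with CV
  `day_cv`. Everything is multiplicative and non-negative, so
  `true_exposure_effects` are *exact* additive effects on mean minutes/day
  — the estimand the recovery experiments compare against — and the
  marginal distributions carry the heavy right skew (SD exceeding the
  mean) that real bouted-MVPA data show.
* **Defaults** follow the scale of the emulated trial: baseline ~45
  min/day, `participant_sd` 30, `residual_sd` 15, `day_cv` 0.6, exposure
  effects 9.4/-3.0/0.2 min/day at 12/25/38 weeks, small positive secular
  trend, ~10% missingness per follow-up assessment, 7 wear days per
  assessment.
* **Epoch days** are built constructively: the daily bouted-MVPA target is
  laid down as explicit bouts (>= 10 min, separated by >= 3 sub-threshold
  minutes so bouts cannot merge), optionally with legal 1–2-minute
  interruptions; sedentary targets become blocks of >= 20 min of <= 1.5
  MET during waking hours; remaining waking time is filled with MET in
  (1.5, 3) plus short >= 3 MET "junk" runs below the 10-minute minimum
  that a correct engine must ignore; nights (23:00–07:00 by default) are
  flagged asleep at ~0.9 MET. The bout engine run on such a day returns
  the MVPA target *exactly* — the generator is the constructive inverse of
  the engine, which is the round-trip property the tests exploit.
* **Questionnaires** are bounded subscale scores (KOOS 0–100, PIHS 0–96,
  PHQ-9 0–27, SRHI and TPB 1–7) from clamped Gaussian participant
  trajectories; item-level scoring is out of scope.
* **Adherence** draws education attendance, counseling calls (per-call
  probability 0.88) and weekly tracker wear days (per-participant
  propensity Beta(12, 1.6)), chosen once so the three fidelity criteria are
  met at roughly the rates the emulated trial reported (~100%/~92%/~80%).

What the generator does **not** emulate: autocorrelated within-day activity
patterns, seasonality, device error in MET estimation, informative
missingness, or real non-wear behaviour (days are fully worn by default).
Passing tests therefore demonstrate the correctness of the *pipeline* under
the stated statistical structure, not robustness to every property of real
accelerometer data.

## Numerical and design choices

* Daily MVPA targets are integers (bouted minutes are integer by
  definition); continuous latent values in (0, 5) snap to 0 and [5, 10) to
  10 because a positive bouted total below the 10-minute minimum is not
  representable. Recovery experiments use the assessment-level fast path
  (`simulate_outcomes()`), which skips this discretization.
* Sedentary targets are capped by a worst-case feasibility bound
  (20-minute blocks, 3-minute separators) so synthesized days can always be
  laid out inside the 960-minute waking window.
* Zero-variance degeneracies are handled explicitly: constant baselines
  make ANCOVA refuse with an error naming the degenerate covariate; with
  all variance components zero the REML fit still recovers all 8
  coefficients exactly (verified to 1e-6).
* Percentages in adherence tables round half-up (80.77 -> 81); an empty
  arm reports blank, not 0%.
* Per-replicate seeds in `recovery_experiment()` are `seed + replicate`,
  so any subset of replicates reproduces independently of execution order.
* Monte-Carlo problem sizes were fixed a priori: 1,000 random sequences
  for the engine/oracle equivalence, 500 days for the generator round
  trip, 2,000 replicates for ANCOVA recovery and coverage, 1,000 for the
  type-I error of the sandwich test, 100,000 for the power simulation.

## Limitations

* The mixed model assumes a random intercept only; random slopes or
  serial correlation within participant are not modelled (the sandwich
  errors are, however, robust to such misspecification, which is why they
  are the default inferential route).
* ANCOVA is complete-case at the endpoint; under missingness dependent on
  unobserved outcomes both estimators would be biased.
* The exposure mapping assumes the DG starts the program exactly one
  assessment late, as per the design; irregular individual start dates are
  not supported.
* Sleep/wake comes from the epoch flag, not from a sleep-staging
  algorithm; the waking window used by the sedentary rule is exactly as
  flagged.
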