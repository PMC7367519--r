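# bouted

Analysis pipeline for wearable-measured physical-activity outcomes in
**delay-control (waitlist) randomized trials**, as used to evaluate
activity-counseling interventions in people with knee osteoarthritis. The
package takes minute-epoch wearable data (per-minute MET, steps, on-body
and asleep flags), derives the bouted activity outcomes that guidelines and
trials report, estimates intervention effects with the two estimators such
trials use, scores protocol fidelity, and ships a ground-truth synthetic
trial generator so the whole pipeline can be validated without access to
participant data.

## What it computes

**Bouted activity outcomes.** A bout is a sustained episode of an activity
class: moderate-to-vigorous physical activity (MVPA) is >= 3 MET sustained
>= 10 min, tolerating interruption runs of <= 2 consecutive sub-threshold
minutes; purposeful activity is the same with a 4 MET threshold; sedentary
behaviour is <= 1.5 MET for >= 20 min during waking hours with no
allowance. Detection is a deterministic greedy maximal-extension scan whose
segmentation provably equals the unique set of maximal valid windows (and
is tested against a brute-force enumeration). Daily summaries feed
per-assessment means over valid wear days (>= 4 valid days of >= 19 h
on-body by default), including guideline attainment (7 x daily bouted
MVPA >= 150 min/week).

**Effect estimation.** In the delay-control design the control arm starts
the identical program one assessment late, so weeks-since-initiation
(exposure: 0/12/25/38 for the immediate group at weeks 0/13/26/39;
0/0/12/25 for the delay group) is staggered against assessment occasion.
The package estimates

* the **ANCOVA adjusted mean difference** at the week-13 endpoint
  (endpoint ~ arm + baseline, optional block adjustment), and
* a **longitudinal linear mixed model**
  `y ~ group + T13 + T26 + T39 + E12 + E25 + E38 + (1 | participant)`
  (REML via lme4) whose exposure terms E12/E25/E38 are the intervention
  effects and occasion terms T13/T26/T39 the secular trend, with both
  model-based and **cluster-robust sandwich** standard errors computed in
  closed form from the variance components,

plus the noncentral-t power of the two-sample pooled t test used for
sample-size reasoning, and intervention-fidelity scoring (education
session attended; >= 3 of 4 counseling calls; tracker used >= 5 days/week
in >= 11 of 12 weeks).

## Worked example

```r
library(bouted)
rules <- default_bout_rules()

# a day with a clean 12-min MVPA episode and a 5+2+5 interrupted episode
met <- c(rep(1.2, 30), rep(3.4, 12), rep(1.2, 60),
         rep(3.6, 5), rep(2.0, 2), rep(3.6, 5), rep(1.2, 1326))
detect_bouts(met, rules$mvpa)
#>   start_minute end_minute duration_minutes qualifying_minutes interruption_minutes
#> 1           30         42               12                 12                    0
#> 2          102        114               12                 10                    2
```

Both episodes count 12 bouted minutes: the second spans 5 qualifying + 2
interruption + 5 qualifying minutes, legal because the interruption run is
<= 2 min and the bout still reaches 10 min.

```r
# one synthetic trial (25/arm) with a true 13 min/day exposure effect
cfg <- trial_config(true_exposure_effects = c("12" = 13, "25" = 13, "38" = 13))
sim <- simulate_outcomes(cfg, seed = 42)

ancova_adjusted_difference(sim$data, "mvpa")
#>     term estimate se_model se_sandwich ci_low ci_high     p estimator n_obs n_participants
#> 1 arm_IG     10.6     9.68          NA  -8.85    30.1 0.277    ancova    48             48

fit <- fit_delay_control_lmm(sim$data, "mvpa", cfg)
fit[fit$term %in% c("E12", "E25", "E38"),
    c("term", "estimate", "se_sandwich", "ci_low", "ci_high")]
#>   term estimate se_sandwich ci_low ci_high
#> 6  E12    -1.51        9.91  -20.9    17.9
#> 7  E25   -12.08       19.60  -50.5    26.3
#> 8  E38   -26.96       25.35  -76.6    22.7
```

The single-trial ANCOVA estimate (10.6 min/day, 95% CI -8.9 to 30.1) is one
noisy draw around the configured truth of 13 — at n = 25/arm with
activity-data skew, single trials are underpowered, which is exactly what
the power computation says:

```r
power_two_sample(75.5, 54.3, 50.0, 46.8, n_total = 50, alpha = 0.1, one_sided = TRUE)
#> [1] 0.685
```

Across many replicates the estimator is unbiased with nominal coverage;
`recovery_experiment(cfg, n_replicates = 2000, estimators = "ancova")`
reports mean estimate, bias, empirical SE, CI coverage and rejection rate.

A full end-to-end run (epoch files on disk -> bout detection -> estimation
-> fidelity -> report tables) is one call:

```r
run_all(trial_config(), "out/", seed = 1)
```

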