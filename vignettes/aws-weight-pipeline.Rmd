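---
title: "Methods: the AWS weight-estimation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the AWS weight-estimation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awsproc)
```

## Problem and model

An automated weighing system (AWS) is a walk-over or feeder-station scale
that records an animal's body weight at every visit. For a herd of growing
beef steers this yields, per animal, an irregular time series of a few
visits per day. The series is contaminated in two characteristic ways:
residual feed or manure on the platform adds a positive offset of tens of
kilograms, and partial stance on the load cell produces large negative
readings. The quantity of interest is a single representative body weight
per animal at the midpoint of each short *measurement window* — the date
on which, in a conventional campaign, the animal would have been run
through a static squeeze-chute scale. The static-scale value serves as the
reference against which the AWS-derived estimate is scored.

The working model is that over a window of a few days an animal's true
weight changes approximately linearly (growth of well under a kilogram per
day), visit-level readings are the true weight plus roughly symmetric
measurement noise, and contamination is sparse but large relative to that
noise. Under this model, robust within-window filtering followed by
aggregation should recover the mid-date weight to within the noise floor.

## The three stages

### Stage 1 — pre-processing (`detect_outliers()`, `daily_average()`)

Records flagged as taken while the forage-intake monitor was active are
screened out first (`screen_concurrent()`); such readings include feed
mass and are invalid by construction. Remaining records are grouped — by
default per animal within each measurement window (`grouping =
"animal_window"`; `"animal_global"` pools an animal's full series) — and
filtered by one of two rules with multiplier `k = 1.5`:

* **Tukey's fences** (`rule = "tukey"`): keep `v` with
  `Q1 − k·IQR ≤ v ≤ Q3 + k·IQR`, quartiles computed by the default
  `stats::quantile()` type-7 definition. Boundary values are kept
  (inclusive fences).
* **Standard-deviation rule** (`rule = "sd"`): keep `v` with
  `|v − mean| ≤ k·s`, with the `n − 1` sample standard deviation;
  boundaries inclusive; a singleton group is always kept.

Groups with fewer than `min_group_size = 4` records bypass filtering
untouched: quartiles and standard deviations of 2–3 points are too
unstable to disqualify data, and a sparse-visiting animal should not lose
its window. Survivors are collapsed into per-animal **daily averages**
(`daily_average()`), which equalises the influence of frequent and
infrequent visitors and is the unit all later stages operate on.

### Stage 2 — estimation (`estimate_all()`)

Each measurement window has a `length_days = 7` span and a
`mid_day_index = 4` mid-date. Three estimators produce the representative
weight from the window's daily averages:

* **mean** — arithmetic mean of the daily averages;
* **median** — their median;
* **linear regression** — ordinary least squares of daily weight on day
  index, fitted on the *non*-mid-date days and evaluated at the mid-date.
  This is a genuine prediction: the day being estimated never enters the
  fit. It requires at least `min_regression_points = 4` fitting days (and
  some spread in the day index); otherwise the estimate is `NA` rather
  than an extrapolation from too little support.

The mean and median likewise return `NA` for a window with no surviving
daily values; missingness is carried through to the report as
`n_missing`, never silently dropped.

### Stage 3 — post-processing (`adg_threshold()`, `postprocess_daily()`)

Statistical fences can pass contamination that is large in absolute terms
but sits inside a wide within-window spread. The third stage bounds daily
values physiologically: a steer cannot plausibly deviate from its baseline
weight by more than roughly a month's worth of maximal growth. The
threshold is

```
threshold = max(ADG_table) × factor_days        (default factor_days = 30)
```

where the ADG table maps body-weight classes to target average daily gain
(kg/day) from national feeding standards. The package ships a clearly
labelled *synthetic* example table
(`inst/extdata/adg_table_synthetic.csv`, maximum 1.0 kg/day, hence a
±30 kg band) with values plausible for growing/fattening beef steers; for
real use, supply the table for your breed and standard via
`read_adg_table()`. Daily averages outside the inclusive band
`baseline ± threshold` are removed and the stage-2 estimators are re-run
on what remains, so every run reports both pre- and post-processing
estimates and their before/after contrast.

**Baseline policy.** The band must be anchored somewhere, and the choice
matters. The default, `policy = "window_median"`, anchors at the median of
the animal's own daily averages within the window being filtered. Within a
7-day window an animal's legitimate weight change is at most about three
days of growth (± ~3 kg), tiny against the ±30 kg band, so a
self-anchored band can never cut clean data — while a ±30 kg excursion
within one week is unambiguously an artefact. The alternative policies
`"previous_reference"` and `"previous_estimate"` anchor at the previous
window's static-scale value or pipeline estimate. These are natural when
windows are close together, but with monthly window spacing an animal
gaining above `threshold / gap ≈ 1 kg/day` has *legitimate* growth outside
a band anchored a month back, so the policy systematically removes clean
records from fast-growing animals. For that reason `window_median` is the
default; the other policies remain available (with the fallback order
previous reference → window median when no previous anchor exists) for
designs with tighter window cadence.

## Evaluation (`build_report()`, `test_battery()`)

Estimates are paired with the static-scale reference at each window
mid-date. Per window and pooled over windows ("Total"), the report gives
the number of pairs, missing estimates, predicted and reference means and
SDs, RMSE, mean absolute difference, and the percentage of animals whose
relative error is within ±5 % and ±10 % (inclusive, denominated by the
reference). `compare_configurations()` ranks the
(rule × estimator × post-processing) combinations by pooled RMSE,
breaking ties by the 5 % margin ratio.

The statistical battery treats each estimator's values and the reference
values as groups:

* pairwise **F-tests** of variance homogeneity against the reference
  (`stats::var.test()`);
* **Dunnett's test** of every estimator group against the reference
  (`multcomp::glht()` with a many-to-one contrast matrix);
* **Tukey's HSD** over all pairwise group differences
  (`stats::TukeyHSD()` on a one-way `aov`);
* **Kruskal–Wallis** (`stats::kruskal.test()`) with **Dunn's post-hoc
  z-tests**. Dunn's test is implemented in the package (rank-mean
  differences standardised with the tie-corrected Kruskal–Wallis
  variance, p-values adjusted by `stats::p.adjust()`, Holm by default)
  because no Dunn implementation is available among the package's
  dependencies; the implementation is verified in the test suite against
  hand-computed oracles, including the textbook case
  `[1,2,3]` vs `[4,5,6]` with `H = 3.857`.

The battery is also run on paired differences (estimate minus reference
per animal), which removes between-animal weight variance and is the more
sensitive test of estimator bias.

## The synthetic herd simulator

Real AWS streams are rarely shareable, so `simulate_aws()` generates a
campaign with full ground truth. Defaults (all overridable via
`sim_config()`):

| parameter | default | meaning |
|---|---|---|
| `n_animals` | 36 | herd size |
| `windows` | 3 × 7-day monthly windows | Feb/Mar/Apr 2019, mid-date on day 4 |
| `initial_weight_mean`, `_sd` | 330, 20 kg | herd weight at day zero |
| `adg_mean`, `adg_sd` | 0.8, 0.15 kg/day | per-animal growth rate |
| `visits_per_day_mean` | 4 | Poisson mean of visits per day |
| `visit_process` | `"poisson"` | or `"fixed"`, see below |
| `noise_sd` | 5 kg | Gaussian visit-level noise |
| `contamination_rate` | 0.05 | per-record contamination probability |
| `positive_offset_range` | 20–80 kg | residual feed / manure offsets |
| `negative_offset_range` | 60–200 kg | partial-stance offsets |
| `reference_noise_sd` | 0 kg | static-scale noise |

Each animal grows exactly linearly from an initial weight and ADG drawn
once per animal; every simulation is deterministic given `seed`
(trajectories, visits and contamination use `seed`, `seed + 1`,
`seed + 2`). The simulator *emulates* the error structure that motivates
the pipeline — sparse two-sided heavy contamination over symmetric noise
on a linear trend — and deliberately does *not* emulate diurnal gut-fill
cycles, non-linear growth, illness-related weight loss, animal-specific
visit habits, or scale drift. It is a test bed for the pipeline's
statistical behaviour, not a biological model.

The `visit_process = "fixed"` option gives every animal exactly
`visits_per_day_mean` visits per day. It exists for degenerate-limit
verification: with noiseless, uncontaminated data on a complete balanced
schedule, every filter keeps everything and every estimator returns the
true mid-date weight exactly, and the test suite asserts this identity.
Under Poisson visits the identity cannot hold as an exact statement — a
Poisson(4) day is empty with probability ≈ 1.8 %, shifting the window
mean off the mid-date, and with unbalanced visit counts the 1.5·SD rule
can clip the legitimate extremes of even a noiseless trending series
(e.g. daily counts (1,4,4,4,4,4,4) over a 7-day trend give a
standardised extreme of ≈ 1.8 > 1.5). These are intrinsic properties of
the methods, worth knowing when interpreting SD-rule results on sparse
data.

## Evaluation design used in the test suite

The acceptance-style checks in `tests/testthat/test-acceptance.R` pin the
pipeline's claims quantitatively, across simulation seeds 1–20 at the
default problem size (36 animals × 3 windows, ≈ 3,000 records per run):

* filter implementations match brute-force oracles on thousands of random
  vectors, including exact boundary constructions;
* the noiseless fixed-schedule limit is an exact identity end to end;
* post-processing never increases the *stage-level* pooled RMSE — pooled
  over all windows and all (rule × estimator) configurations per seed —
  and reduces it on average. The stage level is the honest unit here:
  for an individual SD-rule configuration, band-clipping bias can cancel
  against a surviving contaminated day, and removing that day in
  post-processing occasionally exposes the bias (a few hundredths of a
  kilogram on a small fraction of seeds). Post-processing also never
  reduces any configuration's 10 % margin ratio;
* the Tukey + median + post-processed configuration is at least as
  accurate (pooled over seeds) as its SD-rule counterpart;
* the battery's tests hold their nominal size: on null simulations
  (identical group distributions) the Kruskal–Wallis and F-test rejection
  rates at α = 0.05 fall within Monte-Carlo bounds.

The worked numbers shown in the README (seed 1: pooled RMSE ≈ 1.1 kg for
Tukey + mean, 100 % of animals within 5 %, all Dunnett-adjusted p-values
≈ 1) are produced by exactly this machinery and can be regenerated with
`scripts/acceptance.R`.

## Limitations

* The pipeline estimates weight at window mid-dates only; it is not a
  continuous growth-curve model.
* The linear-regression estimator assumes within-window linearity; over
  windows much longer than a week, or around diet transitions, this
  degrades.
* The ADG band assumes the supplied ADG table brackets the herd's true
  growth; an overly tight table would cut legitimate data, an overly
  loose one filters nothing.
* The `previous_reference` / `previous_estimate` baseline policies are
  only appropriate when consecutive windows are separated by much less
  than `threshold / ADG` days (see the baseline-policy discussion above).
* Dunnett and Tukey HSD assume approximate normality and variance
  homogeneity of group values; the Kruskal–Wallis/Dunn branch and the
  paired-difference battery are the fallback when those fail.
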