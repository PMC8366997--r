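---
title: "Patient similarity network stratification: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient similarity network stratification: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psnstrat)
```

## The problem and the model

Cancer survivors carry a substantial burden of cardiovascular disease, partly
attributable to cardiotoxic therapy. Given longitudinal clinical records --
echocardiographic measurements, laboratory values, demographics -- the goal is
an *unsupervised* stratification of patients into subgroups that differ in
their subsequent risk of de novo cardiac events (atrial fibrillation, coronary
artery disease, heart failure, myocardial infarction, stroke) and of death.

The procedure has four stages.

1. **Trajectory features.** Each longitudinal variable is summarized per
   patient by five quantities: the maximum and minimum over all follow-ups,
   the ordinary-least-squares slope versus time, and the maximum increase and
   maximum decrease within a three-month window. Together with static
   variables these form a patient-by-feature matrix, which is cleaned of gross
   outliers, mean-imputed, and z-scored.
2. **Patient–patient similarity.** Cosine similarity
   \(\;s_{AB} = \sum_i A_i B_i \big/ \sqrt{\sum_i A_i^2}\sqrt{\sum_i B_i^2}\;\)
   over the z-scored feature vectors (Pearson correlation, the cosine of the
   row-centred vectors, is available as an alternative metric). Cosine
   compares the *direction* of a patient's deviation profile, not its
   magnitude, which is what makes the method robust to patient-level severity
   scaling (see the benchmark below).
3. **Clustering on similarity profiles.** Each patient's clustering feature
   vector is its full row of the similarity matrix. K-means (Lloyd iterations
   from a greedy k-means++ initialization, objective
   \(SSE = \sum_i (X_i - \bar X)^2\)) partitions the patients. The network
   *thresholding* step (density-minimizing cutoff) is used only for export
   and visualization; clustering always sees the dense matrix.
4. **Clinical validation.** Kaplan–Meier and Nelson–Aalen estimates per
   subgroup; omnibus and all-pairwise log-rank tests with Benjamini–Hochberg
   adjustment; Cox proportional-hazards ratios against the lowest-risk
   subgroup; chi-squared enrichment of binary outcomes; per-period event
   percentages; and biomarker-threshold survival analyses.

New patients are assigned by computing their similarities *to the training
patients only* (the profile axis of the fitted model), after applying the
training set's imputation means and scaling, and taking the nearest centroid.
This makes train/test validation leakage-free by construction.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `window_days` | 92 | days | "Three months" fixed at the longest calendar quarter. |
| `z_limit` | 4 | robust z | Outlier flagging threshold; `Inf` disables. |
| `metric` | cosine | — | PCC available; cosine is the primary metric. |
| `K` | 4 | clusters | Or chosen by `select_k()` (below). |
| `grid_step` | 0.05 | similarity | Density-profile cutoff increment. |
| `varnet_fraction` | 0.15 | — | Top fraction of variable-pair correlations kept. |
| `alpha` | 0.05 | — | Significance level for K selection. |
| biomarker bins | guideline | pg/mL, µg/L | NT-proBNP 0–125, 125–900, >900; troponin T ≤0.01, 0.01–0.05, >0.05. |

## Numerical choices

* **Slope** is the OLS coefficient of value on time; it is `NA` with fewer
  than two distinct times. Duplicate timestamps are averaged first; feature
  derivation is invariant to row order.
* **Windowed excursions** scan all ordered pairs within the window, are
  floored at zero, and are `NA` when no pair qualifies.
* **Outlier rule.** Robust z with the column median as centre and the MAD
  *floored at the classical sd* as scale. A plain MAD over-flags the minority
  modes of genuinely multimodal columns (a biomarker with distinct patient
  subpopulations), and mean imputation of those flags destroys exactly the
  correlation structure the variable networks look for; gross errors inflate
  both scales but exceed them by orders of magnitude, so they are still
  caught.
* **Scaling** uses the population (divide by *n*) standard deviation by
  default (`sd_type = "sample"` switches). Imputed entries equal exactly 0
  after scaling. Zero-variance columns are centred, flagged, and not scaled;
  all-missing columns are dropped with a warning.
* **Zero-norm patients** get similarity 0 to everyone, with a warning.
* **Density cutoff.** At each cutoff the network keeps nodes with at least
  one retained edge; density is computed over those nodes. Without this
  convention "minimum density" is degenerate (the largest cutoff always
  wins). Ties in the argmin break toward the smaller cutoff, which retains
  more patients. Cutoffs with empty networks are excluded from the argmin but
  reported.
* **K-means.** Greedy k-means++ seeding (each new centre is the best of
  4 + log K candidates drawn proportionally to squared distance), Lloyd
  iterations until the assignment is stable, SSE asserted non-increasing at
  every step. An emptied cluster triggers one re-seed, then an error. Labels
  are canonicalized by descending cluster size. `psn_fit()` uses five
  restarts and keeps the lowest SSE; `stability_analysis()` uses single
  restarts on purpose, since its question is exactly how sensitive the
  optimum is to the initial state.
* **Nearest-centroid ties** break deterministically toward the
  lowest-indexed cluster.
* **AMI** uses the hypergeometric expected mutual information and the
  arithmetic-mean entropy normalizer.
* **Competing risks** are handled as cause-specific censoring: for the de
  novo event endpoint, death before a cardiac event censors the patient at
  the death date. Cumulative hazards are Nelson–Aalen (`-log` Kaplan–Meier
  is trivially available from the same curves).
* **Event on the therapy-start day** counts as de novo (the `>= 0`
  convention).
* **BH families** are all cluster pairs within one endpoint and one K.
* **Percentage intervals** are Wilson score intervals.
* **Time-dependent AUROC** is the cumulative/dynamic variant with inverse
  probability of censoring weights from the Kaplan–Meier estimate of the
  censoring distribution; tied scores count 1/2; evaluation times with no
  cases or no controls are skipped with a note.

## Outcome-guided choice of K

The SSE elbow is typically smooth, so `select_k()` codifies an
outcome-guided rule: a candidate K qualifies when, for both endpoints
(overall survival and de novo cardiac events), the omnibus log-rank p is
below `alpha` *and* every pairwise BH-adjusted log-rank comparison is
significant; among qualifying K the largest is selected, favouring the
finest clinically meaningful stratification. The full per-K table is always
returned, because the original choice of a working K in practice combines
such statistics with clinical judgement — the automated rule is a codified
approximation and is flagged as such in the report.

## What the synthetic cohort emulates

`generate_cohort()` produces a referral cardio-oncology cohort with known
ground truth:

* **Four subgroup archetypes** (sizes 13.5/39/20.5/27%): cardiac-dominant
  high-risk (elevated NT-proBNP and troponin T, reduced LVEF, dilated
  ventricle), a low-risk reference, a renal/metabolic phenotype (elevated
  creatinine and BMI), and an advanced-cancer/cachexia phenotype (elevated
  NT-proBNP, low BMI and hemoglobin, late tumor stage). The archetype
  directions are deliberately non-collinear: cosine geometry separates
  profile *directions*, so subgroups that differ only in magnitude along a
  shared direction are not identifiable by this method — a real limitation
  of the model, reproduced faithfully by the generator.
* **Mean shifts** of `feature_shift` (default 2) nominal standard deviations
  along those directions; within-subgroup spread is `within_sd` (default
  0.5) of the nominal sd, since the cohort-level spread already absorbs the
  between-subgroup shifts. At these defaults the subgroup biomarker levels
  are clinically sensible (e.g. NT-proBNP ≈ 800 vs 300 pg/mL; LVEF ≈ 44 vs
  58%).
* **A within-subgroup severity axis** (`axis_frac`, default 0.4): part of
  the within-subgroup variance lies along the subgroup's own archetype
  direction, so NT-proBNP, troponin and LVEF genuinely co-vary inside the
  cardiac-dominant subgroup. This is what the per-subgroup variable networks
  detect.
* **Trajectories**: per-patient linear value-versus-time with per-subgroup
  slopes (e.g. rising NT-proBNP, declining LVEF in the high-risk group),
  measurement error per visit, and clamping to physiologic ranges.
* **Visits**: a mandatory baseline at day 0 plus a homogeneous Poisson
  process (default 1/year) quantized to a 30-day grid and confined to a
  5-year surveillance window (`surveillance_years`), reflecting that
  imaging concentrates around active treatment. Every patient has at least
  two visits. The quantization also keeps two-visit slope estimates away
  from near-zero time spans, and the surveillance window prevents the
  derived features from encoding follow-up duration — an immortal-time
  artifact that would otherwise let the clustering "discover" spurious
  survival-distinct subgroups.
* **Outcomes**: cause-specific exponential event times per subgroup
  (default totals 0.20/0.02/0.10/0.05 per year, split over the five event
  types with weights 0.3/0.2/0.3/0.1/0.1), exponential death
  (0.08/0.02/0.045/0.13 per year — all subgroup pairs survival-distinct),
  independent exponential censoring (0.08/year) truncated at a 20-year
  horizon, and a 17% chance of a preexisting event dated uniformly within
  two years before therapy start.
* **Missingness**: MCAR at 5% per measurement.
* **Correlated noise** via a multiplicative log-normal patient severity
  factor (`severity_sd`): sicker patients deviate more on *everything*,
  which corrupts Euclidean geometry on raw features much more than cosine
  profile geometry. The relative-performance benchmark uses
  `severity_sd = 0.6`.

What the generator does *not* emulate: informative missingness, ICD coding
noise, medication exposure, non-linear trajectories, heavy-tailed laboratory
distributions, or between-variable correlation beyond the severity axis and
severity factor. Passing tests on this cohort therefore demonstrate the
pipeline's internal correctness and its behaviour under the stated
generative assumptions — not performance on real EMR data.

## Problem sizes used in the test suite

Unit tests run on cohorts of 60–1,000 patients; the end-to-end benchmarks
(partition recovery, restart stability, the correlated-noise comparison,
outcome-guided K selection) use 2,000 patients with four planted subgroups;
statistical calibration uses 1,000 two-group null log-rank simulations
(n = 200 each) and 500 Cox replicates at n = 5,000. These sizes give
Monte-Carlo standard errors a few times smaller than the tolerances being
asserted.

## Known limitations

* Cosine similarity is linear; genuinely non-linear patient similarity is
  out of reach of this metric.
* K-means on similarity profiles inherits k-means' preference for compact,
  roughly balanced clusters; very rare phenotypes may be absorbed.
* The outcome-guided K rule tests many hypotheses; its selected K should be
  treated as a working stratification, not an inferential claim.
* Mean imputation after outlier removal attenuates within-subgroup
  correlations when flags concentrate in one subgroup; the sd-floored
  robust scale mitigates but does not eliminate this.
* Follow-up-dependent features (extremes, slopes) can encode observation
  time; the surveillance-window design limits, but real data would need the
  same scrutiny.
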