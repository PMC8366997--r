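# psnstrat

Unsupervised cardiac-risk stratification of cancer patients from
longitudinal clinical records, via patient–patient similarity networks.

Cardiovascular disease is a leading cause of death in cancer survivors, and
clinicians lack good tools to predict which patients undergoing cancer
therapy will develop cardiac dysfunction (atrial fibrillation, coronary
artery disease, heart failure, myocardial infarction, stroke). `psnstrat`
implements a network-based stratification pipeline for this setting:

1. **Trajectory features.** Every longitudinal variable (echocardiographic
   measures, cardiac biomarkers, labs) is summarized per patient by its
   maximum, minimum, OLS slope versus time, and maximum increase/decrease
   within a three-month window; features are outlier-screened, mean-imputed
   and z-scored.
2. **Similarity network.** Cosine similarity over the feature vectors,

   `s(A, B) = Σᵢ AᵢBᵢ / ( √Σᵢ Aᵢ² · √Σᵢ Bᵢ² )`,

   compared across all patient pairs (Pearson correlation available as an
   alternative metric). A density-minimizing cutoff thresholds the network
   for export/visualization.
3. **Subgroup discovery.** Seeded k-means (greedy k-means++ and Lloyd
   iterations) on each patient's *similarity profile* — their row of the
   dense similarity matrix — with outcome-guided selection of the number of
   clusters, and 100-restart ARI/AMI stability assessment.
4. **Clinical validation.** Kaplan–Meier and Nelson–Aalen curves, omnibus
   and pairwise log-rank tests with Benjamini–Hochberg adjustment, Cox
   hazard ratios against the lowest-risk subgroup, chi-squared outcome
   enrichment, per-period event percentages, biomarker-threshold survival,
   per-subgroup clinical-variable correlation networks (top-15% edges,
   degree/betweenness ranking), and leakage-free random-/time-split
   train–test validation with time-dependent AUROC.

Because institutional EMR data cannot ship with a package, `psnstrat`
includes a seeded synthetic cardio-oncology cohort generator
(`generate_cohort()`) with planted subgroups, longitudinal trajectories,
cause-specific hazards and censoring, so every stage of the pipeline is
testable end to end with known ground truth. See the methods vignette
(`vignettes/methods.Rmd`) for the model, its assumptions and all design
decisions.

## Worked example

```r
library(psnstrat)

coh <- generate_cohort(cohort_config(n_patients = 500, seed = 7))
fit <- psn_fit(coh, K = 4, seed = 1)
outcomes <- classify_events(coh$events)
summary(fit, outcomes = outcomes)
```

```
psn_fit: K = 4 on 500 patients (cosine similarity), SSE = 5278
  cluster sizes: 200/132/106/62

De novo cardiac event enrichment by cluster:
 cluster   n n_event  rate lower upper        p test
       1 200      29 0.145 0.103 0.200 1.70e-06 chi2
       2 132      25 0.189 0.132 0.265 3.11e-02 chi2
       3 106      50 0.472 0.379 0.566 2.17e-08 chi2
       4  62      26 0.419 0.305 0.543 2.24e-03 chi2

Omnibus log-rank p: overall survival 5.61e-18; de novo events 3.32e-18
```

The four discovered subgroups range from 14.5% to 47% de novo cardiac-event
incidence (Wilson 95% intervals shown), and both overall survival and de
novo events separate strongly across subgroups by the omnibus log-rank
test. Against the generator's planted subgroup labels,

```r
adjusted_rand_index(fitted(fit), coh$truth$subgroup)
#> [1] 0.9296479
```

an adjusted Rand index of 0.93 — the unsupervised pipeline recovers the
planted structure almost exactly. Held-out patients are assigned with
`predict(fit, newdata = ...)`, which applies the training preprocessing and
nearest-centroid assignment in the training similarity-profile space.

The whole pipeline (simulate → preprocess → network → cluster → outcomes →
variable networks → stability → split validation) runs from one seeded
configuration:

```r
res <- run_pipeline(run_config(seed = 42), "runs/demo")
```

writing every artifact plus an md5 manifest; identical configurations
reproduce identical hashes. A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

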