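# t2oa — multi-component T2 relaxometry and early knee-OA classification

Early knee osteoarthritis changes cartilage composition before anything is
visible on radiographs or morphological MRI. Quantitative T2 mapping can
see those changes, but the conventional readout — one mono-exponential T2
averaged over the whole cartilage — blurs them away. `t2oa` implements the
fuller analysis as a tested R package plus a set of analysis drivers, for
imaging scientists who want to evaluate multi-component T2 biomarkers or
validate the surrounding statistical machinery:

* **Signal models.** Voxel decays over preparation time *t* as
  mono-exponential `S(t) = A e^(-t/T2)`, bi-exponential
  `S(t) = A [f e^(-t/T2s) + (1-f) e^(-t/T2l)]` (fast macromolecule-bound +
  slow bulk water pools) or stretched-exponential
  `S(t) = A e^(-(t/T2)^alpha)`, with complex amplitude and i.i.d. Gaussian
  channel noise.
* **Experiment design.** Fisher information / Cramér–Rao lower bounds for
  any schedule, and CRLB-driven preparation-time optimization (exhaustive
  or greedy-exchange search).
* **Voxel fitting.** Bounded multi-start Levenberg–Marquardt on the stacked
  complex channels, with the field's box constraints (T2 0.1–400 ms, alpha
  0.1–1, f 0.01–0.99, T2s 0.1–10 ms, T2l 20–300 ms), map assembly and
  convergence flagging.
* **Features and univariate statistics.** Six-sub-region cartilage ROI
  means (PC, TrC, MFC, MTC, LFC, LTC + voxel-weighted Global), in-fold age
  adjustment `Y ~ Age + Group + Age x Group`, Mann–Whitney U with Cliff's
  delta, Benjamini–Hochberg FDR, permutation MANOVA.
* **Classification and evaluation.** Regularized LDA (shrunk pooled
  covariance) under repeated, stratified, nested cross-validation;
  bootstrap AUC CIs, permutation tests, DeLong comparisons, calibration and
  Brier scores, decision-curve net benefit, fold-weight stability.
* **Synthetic cohorts.** A generator that emulates a 26 healthy / 26
  early-OA study (group demographics, sub-regional bi-exponential parameter
  distributions, the 7-point pTE schedule {0, 4.3, 9, 33, 33, 55, 55} ms at
  SNR 50), including an exact-null variant and controlled group shifts for
  calibration and power experiments.

## Worked example

```r
library(t2oa)

# study design: detectable effect of 7% on a 34 +/- 2.6 ms global T2
n <- sample_size_two_means(mean = 34, sd = 2.6, detectable_fraction = 0.07,
                           alpha = 0.05, power = 0.80)
n
#> [1] 20
#> attr(,"power")
#> [1] 0.8053488
total_scan_time(7, 3, 12)$label
#> [1] "22 min 24 s"

# what the 7-point schedule can resolve at SNR 50 (healthy BE medians)
sqrt(crlb(be_params(100, 0.22, 5.7, 54.1), default_pte_schedule(), 2))
#>       re_a       im_a          f   t2_short    t2_long
#> 1.98026305 1.21791951 0.08898291 3.10731967 7.96817978

# simulate a null cohort and check the pipeline finds nothing
cohort <- generate_null_cohort(cohort_config(), seed = 1)
ft <- cohort_true_features(cohort)
X <- as.matrix(ft[, feature_columns(ft)])
res <- nested_cv(X, ft$group, age = ft$age,
                 config = cv_config(repeats = 5), seed = 1)
res
#> nested CV (5x5, 5 repeats): mean AUC 0.429 (pooled 0.430)
```

The per-group sample size of 20, the 22 min 24 s protocol duration, and a
null AUC rattling around 0.5 are the expected answers; the CRLB line shows
why per-voxel bi-exponential parameters need sub-regional averaging (an
absolute f bound of 0.089 and a T2-short bound of 3.1 ms at a true value
of 5.7 ms).

## Analysis workflow

The numbered drivers under `analysis/` run the whole study on synthetic
data and write tables under `results/`:

| script | what it does |
|---|---|
| `01_design_schedule.R` | CRLB precision of the 7-point schedule per model; small-grid design search demo |
| `02_simulate_cohort.R` | simulates the 26 + 26 cohort (images + covariates + latent truth) |
| `03_fit_models.R` | voxelwise ME/SE/BE fitting, ROI means, feature tables |
| `04_univariate_stats.R` | Mann–Whitney / Cliff's delta / BH battery over BE features |
| `05_classify.R` | nested-CV regularized LDA for all models and scopes, with CIs, permutation tests, DeLong, calibration, decision curves, weight stability |
| `06_null_calibration.R` | the same machinery on 200 exact-null cohorts |

On the shipped synthetic cohort, `05_classify.R` prints, per model/scope,
lines such as

```
be_multi  AUC 0.88 [0.79, 0.97], perm p = 0.005, Brier 0.14, top: t2_short_MFC, t2_long_LTC, t2_long_LFC
```

with the bi-exponential multi-ROI model strongest and the mono-exponential
global model weakest — the ordering the method is designed to expose
(absolute synthetic AUCs run higher than on real patients, since the
generator omits the physical confounders discussed in the vignette).

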