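---
title: "Multi-component T2 relaxometry and early-OA classification: models, design and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-component T2 relaxometry and early-OA classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2oa)
```

## The problem

Early knee osteoarthritis alters the composition of articular cartilage —
proteoglycan depletion, collagen disorganization, shifts in water
compartmentation — before any structural damage is visible on radiographs
or morphological MRI. Quantitative T2 mapping probes these changes
noninvasively, but the conventional summary (a single mono-exponential T2
averaged over the whole cartilage) dilutes subtle, spatially localized
effects twice over: once by forcing a one-pool model onto multi-compartment
tissue, and once by global averaging. This package implements the
alternative analysis end to end: multi-component decay models fitted
voxelwise to preparation-time-encoded complex images, sub-regional feature
extraction, and a regularized linear discriminant evaluated under nested
cross-validation — together with the synthetic cohort machinery needed to
validate every stage when real patient data cannot be shared.

## Signal models and noise

Each acquired volume is weighted by a preparation time $t$ (pTE). Three
voxel decay models compete:

* mono-exponential (ME): $S(t) = A\,e^{-t/T_2}$, with $T_2 \in [0.1, 400]$ ms;
* bi-exponential (BE): $S(t) = A\,[f\,e^{-t/T_{2,s}} + (1-f)\,e^{-t/T_{2,l}}]$,
  with $f \in [0.01, 0.99]$, $T_{2,s} \in [0.1, 10]$ ms,
  $T_{2,l} \in [20, 300]$ ms — a fast macromolecule-bound pool plus slow
  bulk water;
* stretched-exponential (SE): $S(t) = A\,e^{-(t/T_2)^\alpha}$,
  $\alpha \in [0.1, 1]$, a heterogeneity continuum with $\alpha = 1$
  recovering ME.

$A$ is complex; the noise is i.i.d. zero-mean Gaussian on the real and
imaginary channels with common $\sigma$ (channel correlation is not
modeled). Two conventions matter numerically: $0^\alpha := 0$ so
$S(0) = A$ exactly for every $\alpha$, and the disjoint BE boxes
($T_{2,s} \le 10 < 20 \le T_{2,l}$) make the two pools identifiable without
post-hoc sorting. One consequence worth stating plainly: because $f$ cannot
reach 0, the BE family does not strictly contain ME — a mono-exponential
signal is representable only up to a short-pool contamination of
$0.01\,A$, and tests of the nesting property carry exactly that allowance.

## Experiment design via the Cramér–Rao bound

`crlb()` evaluates, for a model, nominal parameters, schedule and noise
level, the minimum variance any unbiased estimator can achieve: the
diagonal of the inverse Fisher information in the real parameterization
$(\mathrm{Re}\,A, \mathrm{Im}\,A, \theta)$, which matches the fitting
parameterization downstream. `optimize_schedule()` minimizes the normalized
sum $\sum_i w_i\,\mathrm{CRLB}_i/\theta_i^2$ over multisets of grid times —
exhaustively when the multiset count is small, otherwise by deterministic
greedy exchange, with the strategy recorded in the output. The nominal
tissue parameters and weights are explicit arguments (defaults: the
healthy-cartilage BE medians of `be_reference()`), because a designed
schedule is only optimal *for* a stated tissue; the shipped 7-point
protocol $\{0, 4.3, 9, 33, 33, 55, 55\}$ ms, with its repeated long
preparations entering the likelihood as independent samples, is taken as an
input, not re-derived.

The bound also calibrates expectations. At SNR 50 (per-channel
$\sigma = |A|/50$) on the 7-point schedule at healthy global medians, the
relative CRLB standard deviations are roughly 2% for ME $T_2$, 10%/8% for
SE $T_2$/$\alpha$, and 40%/55%/15% for BE $f$/$T_{2,s}$/$T_{2,l}$. Per-voxel
bi-exponential parameters are intrinsically imprecise at this SNR; the
usable measurement is the sub-regional mean, and simulation-based recovery
checks must be read against these floors rather than against a uniform
precision target.

## Voxel fitting

`fit_voxel()` minimizes the stacked real/imaginary sum of squares with the
complex amplitude free and box constraints on $\theta$, using bounded
Levenberg–Marquardt with analytic Jacobians. Initialization is a
deterministic coarse grid over the nonlinear parameters (ME/SE $T_2$ at
$\{5, 20, 50, 150\}$ ms, $\alpha$ at $\{0.4, 0.7, 1.0\}$; BE $f$ at
$\{0.1, 0.3, 0.5\}$, $T_{2,s}$ at $\{2, 6\}$, $T_{2,l}$ at $\{40, 120\}$),
with the amplitude profiled linearly from the data at each start; the best
start wins, and the returned residual never exceeds any initialization
residual. Tolerances are 1e-10 on function and step, 500 iterations per
start. Degenerate voxels (all-zero signal, or no successful start) come
back flagged rather than as errors, and flagged voxels are excluded from
ROI averaging and counted. Repeated pTEs are separate residual terms — no
pre-averaging — which is what makes the repeat acquisitions an SNR gain in
the likelihood sense.

## Sub-regional features

Label maps use the package's integer legend (PC=1, TrC=2, MFC=3, MTC=4,
LFC=5, LTC=6), written into every sidecar. `extract_roi_means()` averages
valid voxels per label; the `Global` summary is the voxel-weighted mean
over the union of labels — not the mean of ROI means, a distinction that
matters whenever regions differ in size, and recorded here as the package's
convention since either reading is defensible. Feature tables are
parameter-major with the fixed ROI order (PC, TrC, MFC, MTC, LFC, LTC),
giving 1/2/3 global and 6/12/18 multi-ROI features for ME/SE/BE.

## Age adjustment

Cartilage T2 drifts with age, and in this design age is confounded with
group. Features are adjusted by per-feature OLS
$Y \sim \text{Age} + \text{Group} + \text{Age} \times \text{Group}$ on the
age-centered design, after which
$Y_{\text{adj}} = Y - (\hat\beta_{\text{age}} +
\hat\beta_{\text{int}}\,g)\,(\text{age} - \bar a_{\text{train}})$.
This subtracts the group-specific age slope while preserving the group
intercept difference — the disease signal. The regression alone does not
define "the adjusted value"; this residualization is an interpretive choice
and is therefore stated prominently.

Inside cross-validation the adjustment is refit on the training side of
every split. Test subjects are adjusted with the *training-prevalence*
slope ($g$ set to the training mean of the label), never their own label: a
procedural test asserts that corrupting held-out labels cannot change
held-out scores. This detail is not pedantry. With group-specific ages, the
noisy fitted slopes correlate with the fitted group contrast, and applying
label-dependent adjustment to test subjects whose age predicts their label
inflates the null AUC of this pipeline to about 0.61 in simulation. The
exact-null generator therefore draws *all* subject attributes — covariates
included — from one distribution, and the permutation test permutes labels
before the entire nested run, which keeps it exact even under confounding.

## Univariate battery

Group differences per feature use the Mann–Whitney U with midranks
(exact enumeration when both groups are $\le 20$ and tie-free, otherwise
the tie-corrected normal approximation with continuity correction), and
Cliff's $\delta = 2U/(n_1 n_2) - 1$ from the same statistic.
Benjamini–Hochberg step-up controls the FDR across features. Separation of
(possibly multivariate) discriminant scores is tested by permutation with
the Lawley–Hotelling trace $\mathrm{tr}(W^{-1}B)$ — affine-invariant, so
score rescaling is irrelevant; which eigenvalue statistic the original
MATLAB toolboxes use internally is not documented, so the choice is stated
here as this package's own.

## Regularized LDA and nested cross-validation

With up to 18 correlated features and 52 subjects, the pooled covariance
needs shrinkage:
$S(\lambda) = (1-\lambda)S + \lambda\,\frac{\mathrm{tr}(S)}{p}I$, weights
$w = S(\lambda)^{-1}(\mu_1 - \mu_0)$, posteriors from the shared-covariance
Gaussian model with empirical prevalence as prior. $\lambda = 0$ with
$p \ge n$ is refused with instructions rather than silently pseudo-inverted.

Evaluation is nested: 5 stratified outer folds estimate performance, 5
inner folds select $\lambda$ from
$\{0, 0.01, 0.1, 0.3, 0.5, 0.7, 0.9, 1\}$ by pooled inner out-of-fold AUC
(ties break toward the larger, more stable $\lambda$), and the whole
procedure repeats 20 times with reshuffled folds. All preprocessing —
adjustment and standardization — is refit on the training side of every
split, outer and inner. Whether to pool out-of-fold scores into one ROC or
average per-repeat AUCs is ambiguous in the field's phrasing; both are
computed, with the mean of per-repeat pooled AUCs as the headline
(`auc_mean`) and the pooled-mean-score AUC (`auc_pooled`) alongside.
Uncertainty comes from 2000 subject-level bootstrap resamples (percentile
2.5/97.5, class-degenerate resamples redrawn); significance from label
permutation of the entire nested run,
$p = (1 + \#\{\mathrm{AUC}^* \ge \mathrm{AUC}\})/(1 + n_{\text{perm}})$;
model comparisons from DeLong's placement-value test; clinical usefulness
from 10-bin calibration curves with Brier scores and from net benefit
$TP/N - (FP/N)\,p_t/(1-p_t)$ on a 0.05–0.95 threshold grid against
treat-all/treat-none. Fold weights (standardized scale) feed the stability
summary $|\bar w|/\mathrm{sd}(w)$ per feature, optionally with its own
label-permutation p-values.

## The synthetic cohort

`generate_cohort()` emulates the statistical structure of a 26 + 26
case–control study: group ages 51.5 ± 8.4 vs 61.8 ± 7.6 years truncated to
40–75, female fractions 10/26 vs 19/26, BMI 27.3/27.8, and per-subject
latent BE parameters drawn per sub-region around group medians with
IQR-derived spreads (`sd = IQR/1.349`, a normality approximation). Ground
truth is always bi-exponential — ME and SE fits to these data are
deliberately misspecified, as on real cartilage. Images render each
sub-region as a voxel block at the 7-point schedule with SNR 50 at $t = 0$
(both are configuration knobs; the field reports no voxelwise SNR, so 50
is this package's realistic default). Out-of-box draws are truncated to
the box and counted. The generator does *not* attempt anatomy, partial
volume, spatial noise correlation, $B_0$/$B_1$ or magic-angle effects, or
vendor differences — so passing pipelines here demonstrates statistical
correctness of the machinery, not robustness to those physical
confounders.

`generate_null_cohort()` draws both groups — covariates included — from the
healthy distributions with labels assigned independently; `group_shift_sd`
adds controlled effects (e.g. 1.5 between-subject SDs on the medial
compartments) on top of the identical-groups backbone for power
experiments.

## Problem sizes and numerical choices

The shipped validation suite uses sizes chosen for desk-scale runs while
keeping every estimate's Monte-Carlo error well inside its decision band:
200 null cohorts at 3×3 folds with a 39-permutation exact test for
calibration; 500 voxels per model at SNR 50 for recovery; 50 end-to-end
replicates at 2 voxels per sub-region with 5×5×2 nested CV for the shifted
cohort analogue; the acceptance script re-runs the null calibration at 200
cohorts with 5×5 folds. The analysis drivers under `analysis/` use a
4×4×1 sub-region grid (96 voxels per subject). Ties in ranks use midranks
throughout; random draws all flow from explicit integer seeds and every
randomized function restores the caller's RNG state.

## Known limitations

Per-voxel BE precision at realistic SNR sits at the Cramér–Rao floor
described above, so voxelwise BE maps are qualitative at SNR 50 even
though their sub-regional means are usable; the null calibration exercises
the statistical pipeline on latent features (the fitting stage's own null
behavior is covered separately by the recovery and end-to-end suites);
and the synthetic generator's independence assumptions (across ROIs'
noise, across voxels) make it a validation instrument, not a simulator of
scanner physics.
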