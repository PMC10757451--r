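---
title: "Lesion-aware ASL perfusion analysis: models, parameters and design choices"
author: "perfband"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Lesion-aware ASL perfusion analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`perfband` implements a complete perfusion analysis for chronic left-hemisphere
stroke: cerebral blood flow (CBF) quantification from arterial spin labelling
(ASL), lesion-aware region-of-interest (ROI) construction including
perilesional distance bands, whole-brain-normalized perfusion summaries,
a normality-gated battery of group comparisons, and two complementary
perfusion-language models (covariate-adjusted partial correlations and a
lasso with leave-one-out cross-validated penalty). Because subject-level
clinical imaging of this kind is rarely shareable, the package ships a
synthetic-cohort generator with known ground truth; every downstream stage is
exercised against planted effects.

## CBF quantification

ASL acquires interleaved *tag* volumes (arterial blood magnetically inverted)
and *control* volumes. Their difference is proportional to perfusion. The
package uses the single-compartment, single-delay kinetic model in its usual
closed form,

$$\mathrm{CBF} \;=\;
\frac{6000\,\lambda_p\,\Delta M\,e^{\mathrm{PLD}/T_{1b}}}
     {2\,\alpha\,T_{1b}\,M_0\,\bigl(1-e^{-\tau/T_{1b}}\bigr)}
\quad[\mathrm{ml}/100\,\mathrm{g}/\mathrm{min}],$$

with $\Delta M$ the mean control-minus-tag difference, $M_0$ the equilibrium
magnetization image, $\alpha$ the labelling efficiency, $T_{1b}$ the
longitudinal relaxation time of arterial blood (converted to seconds inside
the equation; all interfaces take milliseconds), $\tau$ the label duration
and PLD the post-labelling delay.

Defaults and why:

* `alpha = 0.72`, `t1_blood = 1650` ms — pCASL values appropriate for the
  3 T protocols this analysis targets.
* Two site presets: `site_a` uses $\tau/\mathrm{PLD} = 1470/1500$ ms and, because that
  protocol acquires no separate calibration image, the **first control
  volume** as $M_0$; `site_b` uses $1800/2000$ ms with a separate $M_0$
  volume.
* `lambda_p = 0.9` ml/g — consensus whole-brain partition coefficient; the
  quantity enters only as a global scale.
* Negative CBF voxels are **retained**. Clipping at zero would bias ROI means
  upward wherever the difference signal is noise-dominated; instead the map
  carries an `n_negative` attribute for reporting.
* No smoothing and no partial-volume correction are applied; with lesioned
  brains there is no agreed-on correction, and means over ROIs are the unit
  of analysis. Inputs are assumed co-registered; registration is out of
  scope.

The forward simulator (`simulate_asl`) and the inverse (`quantify_cbf`)
share one algebraic scale factor, so the noiseless round trip is exact by
construction and is asserted to $10^{-6}$ relative error in the tests.

## Lesion-aware ROIs and perilesional bands

Atlas ROIs become *effective* masks by removing lesioned voxels, CSF voxels
and voxels outside the brain mask. Lesion load is the percentage of the
*original* ROI covered by the lesion — exclusions do not change the
denominator. A voxel counts as CSF when its CSF probability is at least
`csf_threshold` (default 0.5) **and** CSF is its most probable tissue; the
conjunction avoids discarding boundary voxels where CSF is merely present.

Perilesional bands are shells at (0,5], (5,10] and (10,15] mm from the
lesion boundary. Distances come from an exact Euclidean distance transform
(separable lower-envelope algorithm) that honours anisotropic voxel sizes in
millimetres; iterated binary dilation was rejected because a
structuring-element "5 mm" is not 5 metric mm on anisotropic grids. The
half-open intervals make the three bands an exact partition of the 0-15 mm
shell, so no voxel is double-counted. Bands are restricted to the left
hemisphere, the brain mask and non-CSF tissue; voxels whose centres lie
within half a voxel of the mid-sagittal plane belong to neither hemisphere,
preventing left/right leakage in asymmetry statistics.

## Perfusion metrics

Each subject's ROI means are divided by the subject's whole-brain mean CBF
with the lesion masked; this removes inter-session and inter-scanner scale
(notably tagging-efficiency differences) and is verified by a
scale-invariance property test. The whole-brain mean includes CSF by default
(a `csf_mask` argument excludes it); only the lesion is masked.
Right-minus-left asymmetry is computed on adjusted values per homologous
pair. Subjects whose effective mask is empty for an ROI (e.g. the ROI is
fully lesioned) are excluded *pairwise* for that ROI rather than listwise,
preserving sample size elsewhere.

## Group statistics

Every two-sample comparison runs the same decision cascade: Shapiro-Wilk on
each group (gate $\alpha$ = 0.05 by default, configurable — the gate level is a
convention, not an estimate); if both pass, an F-test of variance
homogeneity chooses between the pooled t-test and Welch's test; if either
fails, the two-sample Wilcoxon rank-sum test runs. Paired comparisons gate a
paired t-test versus the signed-rank test on the Shapiro of the differences.
Wilcoxon p-values are exact for combined $n \le 25$ without ties and use the
normal approximation with continuity correction otherwise. All tests are
two-tailed, and each result carries a `decision_trace` with every gate
p-value, making the choice reproducible and auditable. Multiplicity is
controlled per family at `family_alpha / m`, where m is the number of atlas
ROIs per hemisphere (0.05/15 = 0.0033 for the 15-ROI default lookup of the
study design; 0.05/6 on the compact synthetic atlas). The demographics
check is a Pearson chi-square **without** continuity correction — with
Yates' correction the printed statistic for a 29/14 vs 19/6 table would be
roughly 0.22 rather than the 0.56 this convention reproduces.

Degenerate inputs are conventions, not errors: zero-variance paired
differences yield a flagged result with p = 1; a constant sample routes to
the rank test (Shapiro is undefined); a constant lesion-load covariate is
dropped from partial correlations (it carries no information and would make
the projection singular).

## Perfusion-language models

**Partial correlations.** For ROI perfusion $x$ and outcome $y$, both are
residualized on an intercept plus covariates (age, sex, months post-onset,
scanning site, lesion volume; optionally the ROI's own lesion load — never
for perilesional bands, which are lesion-free by construction) and the
Pearson correlation of residuals is reported with
$t = r\sqrt{df/(1-r^2)}$, $df = n - 2 - k$. The implementation is checked to
$10^{-10}$ against the independent inverse-correlation-matrix identity, and
is invariant under invertible affine maps of the covariate block.
Sex and site enter as 0/1 indicators.

**Lasso.** The design holds the covariates, adjusted perfusion of every left
atlas ROI and the three bands, and lesion load of every left atlas ROI.
Predictors are standardized to mean 0, sd 1; the outcome is centred via the
intercept but not scaled, so coefficients read "outcome units per predictor
sd". The objective is $\tfrac{1}{2n}\|y-\beta_0-X\beta\|^2 +
\lambda\|\beta\|_1$, solved by cyclic coordinate descent on Gram-matrix
statistics with warm starts down a log-spaced grid from the null threshold
$\max_j |\langle x_j, y-\bar y\rangle|/n$. Correctness anchors: the
$\lambda = 0$ limit equals OLS, the null threshold zeroes all coefficients,
Karush-Kuhn-Tucker residuals stay below $10^{-7}$ along the path, and the
whole path matches glmnet at matched penalties in the test suite. Because
penalty values are convention-bound (the $1/(2n)$ scaling), they are not
numerically comparable to penalties reported under other conventions; the
fit records this in its metadata.

The penalty is chosen by leave-one-out cross-validation minimizing mean
squared prediction error, with standardization recomputed inside every fold
(no leakage) and ties broken toward the larger penalty. Predictors missing
in more than 20% of subjects (e.g. perfusion of an ROI that is fully
lesioned in much of the cohort) are dropped before listwise deletion, which
keeps the complete-case sample near the full cohort. The reported $R^2$
($1 - RSS/TSS$) and RMSE describe the final refit on all data, consistent
with reporting a single $R^2$ per model next to the selected penalty.

A known property of this selection rule deserves emphasis: the CV-*minimum*
lasso is tuned for prediction, not support recovery, and routinely admits a
few small spurious coefficients alongside the true ones. On synthetic
cohorts with two planted ROI-behaviour couplings the planted ROIs are
recovered with correct signs essentially always, but the support is *exactly*
the planted pair in only a minority of seeds; a one-standard-error rule
would recover exact support far more often, but the minimum-MSE rule is the
documented procedure and is what the package implements. Consumers who need
sparser, more stable supports should read the coefficient table with this in
mind.

## The synthetic cohort

`simulate_cohort()` builds, per subject, everything the pipeline consumes.
What it emulates, with defaults:

* **Template**: a mirror-symmetric ellipsoidal brain on a
  $20 \times 24 \times 20$ grid of 2 mm voxels with WM core, GM band, CSF
  rim and ventricles (tissue probabilities form a partition of unity inside
  the brain); 4 language-analogue and 2 control ROI pairs placed by
  deterministic farthest-point packing in the left hemisphere and reflected
  exactly. ROIs are simple ellipsoids: the downstream statistics are
  agnostic to shape, and exact mirror symmetry is what makes laterality
  tests falsifiable. The compact grid keeps a 40-subject cohort's
  simulation-plus-analysis under a few seconds; all geometry is in physical
  mm, so nothing changes qualitatively on finer grids.
* **Ground-truth CBF**: GM baseline 55 ml/100 g/min (inside the normal
  35-80 range), WM 22; per-subject, per-ROI Gaussian offsets
  (sd 6 ml/100 g/min, scaled by local GM+WM fraction) model regional
  between-subject variability; patients additionally get a planted
  -8 ml/100 g/min deficit in left ROIs 1-2 and multiplicative perilesional
  suppression 0.85/0.95/1.00 over the three bands. CBF is zero in the
  lesion and in pure CSF.
* **Flow conservation** (`conserve_global_flow = TRUE`): each patient's
  planted focal deficit is redistributed as a tissue-weighted uniform
  increase over brain tissue outside all ROIs and outside the 0-15 mm
  shell, so the whole-brain mean is preserved. Without this, whole-brain
  normalization mechanically inflates every unaffected ROI's adjusted value
  in patients — on a compact synthetic brain the shift reaches a meaningful
  fraction of the between-subject spread and manufactures spurious
  contralesional group differences. Approximate conservation of total
  cerebral blood flow with post-stroke redistribution is also the
  physiological reading of contralesional findings in this literature.
* **Lesions**: one per patient, an ellipsoid of radius 5-9 mm (jittered,
  per-axis eccentricity 0.85-1.15) centred on left ROI 1, clipped to brain
  and hemisphere, reduced to its connected component — a single subcortical
  stroke analogue occupying roughly 1-6% of the brain.
* **ASL**: control volumes at $M_0 = 1000$, tags lowered by the forward
  kinetic model, i.i.d. Gaussian noise of sd 2 (0.2% of $M_0$) per volume;
  site A acquires 20 tag/control pairs with the first-control calibration,
  site B 8 pairs with a separate $M_0$ — mirroring a two-site design with
  different label timing. Sites and sex are independent Bernoulli draws
  (70% site A, 68% male) since they act as covariates only.
* **Behaviour**: six WAB-style scores, each
  `clip(intercept + sum w_r adj_r - sum v_r load_r + covariates + noise, bounds)`
  computed from *ground-truth* adjusted perfusion and lesion load, noise sd
  0.25 on the 0-10 subtest scale (2.5 for the 0-100 severity composite),
  clipping applied after noise so scores respect their bounds. Weights
  default to +8 on left ROIs 3-4; intercepts are anchored to an unlesioned
  template subject so targets land where configured. `recovery_config()`
  gives the weights-only variant used in the support-recovery experiments.
* **Reproducibility**: every subject draws from a private stream derived
  from (master seed, subject index), so cohorts are bit-reproducible and
  stable under resizing.

What it does **not** emulate: motion, transit-delay dispersion, background
suppression physics, spatially correlated perfusion noise (voxelwise
independence is the default; the study protocol gives no spatial covariance
to target), realistic cortical folding, or multi-lesion anatomy. Passing
tests therefore certify the *analysis machinery* — exclusion rules, metric
geometry, normalization algebra, test selection, selection-and-shrinkage
behaviour — under known truth, not robustness to MR artefacts.

## Numerical conventions

* Distances: voxel-centre to voxel-centre, mm; exact EDT, verified against
  an all-pairs oracle on $\le 16^3$ grids.
* Band intervals half-open on the left, closed on the right.
* Coordinate descent: tolerance $10^{-11}$ on coefficient changes
  (KKT residuals then sit near machine precision), warm starts, penalty
  grid of 60 points spanning three decades below the null threshold.
* CSV output rounds to 6 significant digits; reruns with the same seed are
  byte-identical.
* Lesion masks must be strictly binary on load; any other value is a
  validation error naming the subject and file.

## Limitations

Registration, lesion tracing and partial-volume correction are upstream
problems the package assumes solved. The synthetic brain is compact, so
absolute adjusted levels (e.g. band means sitting above 1 because the
whole-brain mean includes CSF) are not calibrated to clinical values —
orderings and planted contrasts are the meaningful quantities. The
minimum-MSE penalty rule overselects, as discussed above. Group tests treat
subjects as exchangeable within group; there is no mixed-effects modelling
of site beyond its inclusion as a covariate.
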