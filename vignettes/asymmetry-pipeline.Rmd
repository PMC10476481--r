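---
title: "Hemispheric asymmetry radiomics for early-AD staging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemispheric asymmetry radiomics for early-AD staging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Alzheimer's disease (AD) and its prodrome, mild cognitive impairment (MCI),
produce structural change that is not left-right symmetric: hippocampal
atrophy and gray-matter texture change tend to begin unilaterally, so the
*asymmetry* between homologous structures carries diagnostic signal before
absolute atrophy is obvious. `adasym` implements a complete classification
pipeline built around that idea. From a labelled T1-like MR volume it
extracts, per hemisphere and per structure (gray matter, white matter,
cerebrospinal fluid, hippocampus):

* **structure volume** (voxel count x voxel volume, mm^3);
* **first-order histogram statistics** — mean, population variance, and the
  energy $\sum_b p_b^2$ and entropy $-\sum_b p_b \log_2 p_b$ of a
  uniform-bin intensity histogram;
* **gray-level co-occurrence matrix (GLCM) statistics** — with
  $P(o,k)$ the normalised count of gray-level pairs $(o,k)$ at voxel offset
  $d\varphi$:
  energy $\sum P^2$, contrast $\sum (o-k)^2 P$, inverse difference moment
  $\sum P / (1+(o-k)^2)$, entropy $-\sum P \log_2 P$, and correlation
  $(\sum o\,k\,P - \eta_x\eta_y)/(\gamma_x\gamma_y)$ with marginal means
  $\eta$ and standard deviations $\gamma$;
* **run-length matrix (RLM) statistics** — with $R(i,j)$ the number of
  maximal collinear runs of level $i$ and length $j$ and $N_r$ the total run
  count: short/long-run emphasis (SRE/LRE), low/high gray-level run emphasis
  (LGRE/HGRE) and their four joint forms, all normalised by $N_r$.

That yields 144 features per subject (8 regions x 18 features). Two
asymmetry transforms then pair each left feature $\mathrm{Fea}_{o,L}$ with
its right counterpart $\mathrm{Fea}_{o,R}$:

$$\mathrm{Fea}_{o,D} = |\mathrm{Fea}_{o,L} - \mathrm{Fea}_{o,R}|, \qquad
  \mathrm{Fea}_{o,R^*} = \mathrm{Fea}_{o,L} / \mathrm{Fea}_{o,R},$$

giving five feature-set variants: *left*, *right*, *whole* (concatenation),
*difference*, and *ratio*. A Fisher-filter + SVM-wrapper sequential forward
selection picks a compact subset, and an RBF-kernel SVM classifies the two
clinical pairs NC-vs-AD and NC-vs-MCI under repeated nested
cross-validation. A monotonicity analysis flags features whose class means
change strictly monotonically across the NC → MCI → AD continuum.

## The classifier

The SVM decision function is kept in its dual form,
$f(x) = \operatorname{sgn}\big(\sum_o \beta_o y_o K(x_o, x) + q^*\big)$,
with three kernels available: polynomial $(x^\top x_o + 1)^u$, radial basis
$\exp(-|x - x_o|^2/u^2)$, and sigmoid $\tanh(C x^\top x_o + C)$. The dual is
solved by libsvm (through e1071); the package stores the support vectors,
dual coefficients and bias itself and reconstructs all decision values from
those parts, which the test suite checks against the solver to $10^{-8}$.
RBF is the default kernel, as the usual best performer at this feature
dimensionality. Features are standardised with training-fold means and
standard deviations before the SVM sees them; the same transform is applied
to the held-out fold.

## The phantom: what it emulates, and what it does not

No public dataset accompanies this problem setting, so the package ships a
seeded synthetic cohort generator that emulates the study conditions:
three classes (NC/MCI/AD) of 50 subjects each by default, ~1.5 mm isotropic
voxels, four bilateral structures, class-graded hemispheric asymmetry, and
MR-magnitude (Rician) noise. Each subject is built from nested ellipsoids
per hemisphere (CSF shell > WM shell > GM core > hippocampal blob, overlap
resolved hippocampus > GM > WM > CSF), mirror-symmetric before effects.

* **Volume effects.** A `volume_scale` of $s$ multiplies ellipsoid radii by
  $s^{1/3}$, so the parameter reads directly as a volume ratio. Note one
  geometric consequence: shrinking the hippocampus returns its released
  voxels to the enclosing gray matter, so a hippocampal effect also
  perturbs ipsilateral GM volume slightly — anatomically not unreasonable,
  and documented rather than suppressed.
* **Texture effects.** Each region carries a stationary correlated random
  field: white Gaussian noise smoothed by an isotropic Gaussian of width
  `correlation_length_vox` (voxels), standardised over the region and
  scaled to the structure amplitude. Longer correlation length means
  smoother texture: lower GLCM contrast, higher inverse difference moment —
  the test suite checks this monotonicity over a three-level smoothness
  sweep.
* **Class effects.** The shipped defaults encode asymmetry growing along
  the disease continuum: AD scales the left hippocampus to 70% of its
  mirror volume and multiplies the left-GM correlation length by 1.5; MCI
  sits halfway (85%, x1.25); NC is identity. The literature gives no
  quantitative effect sizes for early-AD asymmetry, so these were chosen
  once as a qualitative encoding of "asymmetry grows with disease stage"
  and are deliberately not tuned further: they reproduce orderings
  (NC-AD easier than NC-MCI; left-variant better than right-variant), not
  any particular accuracy percentage.
* **Subject variability.** Without per-subject variation, every subject of
  a class would have identical geometry and the classification problem
  would be degenerate (zero within-class variance). The generator therefore
  applies log-normal per-subject multipliers: whole-brain radii (sd 0.03,
  i.e. ~9% volumetric CoV across the brain), per-structure volume (sd
  0.05), and correlation length (sd 0.05) — values in the range of normal
  inter-subject volumetric variability. These are configuration fields
  (`jitter`), so fully deterministic phantoms are one argument away.
* **Noise.** Magnitude-MR noise is Rician: each voxel becomes
  $\sqrt{(I+n_1)^2 + n_2^2}$ with $n_1, n_2 \sim N(0, \sigma)$; the default
  $\sigma$ is 2% of the GM base intensity. At zero signal the output is
  Rayleigh with mean $\sigma\sqrt{\pi/2}$, which the tests verify.

What the phantom does **not** model: cortical folding, scanner k-space
physics, bias fields, registration error, or segmentation error (label maps
are supplied exactly). Passing tests on phantoms therefore demonstrate that
the pipeline recovers the kind of signal it targets under controlled
conditions — not clinical performance. Real-scan users must rigidly
register and segment their volumes upstream; the package starts at the
labelled-volume stage deliberately, because no registration/segmentation
algorithm choice is part of this method.

A `mirror_texture` flag copies the left-hemisphere field onto the right by
exact reflection, producing a textured but perfectly symmetric subject;
with zero noise and zero jitter, every difference feature is exactly 0 and
every ratio feature exactly 1, which the acceptance tests assert without
tolerance.

## Numerical and design choices

* **Quantisation.** Gray levels `Z = 32` by default, uniform bins over the
  in-mask `[min, max]` with the maximum assigned to level `Z-1`; a constant
  region maps to level 0. Min-max normalisation (not z-scoring) upstream
  keeps bins comparable across subjects. Levels 0-based; the RLM gray
  weight uses the 1-based index `g = level + 1` to avoid division by zero.
* **Co-occurrence.** Distance `d = 1`, the 13 canonical 3D directions
  (symmetric closure = all 26 neighbours), counts aggregated over
  directions into a single matrix rather than averaged per direction —
  simpler, deterministic, and invariant under left-right reflection because
  the direction set is closed under it. Entropy uses log base 2 with
  `0 log 0 := 0`. Degenerate correlation (zero marginal variance) returns 0
  rather than NaN so feature tables stay finite.
* **Run lengths.** Maximal runs strictly inside the mask: a mask gap or
  grid boundary terminates a run; matrices are summed over the 13 unsigned
  directions (runs are unoriented).
* **Difference sign.** The absolute difference is the default (ratio of the
  prose definition of the transform); the signed form is available via
  `absolute = FALSE` since both conventions circulate.
* **Degenerate ratios.** A ratio column whose denominator falls within
  `1e-12` of zero for any subject is dropped with a warning, never imputed.
* **Fisher score.** $\sum_c n_c(\mu_c-\mu)^2 / \sum_c n_c\sigma_c^2$ with
  population variances; a feature with zero within-class variance but
  nonzero between-class separation scores `+Inf`, an explicit sentinel that
  ranks above all finite scores deterministically.
* **Selection.** The selector is the package's own composition — a Fisher
  filter (top 40 candidates by default) followed by SVM-wrapper sequential
  forward selection with stratified inner CV; it stops when the best
  accuracy improvement falls below `delta_min = 0.002` or `max_k` features
  are reached. Ties break by higher Fisher score, then name. Monotone
  flags demand *strict* monotonicity of the three class means; ties never
  count.
* **Hyperparameters.** Grid search over `C ∈ {0.1, 1, 10, 100}` and RBF
  width `u ∈ {0.25, 0.5, 1, 2, 4} ×` the median pairwise distance of the
  standardised training features; ties prefer smaller `C` then smaller `u`,
  so the winner is independent of grid ordering.
* **Validation.** Stratified outer k-fold CV (default 5 folds) with both
  feature selection and grid search re-run inside every outer training
  fold, so no held-out label can influence the selected subset — the test
  suite asserts this structurally by reproducing each fold's selection from
  its training rows alone. The original protocol this mirrors did not
  document its validation scheme; nesting is the defensible choice, and the
  headline percentages reported elsewhere for this method should therefore
  not be expected to reproduce here.
* **Determinism.** Every stochastic stage draws its own 31-bit seed from a
  rolling hash of the master seed and a stage tag (`derive_seed()`), so
  cohorts, fold assignments and wrapper CVs are reproducible independently
  of evaluation order.

## Problem sizes used by the tests and acceptance script

The shipped test suite and `scripts/acceptance.R` exercise the full
pipeline on cohorts of 30 subjects per class on a 48^3 grid — the package's
chosen working scale for routine verification, with ten independent cohort
seeds for the recovery and monotonicity rates. The generator's defaults
(50 per class, 64^3) remain those of the emulated study design and are what
`run_pipeline()` uses unless configured otherwise.

## Known limitations

* Ellipsoid geometry carries volume and texture signal but no shape
  information beyond volume; Fourier/shape descriptors are out of scope.
* The selected-feature *counts* per structure are comparable across runs,
  but the identity of selected texture features can vary with seed — only
  rates over seeds are asserted, not specific features.
* The monotone-flag null rate has an irreducible chance level of 1/3 for
  any exchangeable feature (two monotone orderings out of six), so null
  features are expected to flag occasionally; the analysis reports rates,
  not certainties.
* Three-class classification is not implemented; the clinically reported
  comparisons are the pairwise NC-vs-AD and NC-vs-MCI designs.
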