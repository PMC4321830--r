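---
title: "Models and methods: synthetic WMH/NAWM phantoms and their analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: synthetic WMH/NAWM phantoms and their analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmpipeline)
```

# The problem

White matter hyperintensities (WMH) are focal FLAIR/T2-bright lesions of
presumed vascular origin in the aging brain; the surrounding
normal-appearing white matter (NAWM) can carry microstructural change that
conventional images do not show. Four quantitative MRI biomarkers summarise
that microstructure: fractional anisotropy (FA, unitless), mean diffusivity
(MD, 10⁻⁹ m²s⁻¹), magnetization transfer ratio (MTR, %), and longitudinal
relaxation time (T1, s). Three questions drive the analysis this package
implements: how strongly each biomarker separates WMH from NAWM; how NAWM
integrity degrades with visual lesion load (total Fazekas score 0–6, the
sum of periventricular and deep 0–3 ratings); and whether NAWM abnormality
is graded with distance from the lesions (a "penumbra").

Cohort images of this kind are not publicly deposited, so the package is
built around a synthetic-data module that is itself first-class, tested
code: phantoms are generated with known ground truth, and every downstream
claim a test makes is a claim about recovering that stated world.

# The generator's stated world

**Cohort model.** `make_cohort()` draws one record per subject: a total
Fazekas score with group sizes `(9, 100, 311, 143, 72, 28, 13)` over scores
0–6 (676 subjects in all), gender from the per-group male fractions, and
age uniform over 71.0–74.2 years (stored in days — the cohort is a narrow
birth-year sample, so age has deliberately little range). For each
biomarker a paired (NAWM, WMH) pair of subject-level means is drawn from a
bivariate Gaussian: the NAWM marginal from the subject's score-group row of
the per-score table, the WMH marginal from the population table, with
between-tissue correlation ρ. ρ is not published anywhere; the default 0.6
was chosen once so that the paired t test is well behaved, and pooled-SD
effect sizes are independent of it. The per-score NAWM table aggregates
back to the population marginals (pooled MD mean 0.6927 vs 0.692), so the
two calibration sources are mutually consistent; a test checks this
recovery at n = 676 within 3 standard errors.

**Vascular risk factors.** `assign_vrf()` draws smoking status
(current/ex/never) as one categorical per subject and the remaining factors
(hypertension, diabetes, hypercholesterolemia, cardiovascular disease,
stroke) as independent Bernoulli flags, all at gender-specific incidence
rates. Independence between factors is a simplification: real risk factors
co-occur, so the VRF block's joint distribution — but not its margins — is
synthetic.

**Geometry.** `make_label_phantom()` builds a schematic head on a default
64³ grid of 2 mm isotropic voxels: two ellipsoidal lateral-ventricle CSF
bodies (semi-axes 8×20×12 mm, offset ±12 mm) inside a white-matter
ellipsoid sized to leave ≥ 12 mm of NAWM margin, so that 10 mm distance
shells always fit (undersized grids are a hard error). The score is split
pv = ⌈s/2⌉, deep = ⌊s/2⌋; the periventricular part becomes a rind of NAWM
within {4, 6, 8} mm of the ventricles and the deep part becomes 2·deep
spheres of radius (2+deep) mm placed ≥ 12 mm from CSF with a fixed
separation, consumed from a seed-determined candidate list so that lesion
sets are nested across scores at a fixed seed — WMH volume is monotone in
the score *by construction*, because no published volume-per-score
calibration exists. The cap starts at 4 mm so that the 1-voxel CSF
dilation used in mask refinement can never erase a lesion entirely.
Ground-truth scores are recorded, not re-derived visually.

**Intensities.** Structural contrasts are tissue mean + Gaussian noise per
modality. The mean table is arbitrary in absolute units but fixed in its
orderings (FLAIR: WMH ≫ NAWM > CSF; T2W: CSF ≫ WMH > NAWM; T1W: NAWM
brightest) — precisely the orderings the colour-fusion segmentation needs
to be solvable. The default noise SD of 8 units gives roughly SNR 15–25,
a plausible clinical regime. Parametric maps draw WMH/NAWM voxels around
the subject's tissue means with the population SDs as voxel noise; CSF gets
fixed fluid values (FA 0.1, MD 3.0, MTR 5, T1 4.0) that only matter for
partial-volume behaviour; stroke tissue reuses the WMH distribution since
it is excluded from all analysis masks anyway.

**Penumbra.** With a `penumbra_config(alpha, lambda)`, a NAWM voxel at
Euclidean distance *d* mm from the nearest WMH voxel has its expected value
shifted toward the WMH mean by `alpha·exp(−d/lambda)·(μ_WMH − μ_NAWM)`.
The defaults α = 0.3, λ = 4 mm qualitatively reproduce decaying shell
profiles; they are synthetic choices, not estimates, and tests assert only
monotonicity and the shift formula itself, never specific profile values.

**What the generator does not emulate:** cortical anatomy, bias fields,
motion, registration error, k-space or diffusion-weighted raw data,
partial-volume mixing at tissue borders (voxels are pure), and skewed or
heavy-tailed biomarker distributions (all draws are Gaussian). A green
test therefore establishes that the *methods* behave correctly in this
stated world, not that the world matches any particular scanner.

# Segmentation

Two channels are normalised by clipping to the 1st/99th in-brain
percentiles and mapping to [0, 255] (constant volumes map to zero), fused
as red/green, and quantized.

**Minimum-variance quantization.** The quantizer partitions the in-mask
colours into `n_levels` clusters minimising within-cluster squared colour
distance (SSE). At volume scale it splits greedily: among all current
boxes and all axis-aligned channel/threshold cuts, execute the split that
most reduces total SSE, until `n_levels` boxes exist. Total SSE is
non-increasing in `n_levels` by construction. For tiny palettes (≤ 12
distinct colours — noiseless phantoms, toy instances) the split tree is
found by exhaustive enumeration instead, so the partition is exactly
minimum-variance. This split of regimes is deliberate: we measured that no
pure greedy split sequence (largest-SSE box, best-reduction box, or either
followed by a Lloyd polish) stays within 10% of the optimum on adversarial
small palettes (observed ratios up to ~2×), while at volume scale the
tissue modes are far apart relative to noise and the greedy result is
essentially exact. The default of 16 levels is the classic palette size
for this family of quantizers; the level count used by the original
semi-automatic tooling is not published.

**Cluster → tissue rules.** On the T1W(red)+T2W(green) fusion, NAWM is the
red-dominant group: clusters whose centroid red−green exceeds half the
maximum observed red−green; CSF symmetrically with green−red. On the
T2*W(red)+FLAIR(green) fusion, WMH are clusters whose centroid green
exceeds an Otsu threshold over centroid greens — an adaptive,
parameter-free stand-in for the original method's manual step — subject to
two guards: the cluster must be genuinely FLAIR-hyperintense (green > red),
and the selection must cover at most 30% of the brain mask. The guards
exist because percentile normalisation is scale-free: in a lesion-free
subject it stretches healthy-tissue noise across the whole intensity range
and the Otsu cut then lands inside normal tissue; the sparsity prior
(real phantom lesions occupy ≤ ~8% of brain even at score 6) rejects such
selections, so Fazekas-0 subjects return an empty mask with a warning
rather than a hallucinated lesion. Masks are refined by dilating CSF one
voxel (26-neighbourhood box) and subtracting it from NAWM and WMH —
insurance against CSF partial-volume contamination — and stroke masks are
subtracted last. On zero-noise phantoms the recovered masks equal ground
truth exactly; with default noise the WMH Dice stays above 0.90 (in
practice ≈ 0.99).

# Distance shells

`build_shells()` thresholds a single exact Euclidean distance transform
(anisotropy-aware, voxel-centre to voxel-centre) rather than iterating
structuring elements: shell_k is the NAWM at distance (k−2, k] mm from the
nearest WMH voxel. Nominal distances are approximate in the sense that the
lattice quantises them — on a 2 mm grid, the 2 mm shell of a point is its 6
face neighbours, and the 4 mm shell contains the 12 edge, 8 corner and 6
face-distance-2 neighbours (26 voxels; enumeration of neighbour distances
is the test oracle). Shells plus the remaining NAWM partition the NAWM mask
exactly; subjects without lesions are a defined error and skip the stage.
Fixed-location spherical ROIs (`sample_fixed_rois`) provide the control
analysis that NAWM trends are not artefacts of lesion location; their
coordinates are configurable because no canonical set exists.

# Statistics

- **Paired comparison:** classic paired t on per-subject (NAWM, WMH) means;
  effect size `d = (μ_NAWM − μ_WMH)/√((σ²_NAWM + σ²_WMH)/2)`, so biomarkers
  elevated in lesions (MD, T1) get negative d. Zero-variance differences
  are a degenerate-input error (this includes x = y).
- **Discrimination:** empirical ROC over thresholds at midpoints of
  consecutive sorted unique values; trapezoid AUC, which equals the
  Mann–Whitney pair-count (asserted exactly in tests); DeLong 95% CI; the
  operating threshold maximises Youden's J with ties broken toward the
  lower threshold. Youden and DeLong are the conventional choices of the
  standard ROC tooling; neither is dictated by the data. Observations are
  subject-level tissue means (the calibration tables are subject-level), a
  choice that matters: voxel-level ROC would see within-subject rather than
  between-subject variance.
- **Logistic regression** is fit by IRLS with a 1e-8 log-likelihood
  tolerance and an explicit complete-separation flag (deviance collapsing
  to zero) instead of silently divergent coefficients.
- **Trend:** ANCOVA with the total Fazekas score as a *categorical* factor
  (no linearity assumption across 0–6) plus age, gender, and optionally the
  VRF block; F statistics use Type II sums of squares (each term adjusted
  for the others; with no interactions this is the drop-one F). Empty
  score groups are dropped with a warning — the score-0 group is tiny in
  realistic cohorts and must not crash the model. Constant covariates are
  dropped so the model reduces exactly to one-way ANOVA. Nested models
  with/without the VRF block are compared by
  `F = ((RSS₁−RSS₂)/Δdf)/(RSS₂/df₂)`.
- **Incidence:** Pearson χ² without continuity correction on 2×k
  gender-by-factor tables.
- **Outliers:** the irreproducible visual-inspection step is replaced by a
  logged flag: robust z-scores (median/scaled-MAD, SD fallback when MAD is
  zero) with |z| > 3.5 flagged for review, never auto-dropped.

# Numerical and design choices

- All randomness flows through a single integer seed per generator call
  (`withr::with_seed`), so every pipeline output is a pure function of
  (arguments, seed); replicate studies derive per-replicate seeds by fixed
  offsets.
- Distance thresholds carry a 1e-9 tolerance so exact lattice distances
  (2.0 mm at 2 mm spacing) fall inside their shell.
- The exact EDT is separable O(L²) per line in pure R — ample for ≤ ~96³
  phantom grids and verified against all-pairs brute force.
- Voxel indices are 1-based (R convention); all physical distances are
  voxel-centre based, so the convention is invisible to results.
- NIfTI-1 I/O is implemented in-package (no reader in the supported
  dependency set): single-file `.nii`/`.nii.gz`, common datatypes, pixdim
  geometry only. Configs round-trip through JSON for the same reason.
- The volumetric study draws each subject's tissue means from the same
  cohort model as the summary study and adds voxel noise on top, so the two
  entry points agree at subject level (asserted in tests without penumbra,
  which deliberately shifts near-lesion NAWM); the volumetric path is
  exercised at n ≈ 2–10, never 676 — the statistical calibration targets
  are the summary path's job.

# Known limitations

Geometry is schematic (no cortex, no sulcal CSF, single stroke blob);
lesion volume per score is an invented monotone mapping; VRF flags are
independent given gender; biomarker draws are Gaussian although real WMH
distributions are skewed — which is exactly why the simulated overall
classification accuracy sits slightly below a real cohort's (the
sensitivity side of the Gaussian surrogate is conservative); and the
segmentation guards assume lesions are sparse, so a pathology occupying
more than ~30% of the brain mask would be rejected as implausible.
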