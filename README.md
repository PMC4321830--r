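# wmpipeline

Synthetic multimodal brain MRI phantoms and the full analysis pipeline for
characterising **white matter hyperintensities (WMH)** against
**normal-appearing white matter (NAWM)** in an aging cohort: multispectral
tissue segmentation, distance-shell profiling of the lesion penumbra, and
the discrimination/trend statistics that summarise how four quantitative
biomarkers — fractional anisotropy (FA), mean diffusivity
(MD, 10⁻⁹ m²s⁻¹), magnetization transfer ratio (MTR, %) and longitudinal
relaxation time (T1, s) — separate the two tissue classes.

## Who this is for

Imaging researchers who want a fully reproducible, deposit-free testbed for
WMH/NAWM analysis methods. Real cohort images of this kind are not public;
the package instead *generates* co-registered phantom volumes and cohort
tables whose statistical structure is calibrated to published population
summaries (tissue means/SDs per biomarker, Fazekas group sizes, per-score
NAWM distributions, vascular-risk-factor incidence), and then runs the same
analysis a study of real data would run.

## What it computes

- **Phantoms** (`make_label_phantom`, `synthesize_structural`,
  `synthesize_parametric`, `make_cohort`, `assign_vrf`): ellipsoidal
  ventricles (CSF), a NAWM compartment, periventricular caps and deep
  spherical WMH whose volume grows with the total Fazekas score (0–6), four
  structural contrasts (T1W/T2W/FLAIR/T2\*W), four parametric maps, and an
  optional distance-decaying NAWM "penumbra": at distance *d* mm from the
  nearest lesion voxel the expected biomarker value is shifted toward the
  WMH mean by `α·exp(−d/λ)·(μ_WMH − μ_NAWM)`.
- **Segmentation** (`segment_subject` and friends): two contrasts are
  normalised to [0,255], fused into red–green colour space, reduced by
  minimum-variance quantization clustering, and tissues are selected from
  cluster centroids (T1W+T2W → NAWM and CSF; T2\*W+FLAIR → WMH via an Otsu
  cut on FLAIR intensity). The CSF mask is dilated one voxel and subtracted
  from the tissue masks; stroke lesions are excluded.
- **Shells** (`build_shells`, `shell_means`): disjoint NAWM bands at
  nominal 2,4,…,10 mm Euclidean distance from the WMH plus the remaining
  NAWM — an exact partition of the NAWM mask.
- **Statistics** (`paired_t`, `cohen_d_pooled`, `roc_discrimination`,
  `logistic_univariate`, `ancova_trend`, `nested_f`,
  `chi_square_incidence`, `flag_outliers`): paired t tests with pooled-SD
  Cohen's d, `d = (μ₁−μ₂)/√((σ₁²+σ₂²)/2)`; empirical ROC with trapezoid
  AUC (= Mann–Whitney statistic), DeLong 95% CI and Youden-optimal
  threshold; Fazekas-trend ANCOVA (score as categorical factor, age and
  gender covariates, Type II sums of squares) with nested F tests for a
  vascular-risk-factor block; Pearson χ² incidence tests.

## Worked example

```r
library(wmpipeline)
res <- run_summary_study(pipeline_config(seed = 1))
res$tissue_contrast[, c("biomarker", "mean_nawm", "mean_wmh", "p", "cohen_d")]
```

```
  biomarker mean_nawm mean_wmh         p cohen_d
1        FA     0.337    0.298 5.71e-115   1.119
2        MD     0.693    0.838 6.26e-309  -2.760
3       MTR    56.750   54.328 6.49e-240   1.927
4        T1     0.999    1.083  5.93e-84  -0.797
```

Each row compares the per-subject NAWM and WMH means of one biomarker over
a simulated 676-subject cohort: FA and MTR are lower in lesions, MD and T1
higher, all at p < 0.0001, with MD giving by far the largest pooled-SD
effect size — the same ordering the calibration tables encode.

```r
res$roc[res$roc$biomarker == "MD", ]
#   biomarker   auc ci_low ci_high threshold direction sensitivity specificity accuracy
#          MD 0.974  0.965   0.982     0.751         >       0.907       0.956    0.931
```

MD discriminates NAWM from WMH with AUC ≈ 0.97 at this seed; the
Youden-optimal threshold lands near 0.75 ×10⁻⁹ m²s⁻¹ with specificity
≈ 0.95. The Fazekas-trend table (`res$score_trend`) shows the NAWM decline
with lesion load: for FA the score factor gives F ≈ 16.8 (p < 10⁻¹⁷),
R² ≈ 0.15 with age and gender, rising to ≈ 0.16 with the VRF block.

The volumetric path runs the same statistics through actual images:

```r
out <- run_volumetric_study(pipeline_config(seed = 7), n_subjects = 5)
out$dice      # per-subject Dice of recovered vs ground-truth masks (>= 0.90)
out$shells    # per-shell biomarker means: the penumbra profile
```

A command-line front end is installed at
`system.file("cli", "wmpipeline.R", package = "wmpipeline")` with
subcommands `run`, `fixtures` (writes a 64³ demo subject in ~2 s),
`segment` and `shells`.

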