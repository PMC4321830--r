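Package: wmpipeline
Title: Synthetic Multimodal MRI Phantoms and White Matter Hyperintensity
    Analysis
Version: 0.1.0
Authors@R:
    person("LBC", "Imaging Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates synthetic co-registered multimodal brain MRI phantoms
    (structural contrasts and FA/MD/MTR/T1 parametric maps with ground-truth
    CSF/NAWM/WMH labels), segments white matter hyperintensities (WMH) and
    normal-appearing white matter (NAWM) by red-green colour fusion with
    minimum-variance quantization clustering, builds distance shells around
    lesions to profile the NAWM penumbra, and implements the statistical
    surface used to characterise WMH versus NAWM: paired t tests with
    pooled-SD Cohen's d, per-biomarker logistic/ROC discrimination with
    DeLong confidence intervals and Youden-optimal thresholds, Fazekas-trend
    ANCOVA with covariates and nested F tests, and chi-squared incidence
    tests for vascular risk factors.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
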