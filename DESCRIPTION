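Package: fwpenumbra
Title: Free-Water DTI and Longitudinal FLAIR Mapping of White Matter
    Hyperintensity Penumbra Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study progression of white matter hyperintensities
    (WMH) of presumed vascular origin with serial MRI. Simulates seeded,
    co-registered longitudinal FLAIR and single-shell diffusion MRI phantom
    cohorts with growing periventricular lesions; fits standard and
    free-water-corrected (bi-tensor) diffusion tensor models to single-shell
    DWI; constructs the 3 mm WMH penumbra from serial lesion masks;
    localizes lesion progression with per-voxel FLAIR intensity slopes
    converted to Z-statistics against a stable normal-appearing white matter
    null and cluster-corrected with Gaussian random field theory; and
    quantifies prediction of voxel-wise progression from baseline diffusion
    metrics with cluster-robust logistic regression, ROC/AUC with
    subject-level bootstrap, and the Liu optimal cutoff.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    pROC,
    optparse
Config/testthat/edition: 3
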