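# fwpenumbra

Free-water DTI and longitudinal FLAIR mapping of white matter
hyperintensity (WMH) penumbra progression.

## The problem

WMH — FLAIR-bright white matter lesions of presumed vascular origin —
grow over time, and their growth heralds vascular cognitive decline.
Growth concentrates in the **penumbra**: the rim of normal-appearing
white matter (NAWM) within ~3 mm of existing lesions. The scientific
question this package operationalizes, for researchers studying cerebral
small vessel disease with serial MRI: does the **free-water (FW)
fraction** from diffusion MRI — an in-vivo proxy for interstitial fluid —
predict, voxel by voxel, which penumbra tissue will convert to lesion
over the following year?

## What it implements

**Bi-tensor (free-water elimination) model.** Each voxel's diffusion
signal is

    S(b, g) = S0 [ f e^{-b d_fw} + (1 - f) e^{-b g'Dg} ],   d_fw = 3.0e-3 mm^2/s

with FW fraction `f`, tissue tensor `D`, and FW-corrected scalars
FA_Tissue / MD_Tissue from `D`. `fit_freewater_singleshell()` fits this
to single-shell DWI in two modes: `"profile"` (plain least squares;
exact on noiseless data) and `"anchored"` (tissue-trace coupling anchor;
the practical mode at clinical SNR, where a single shell leaves `f` and
the tissue trace nearly interchangeable). `fit_dti_wls()` and
`compute_trace()` cover the conventional tensor and the geometric-mean
trace image.

**Penumbra construction.** `build_penumbra()`: lesions from all
timepoints are combined, dilated by 3 mm in *physical* units (anisotropic
voxels honoured; exact against brute-force enumeration), and the baseline
WMH is subtracted. `classify_penumbra()` labels a penumbra voxel as
progressing only if it is newly segmented as lesion *and* lies in a
cluster of significantly increasing FLAIR intensity (the AND rule).

**Progression localization.** GM-normalized (`normalize_flair()`),
non-local-means denoised (`denoise_nlm_series()`) FLAIR series; per-voxel
OLS slopes over time (`fit_voxel_slopes()`); Z-statistics against the
stable-NAWM null (`slopes_to_z()`); Gaussian-random-field cluster
correction at Z >= 2.3, p < 0.01 (`grf_cluster_correct()`), with a
time-permutation calibration mode (`cluster_permutation_test()`).

**Pooled voxel statistics.** Logistic regression with subject-clustered
sandwich standard errors (`fit_logistic_clustered()`), ROC/AUC via the
Mann-Whitney identity with a subject-level bootstrap (`roc_auc()`), the
Liu optimal cutoff (`liu_cutoff()`), and random-intercept mixed models of
ROI trajectories (`roi_longitudinal()`).

**Synthetic cohorts.** `cohort_config()` / `simulate_cohort()` generate
seeded, pre-aligned longitudinal FLAIR + DWI phantom cohorts with growing
periventricular lesions whose conversion probability increases with
baseline FW, calibrated to a target growth volume (default 2.9 ml/year),
with published white matter class means as the tissue defaults. Volumes
round-trip through NIfTI-1 with FSL-dialect bval/bvec
(`write_subject()`, `read_bvalbvec()`).

`run_pipeline()` orchestrates simulate → fit-fw → rois → map → predict;
a thin CLI with those subcommands ships in `inst/cli/fwpenumbra`.

## Worked example

```r
library(fwpenumbra)

cfg <- cohort_config(seed = 42)   # 8 subjects, 48^3 grid, 5 visits over 1 year
report <- run_pipeline(cfg)
print(report)
```

```
WMH penumbra pipeline report
  subjects: 8, pooled penumbra voxels: 5218
  median detected growth: 2.67 ml/year
  AUC(fw) = 0.880 [0.871, 0.889]
  AUC(md_tissue) = 0.875 [0.867, 0.882]
  AUC(fa_tissue) = 0.698 [0.665, 0.722]
  AUC(clinical) = 0.515 [0.494, 0.528]
  Liu cutoff on FW: 0.340 (sens 0.80, spec 0.79)
```

Reading the numbers: the generator was calibrated to 2.9 ml/year of
lesion growth and the full pipeline (normalize → denoise → slope → Z →
GRF clusters → AND rule) detects a median of 2.67 ml/year — boundary
voxels whose slopes are diluted by denoising account for the small
deficit. Baseline fitted free water classifies which penumbra voxels
progress (AUC 0.880) better than FW-corrected mean diffusivity and
fractional anisotropy, while the exchangeable clinical covariates alone
sit at chance (0.515) — the qualitative pattern expected when
interstitial fluid drives conversion. The Liu cutoff is the FW value
balancing sensitivity and specificity on the pooled voxels.

```r
sl <- report$mixed$flair$slopes
sl$annual_change[sl$roi == "pen_prog"]   # 0.061 normalized FLAIR / year
ct <- report$mixed$fw$contrasts
ct$vs_ref[ct$roi == "pen_prog"]          # 0.028 FW / year vs NAWM
```

The mixed models recover the generator's FLAIR intensity rise
(0.058/year injected) and FW rise (0.034/year injected, attenuated to
~0.86x by the single-shell anchoring; see the methods vignette in
`vignettes/fwpenumbra-methods.Rmd`).

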