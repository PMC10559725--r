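cfg <- cohort_config(n_subjects = 1, seed = 7)

test_that("identical seed and config give a bit-identical cohort", {
  s1 <- simulate_subject(cfg, 1, dwi = "baseline")
  s2 <- simulate_subject(cfg, 1, dwi = "baseline")
  expect_identical(s1$truth$tissue_labels, s2$truth$tissue_labels)
  expect_identical(s1$truth$fw_field, s2$truth$fw_field)
  expect_identical(s1$truth$wmh_mask_t, s2$truth$wmh_mask_t)
  expect_identical(s1$flair, s2$flair)
  expect_identical(s1$dwi$t1, s2$dwi$t1)
  expect_identical(s1$covariates, s2$covariates)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(timepoints = c(0, 0.5)), "at least 3")
  expect_error(cohort_config(timepoints = c(0, 0.5, 0.25)), "increasing")
  expect_error(cohort_config(roi_fw_means = c(csf = 0.9, gm = 0.1,
                                              nawm = 0.4, pen_stable = 0.3,
                                              pen_prog = 0.45, wmh = 0.5)),
               "ordered")
  expect_error(cohort_config(flair_noise_sd = -1), "non-negative")
  expect_error(make_anatomy(cohort_config(grid_shape = 16)), "too small")
})

test_that("baseline WMH volume hits the configured fraction of TICV", {
  tr <- make_anatomy(cfg, 1)
  frac <- sum(tr$wmh_baseline) / tr$ticv_vox
  expect_lt(abs(frac - 0.01), 0.001)
})

test_that("zero-lesion config degenerates cleanly", {
  cfg0 <- cohort_config(n_subjects = 1, seed = 7, wmh_fraction_ticv = 0,
                        fw_jitter_sd = 0)
  tr <- grow_lesions(make_anatomy(cfg0, 1), cfg0)
  expect_false(any(tr$wmh_baseline))
  expect_false(any(tr$progression_mask))
  wm <- tr$tissue_labels == 3L
  expect_true(all(abs(tr$fw_field[wm] - 0.205) < 1e-12))
})

test_that("lesion masks are monotone in time and progression is confined to
           the penumbra", {
  tr <- grow_lesions(make_anatomy(cfg, 1), cfg)
  for (i in seq_len(length(tr$wmh_mask_t) - 1))
    expect_true(all(!tr$wmh_mask_t[[i]] | tr$wmh_mask_t[[i + 1]]))
  expect_true(all(!tr$progression_mask | tr$penumbra_mask))
  expect_false(any(tr$progression_mask & tr$wmh_baseline))
  expect_true(all(tr$fw_field >= 0 & tr$fw_field <= 1))
})

test_that("degenerate growth settings behave as documented", {
  ## probability ~0: no voxel converts
  cfg_off <- cohort_config(n_subjects = 1, seed = 7,
                           calibrate_growth = FALSE,
                           growth_logit = c(-50, 0))
  tr <- grow_lesions(make_anatomy(cfg_off, 1), cfg_off)
  expect_false(any(tr$progression_mask))
  expect_identical(tr$wmh_mask_t[[5]], tr$wmh_baseline)

  ## probability ~1: the whole risk shell converts, with a warning
  cfg_all <- cohort_config(n_subjects = 1, seed = 7,
                           calibrate_growth = FALSE,
                           growth_logit = c(50, 0))
  expect_warning(tr1 <- grow_lesions(make_anatomy(cfg_all, 1), cfg_all),
                 "degenerate")
  expect_identical(tr1$progression_mask, tr1$risk_shell)
})

test_that("sampled conversions match the logistic expectation and calibrate
           to the growth target", {
  base <- make_anatomy(cfg, 1)
  n_rep <- 30
  counts <- numeric(n_rep)
  expected <- NA_real_
  for (r in seq_len(n_rep)) {
    b <- base; b$subject <- 1000L + r   # fresh conversion stream
    tr <- grow_lesions(b, cfg)
    counts[r] <- sum(tr$progression_mask)
    if (r == 1) {
      gp <- tr$growth_params
      f <- tr$fw_field[tr$risk_shell]
      expected <- sum(plogis(gp$a + gp$b * f))
    }
  }
  ## closed-form expectation vs Monte-Carlo (binomial error ~ sqrt(E))
  expect_lt(abs(mean(counts) - expected),
            4 * sqrt(expected) / sqrt(n_rep) + 0.02 * expected)
  ## calibration: mean converted volume within 15% of target_growth_ml
  vol <- mean(counts) * voxel_ml(cfg)
  expect_lt(abs(vol - cfg$target_growth_ml), 0.15 * cfg$target_growth_ml)
})

test_that("noiseless FLAIR rendering reproduces class means, gain linearity
           and the progression slope", {
  cfgn <- cohort_config(n_subjects = 1, seed = 7, flair_noise_sd = 0,
                        fw_jitter_sd = 0,
                        gain_per_timepoint = c(1, 2, 1, 1, 1))
  tr <- grow_lesions(make_anatomy(cfgn, 1), cfgn)
  v0 <- render_flair(tr, 0, cfgn)
  nawm <- tr$roi_class == 3L
  expect_true(all(abs(v0[nawm] - 0.928) < 1e-12))
  wmh <- tr$roi_class == 6L
  expect_true(all(abs(v0[wmh] - 1.189) < 1e-12))
  ## doubling the gain doubles every voxel at that timepoint
  v1 <- render_flair(tr, 0.25, cfgn)
  base25 <- tr$flair_mean_field + tr$flair_slope_field * 0.25
  expect_equal(v1, 2 * base25, tolerance = 1e-12)
  ## converted voxel: intensity difference = slope x dt x gain
  prog <- which(tr$progression_mask)[1]
  v2 <- render_flair(tr, 0.5, cfgn)
  v3 <- render_flair(tr, 0.75, cfgn)
  expect_equal(v3[prog] - v2[prog], 0.058 * 0.25, tolerance = 1e-12)
  expect_error(render_flair(tr, 0.1, cfgn), "timepoints")
  expect_error(render_flair(tr, 0, cfgn, noise_sd = -1), "non-negative")
})

test_that("noiseless DWI rendering matches the scalar forward model", {
  cfgn <- cohort_config(n_subjects = 1, seed = 7, dwi_snr = Inf,
                        fw_jitter_sd = 0, fa_jitter_sd = 0, md_jitter_sd = 0)
  tr <- grow_lesions(make_anatomy(cfgn, 1), cfgn)
  sch <- default_scheme()
  dwi <- render_dwi(tr, sch, cfgn, t = 0, snr = Inf)
  ## b0 volumes equal S0 inside the head, 0 outside
  inside <- tr$tissue_labels != 0L
  b0 <- dwi[, , , 1]
  expect_true(all(abs(b0[inside] - cfgn$s0) < 1e-9))
  expect_true(all(b0[!inside] == 0))
  ## spot-check one WM voxel against bitensor_signal
  v <- which(tr$roi_class == 3L)[1]
  sig <- bitensor_signal(cfgn$s0, tr$fw_field[v], tr$tensor_d6[v, ], sch)
  flat <- matrix(dwi, prod(dim(b0)), 16)
  expect_equal(flat[v, ], as.numeric(sig), tolerance = 1e-9)
  ## all rendered intensities are positive inside the head
  expect_true(all(flat[inside, ] > 0))
})

test_that("segmentation flip noise stays on lesion boundaries and respects
           the flip rate", {
  cfgf <- cohort_config(n_subjects = 1, seed = 7, label_flip_rate = 0.3)
  tr <- grow_lesions(make_anatomy(cfgf, 1), cfgf)
  subj_masks <- segmentation_masks(tr, cfgf)
  truth_masks <- tr$wmh_mask_t
  ## flipped voxels exist but masks stay close to truth
  diff1 <- sum(xor(subj_masks[[1]], truth_masks[[1]]))
  expect_gt(diff1, 0)
  expect_lt(diff1, sum(truth_masks[[1]]))
  ## rate 0 returns truth
  cfg0 <- cohort_config(n_subjects = 1, seed = 7, label_flip_rate = 0)
  tr0 <- grow_lesions(make_anatomy(cfg0, 1), cfg0)
  expect_identical(segmentation_masks(tr0, cfg0), tr0$wmh_mask_t)
})
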