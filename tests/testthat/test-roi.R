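test_that("penumbra dilation agrees exactly with brute-force mm enumeration", {
  ## single voxel lesion, 1 mm isotropic, radius 3
  d <- c(15, 15, 15)
  mask <- array(FALSE, d); mask[8, 8, 8] <- TRUE
  wm <- array(TRUE, d)
  got <- build_penumbra(list(mask), mask, wm, NULL,
                        penumbra_config(radius_mm = 3), c(1, 1, 1))
  oracle <- brute_dilate(mask, 3, c(1, 1, 1)) & !mask
  expect_identical(got, oracle)
  ## the count is the number of lattice points at Euclidean distance (0, 3]
  expect_equal(sum(got), sum(oracle))

  ## anisotropic 1 x 1 x 3.5 mm voxels: radius 3 never crosses a slice
  aniso <- build_penumbra(list(mask), mask, wm, NULL,
                          penumbra_config(radius_mm = 3), c(1, 1, 3.5))
  oracle_a <- brute_dilate(mask, 3, c(1, 1, 3.5)) & !mask
  expect_identical(aniso, oracle_a)
  expect_true(all(which(aniso, arr.ind = TRUE)[, 3] == 8))

  ## an irregular multi-voxel lesion on a small grid
  set.seed(5)
  d2 <- c(12, 10, 9)
  m2 <- array(runif(prod(d2)) < 0.03, d2)
  m2[1, 1, 1] <- TRUE
  got2 <- dilate_mm(m2, 2.6, c(1.2, 1, 2))
  expect_identical(got2, brute_dilate(m2, 2.6, c(1.2, 1, 2)))
})

test_that("empty union gives an empty penumbra", {
  d <- c(8, 8, 8)
  empty <- array(FALSE, d)
  got <- build_penumbra(list(empty, empty), empty, array(TRUE, d), NULL,
                        penumbra_config(), c(1, 1, 1))
  expect_false(any(got))
})

test_that("dilation is monotone in radius", {
  d <- c(16, 16, 16)
  set.seed(6)
  m <- array(runif(prod(d)) < 0.02, d)
  wm <- array(TRUE, d)
  p1 <- build_penumbra(list(m), m, wm, NULL, penumbra_config(radius_mm = 2),
                       c(1, 1, 1))
  p2 <- build_penumbra(list(m), m, wm, NULL, penumbra_config(radius_mm = 4),
                       c(1, 1, 1))
  expect_true(all(!p1 | p2))
})

test_that("grid mismatch between masks is rejected", {
  a <- array(FALSE, c(8, 8, 8)); b <- array(FALSE, c(8, 8, 9))
  expect_error(build_penumbra(list(a), a, b, NULL, penumbra_config(),
                              c(1, 1, 1)), "grid mismatch")
})

test_that("classification follows the AND rule", {
  d <- c(10, 10, 10)
  wm <- array(TRUE, d)
  base <- array(FALSE, d); base[5, 5, 5] <- TRUE
  later <- base; later[6, 5, 5] <- TRUE; later[4, 5, 5] <- TRUE
  pen <- build_penumbra(list(base, later), base, wm, NULL,
                        penumbra_config(), c(1, 1, 1))
  sig <- array(FALSE, d); sig[6, 5, 5] <- TRUE   # only one new voxel survives
  part <- classify_penumbra(pen, list(base, later), sig, wm_mask = wm)
  expect_true(part$pen_prog[6, 5, 5])            # new + significant
  expect_true(part$pen_stable[4, 5, 5])          # new but not significant
  expect_false(any(part$pen_prog & part$pen_stable))

  ## no new segmented lesions -> zero progressing
  part0 <- classify_penumbra(pen, list(base, base), sig, wm_mask = wm)
  expect_equal(sum(part0$pen_prog), 0L)
})

test_that("every WM voxel belongs to exactly one partition region", {
  subj <- small_subject()
  tr <- subj$truth
  wm <- tr$tissue_labels == 3L
  excl <- dilate_mm(tr$infarct_mask, 3, tr$voxel_size)
  pen <- build_penumbra(subj$seg_masks, subj$seg_masks[[1]], wm, excl,
                        penumbra_config(), tr$voxel_size)
  sig <- tr$progression_mask   # stand-in significance map
  part <- classify_penumbra(pen, subj$seg_masks, sig, wm_mask = wm,
                            exclusion_mask = excl)
  total <- part$baseline_wmh + part$pen_prog + part$pen_stable +
    part$nawm + part$excluded
  expect_true(all(total[wm] == 1))
  expect_true(all(total[!wm] == 0))
})

test_that("annualized growth arithmetic", {
  d <- c(20, 20, 20)
  part <- list(pen_prog = array(FALSE, d))
  part$pen_prog[seq_len(1000)] <- TRUE
  class(part) <- "roi_partition"
  g <- annualized_growth(part, c(1, 1, 1), 1, ticv_vox = 8000)
  expect_equal(g$ml_per_year, 1.0)
  expect_equal(g$pct_ticv_per_year, 100 * 1 / 8)

  part$pen_prog[] <- FALSE
  expect_equal(annualized_growth(part, c(1, 1, 1), 2)$ml_per_year, 0)
  expect_error(annualized_growth(part, c(1, 1, 1), 0), "positive")
  expect_error(annualized_growth(part, c(1, 1, 1), 1, ticv_vox = 0), "TICV")
})
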