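test_that("GM normalization is exact, idempotent and gain-invariant", {
  d <- c(10, 10, 10)
  gm <- array(FALSE, d); gm[1:3, , ] <- TRUE
  vol <- array(200, d); vol[5, 5, 5] <- 240
  nv <- normalize_flair(vol, gm)
  expect_equal(nv[5, 5, 5], 1.2)
  expect_equal(mean(nv[gm]), 1, tolerance = 1e-12)
  ## idempotence
  expect_equal(normalize_flair(nv, gm), nv, tolerance = 1e-12)
  ## gain invariance
  expect_equal(normalize_flair(vol * 3.7, gm), nv, tolerance = 1e-12)
  ## degenerate GM
  expect_error(normalize_flair(vol, array(FALSE, d)), "empty")
  expect_error(normalize_flair(-vol, gm), "positive")
})

test_that("non-local means: identity and smoothing properties", {
  d <- c(12, 12, 12)
  const <- array(5, d)
  expect_equal(denoise_nlm(const, h = 1), const, tolerance = 1e-12)
  set.seed(8)
  noisy <- array(rnorm(prod(d)), d)
  expect_identical(denoise_nlm(noisy, h = 0), noisy)
  ## flat region + Gaussian noise: residual SD strictly reduced
  flat <- array(1 + rnorm(prod(d), sd = 0.1), d)
  den <- denoise_nlm(flat, h = 0.15, sigma = 0.1)
  expect_lt(sd(den - 1), sd(flat - 1))
})

test_that("series denoiser shares weights and preserves uniform trends", {
  d <- c(12, 12, 12)
  set.seed(9)
  base <- array(rnorm(prod(d), 1, 0.05), d)
  times <- c(0, 0.5, 1)
  ## a spatially uniform linear trend passes through a fixed linear operator
  series <- lapply(times, function(t) base + 0.1 * t)
  den <- denoise_nlm_series(series, mask = array(TRUE, d))
  sl <- fit_voxel_slopes(den, times)
  expect_equal(sl$beta, array(0.1, d), tolerance = 1e-10)
  expect_false(is.null(attr(den, "noise_scale")))
  expect_true(all(attr(den, "noise_scale") <= 1 + 1e-12))
})

test_that("voxel slopes equal the closed-form OLS estimator", {
  d <- c(6, 6, 6)
  times <- c(0, 0.25, 0.5, 0.75, 1)
  ## exactly linear series
  series <- lapply(times, function(t) array(1 + 0.05 * t, d))
  expect_equal(fit_voxel_slopes(series, times)$beta, array(0.05, d),
               tolerance = 1e-12)
  ## constant series
  series0 <- lapply(times, function(t) array(2, d))
  expect_equal(fit_voxel_slopes(series0, times)$beta, array(0, d))
  ## random series vs the independent formula sum(x-xbar)(y-ybar)/sum(x-xbar)^2
  set.seed(10)
  series_r <- lapply(times, function(t) array(rnorm(prod(d)), d))
  beta <- fit_voxel_slopes(series_r, times)$beta
  v <- c(3, 4, 5)
  y <- vapply(series_r, function(s) s[v[1], v[2], v[3]], 0)
  oracle <- sum((times - mean(times)) * (y - mean(y))) /
    sum((times - mean(times))^2)
  expect_equal(beta[v[1], v[2], v[3]], oracle, tolerance = 1e-12)
  expect_error(fit_voxel_slopes(series_r[1], times[1]), "2 distinct|differ")
})

test_that("NAWM null estimation matches a two-pass oracle and rejects
           degenerate inputs", {
  d <- c(8, 8, 8)
  set.seed(11)
  beta <- array(rnorm(prod(d), 0.01, 0.002), d)
  mask <- array(runif(prod(d)) > 0.3, d)
  nl <- estimate_null(beta, mask)
  x <- beta[mask]
  expect_equal(nl$mu_nawm, sum(x) / length(x), tolerance = 1e-12)
  expect_equal(nl$sigma_nawm,
               sqrt(sum((x - mean(x))^2) / (length(x) - 1)),
               tolerance = 1e-12)
  ## symmetric slopes give zero mean
  beta2 <- array(0, d); beta2[1:256] <- 0.3; beta2[257:512] <- -0.3
  expect_equal(estimate_null(beta2, array(TRUE, d))$mu_nawm, 0)
  ## single-valued NAWM rejected
  expect_error(estimate_null(array(0.01, d), array(TRUE, d)),
               "zero variance")
  expect_error(estimate_null(beta, mask, min_voxels = 1e6), "at least")
})

test_that("Z transform is exact by construction", {
  d <- c(10, 10, 10)
  set.seed(12)
  beta <- array(rnorm(prod(d)), d)
  mask <- array(TRUE, d)
  nl <- estimate_null(beta, mask)
  z <- slopes_to_z(beta, nl)
  expect_equal(slopes_to_z(array(nl$mu_nawm, d), nl), array(0, d))
  expect_equal(slopes_to_z(array(nl$mu_nawm + 2 * nl$sigma_nawm, d), nl),
               array(2, d), tolerance = 1e-12)
  ## over NAWM: mean 0, SD 1 to 1e-10
  expect_lt(abs(mean(z[mask])), 1e-10)
  expect_lt(abs(sd(z[mask]) - 1), 1e-10)
})

test_that("heteroscedastic standardization keeps the NAWM null at unit
           scale", {
  d <- c(10, 10, 10)
  set.seed(13)
  beta <- array(rnorm(prod(d)), d)
  mask <- array(TRUE, d)
  nl <- estimate_null(beta, mask)
  r <- array(runif(prod(d), 0.5, 1), d)
  z <- slopes_to_z(beta, nl, noise_scale = r, nawm_mask = mask)
  expect_true(is.finite(sd(z)))
  expect_error(slopes_to_z(beta, nl, noise_scale = r), "nawm_mask")
})
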