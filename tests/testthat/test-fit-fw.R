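scheme <- default_scheme()

test_that("noiseless bi-tensor round trip is identifiable without oracle
           initialization over the f x FA grid", {
  cases <- expand.grid(f = seq(0, 0.9, by = 0.1), fa = seq(0.2, 0.8, by = 0.2))
  d6 <- t(apply(cases, 1, function(r)
    tensor_from_fa_md(r[["fa"]], 0.7e-3, c(1, 0.3, 0.2))))
  sig <- bitensor_signal(500, cases$f, d6, scheme)
  fit <- fit_freewater_singleshell(sig, scheme,
                                   opts = fw_fit_options(refine = "optimize"))
  expect_lt(max(abs(fit$f - cases$f)), 0.01)
  expect_lt(max(abs(fit$fa_tissue - cases$fa)), 0.01)
})

test_that("boundary cases: pure free water and pure tissue", {
  d6 <- tensor_from_fa_md(0.5, 0.7e-3, c(1, 1, 0))
  sig1 <- bitensor_signal(500, 1, d6, scheme)
  fit1 <- fit_freewater_singleshell(sig1, scheme)
  expect_gte(fit1$f, 0.99)

  sig0 <- bitensor_signal(500, 0, d6, scheme)
  fit0 <- fit_freewater_singleshell(sig0, scheme,
                                    opts = fw_fit_options(refine = "optimize"))
  wls <- fit_dti_wls(sig0, scheme)
  expect_lte(fit0$f, 0.01)
  expect_lt(abs(fit0$fa_tissue - wls$fa), 0.01)
})

test_that("oracle initialization pins the noiseless fit to 1e-4", {
  d6 <- tensor_from_fa_md(0.6, 0.65e-3, c(0, 1, 1))
  sig <- bitensor_signal(500, 0.3, d6, scheme)
  fit <- fit_freewater_singleshell(
    sig, scheme,
    opts = fw_fit_options(refine = "optimize", f_init = 0.3,
                          init_halfwidth = 0.05))
  expect_lt(abs(fit$f - 0.3), 1e-4)
})

test_that("adding free water raises conventional MD and lowers conventional
           FA while tissue-corrected scalars stay put", {
  d6 <- tensor_from_fa_md(0.6, 0.65e-3, c(1, 0.2, 0))
  f_levels <- c(0, 0.2, 0.4)
  conv_md <- conv_fa <- tis_md <- tis_fa <- numeric(length(f_levels))
  for (i in seq_along(f_levels)) {
    sig <- bitensor_signal(500, f_levels[i], d6, scheme)
    conv <- fit_dti_wls(sig, scheme)
    conv_md[i] <- conv$md; conv_fa[i] <- conv$fa
    fw <- fit_freewater_singleshell(sig, scheme,
                                    opts = fw_fit_options(refine = "optimize"))
    tis_md[i] <- fw$md_tissue; tis_fa[i] <- fw$fa_tissue
  }
  expect_true(all(diff(conv_md) > 0))
  expect_true(all(diff(conv_fa) < 0))
  expect_lt(max(abs(tis_md - 0.65e-3)), 2e-5)
  expect_lt(max(abs(tis_fa - 0.6)), 0.02)
})

test_that("all-zero voxels are marked unfit and excluded", {
  d6 <- tensor_from_fa_md(0.5, 0.7e-3)
  sig <- rbind(bitensor_signal(500, 0.2, d6, scheme), 0)
  fit <- fit_freewater_singleshell(sig, scheme)
  expect_equal(fit$n_unfit, 1L)
  expect_true(is.na(fit$f[2]))
  expect_false(is.na(fit$f[1]))
})

test_that("anchored mode recovers class means at clinical SNR", {
  set.seed(11)
  classes <- list(nawm = c(f = 0.205, fa = 0.479, md = 6.06e-4),
                  wmh = c(f = 0.520, fa = 0.385, md = 6.91e-4))
  for (cl in classes) {
    n <- 600
    ax <- matrix(rnorm(3 * n), n, 3)
    d6 <- t(sapply(seq_len(n), function(i)
      tensor_from_fa_md(cl[["fa"]], cl[["md"]], ax[i, ])))
    sig <- add_noise(bitensor_signal(500, cl[["f"]], d6, scheme),
                     500 / 40, "rician")
    fit <- fit_freewater_singleshell(sig, scheme,
                                     opts = fw_fit_options(method = "anchored"))
    expect_lt(abs(mean(fit$f) - cl[["f"]]), 0.02)
    expect_lt(abs(mean(fit$fa_tissue) - cl[["fa"]]), 0.03)
    expect_lt(abs(mean(fit$md_tissue) - cl[["md"]]), 0.4e-4)
  }
})

test_that("fit_map reshapes fitted vectors onto the source grid", {
  subj <- small_subject()
  wm <- subj$truth$tissue_labels == 3L
  ## single-slab fit keeps this quick
  mask <- array(FALSE, dim(wm)); mask[, , 20:28] <- wm[, , 20:28]
  fit <- fit_freewater_singleshell(subj$dwi$t1, subj$scheme, mask = mask,
                                   opts = fw_fit_options(method = "anchored"))
  fmap <- fit_map(fit, "f")
  expect_equal(dim(fmap), dim(wm))
  expect_true(all(is.na(fmap[!mask])))
  expect_true(all(!is.na(fmap[mask])))
})
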