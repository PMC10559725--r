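## toy clustered binary data used across several blocks
make_toy <- function(seed = 18, n_sub = 3, per = 10) {
  set.seed(seed)
  data.frame(
    subject = rep(seq_len(n_sub), each = per),
    x = rnorm(n_sub * per),
    z = rnorm(n_sub * per),
    outcome = rbinom(n_sub * per, 1, 0.4))
}

test_that("cluster sandwich agrees with the sandwich-package reference", {
  ## sandwich::estfun builds scores from working residuals, which differ
  ## from the analytic (y - p) X by ~1e-7 relative rounding, so this
  ## cross-check is at 1e-6; the exact 1e-8 check is against the
  ## hand-coded oracle below
  d <- make_toy(18, 5, 40)
  fit <- fit_logistic_clustered(outcome ~ x + z, d)
  g <- glm(outcome ~ x + z, data = d, family = binomial())
  V_o <- sandwich::vcovCL(g, cluster = d$subject, type = "HC0",
                          cadjust = FALSE)
  expect_lt(max(abs(fit$vcov - V_o)), 1e-6)
})

test_that("each row its own cluster reduces to HC0", {
  d <- make_toy(19, 1, 60)
  d$subject <- seq_len(nrow(d))
  fit <- fit_logistic_clustered(outcome ~ x, d)
  g <- glm(outcome ~ x, data = d, family = binomial())
  expect_lt(max(abs(fit$vcov - sandwich::vcovHC(g, type = "HC0"))), 1e-6)
})

test_that("coefficients and SEs match a hand-coded Newton-Raphson +
           sandwich oracle on a 30-row table", {
  d <- make_toy(20, 3, 10)
  fit <- fit_logistic_clustered(outcome ~ x, d)
  ## independent oracle: IRLS from scratch + explicit sandwich
  X <- cbind(1, d$x)
  y <- d$outcome
  b <- c(0, 0)
  for (i in 1:50) {
    p <- 1 / (1 + exp(-X %*% b))
    W <- as.numeric(p * (1 - p))
    b <- b + solve(t(X) %*% (W * X), t(X) %*% (y - p))
  }
  bread <- solve(t(X) %*% (as.numeric(p * (1 - p)) * X))
  s <- X * as.numeric(y - p)
  sg <- rowsum(s, d$subject)
  V <- bread %*% crossprod(sg) %*% bread
  expect_lt(max(abs(fit$coefficients - b)), 1e-8)
  expect_lt(max(abs(fit$vcov - V)), 1e-8)
  ## McFadden pseudo-R2 from the same likelihoods
  ll <- sum(y * log(p) + (1 - y) * log(1 - p))
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  expect_equal(fit$pseudo_r2, 1 - ll / ll0, tolerance = 1e-8)
})

test_that("a predictor independent of the outcome stays within 3 SE of 0", {
  set.seed(21)
  d <- data.frame(subject = rep(1:20, each = 200))
  d$x <- rnorm(nrow(d))
  d$outcome <- rbinom(nrow(d), 1, 0.3)
  fit <- fit_logistic_clustered(outcome ~ x, d)
  expect_lt(abs(fit$z[["x"]]), 3)
})

test_that("clustered SEs exceed naive SEs under intra-cluster correlation", {
  set.seed(22)
  wins <- 0
  for (r in 1:20) {
    n_sub <- 12; per <- 50
    u <- rnorm(n_sub, 0, 1.5)
    d <- data.frame(subject = rep(seq_len(n_sub), each = per))
    d$x <- rnorm(n_sub * per) + rep(rnorm(n_sub), each = per)
    eta <- -0.5 + 0.4 * d$x + rep(u, each = per)
    d$outcome <- rbinom(nrow(d), 1, plogis(eta))
    if (length(unique(d$outcome)) < 2) next
    fit <- fit_logistic_clustered(outcome ~ x, d)
    naive <- summary(fit$glm_fit)$coefficients["x", "Std. Error"]
    if (fit$se[["x"]] >= naive) wins <- wins + 1
  }
  expect_gte(wins, 17)
})

test_that("degenerate logistic inputs are rejected or flagged", {
  d <- make_toy(23)
  d1 <- d; d1$subject <- 1
  expect_error(fit_logistic_clustered(outcome ~ x, d1), "2 clusters")
  d2 <- d; d2$outcome <- 1
  expect_error(fit_logistic_clustered(outcome ~ x, d2), "both classes")
  ## complete separation flagged
  d3 <- data.frame(subject = rep(1:2, each = 10),
                   x = c(rnorm(10, -5), rnorm(10, 5)),
                   outcome = rep(c(0, 1), each = 10))
  warns <- capture_warnings(fit3 <- fit_logistic_clustered(outcome ~ x, d3))
  expect_true(any(grepl("separation", warns)))
  expect_true(fit3$separation)
})

test_that("AUC equals exhaustive pair enumeration, including ties", {
  set.seed(24)
  scores <- round(rnorm(20), 1)        # rounding forces ties
  y <- rbinom(20, 1, 0.5)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  r <- roc_auc(scores, y)
  pos <- scores[y == 1]; neg <- scores[y == 0]
  conc <- 0
  for (a in pos) for (b in neg)
    conc <- conc + (a > b) + 0.5 * (a == b)
  expect_equal(r$auc, conc / (length(pos) * length(neg)), tolerance = 1e-12)
})

test_that("AUC trivials, invariance and bootstrap plumbing", {
  ## perfectly ordered
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  ## all scores identical
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  ## invariance under strictly increasing transforms
  set.seed(25)
  s <- rnorm(50); y <- rbinom(50, 1, 0.5); y[1:2] <- c(0, 1)
  expect_equal(roc_auc(s, y)$auc, roc_auc(exp(s), y)$auc)
  expect_equal(roc_auc(s, y)$auc, roc_auc(qlogis(plogis(s)), y)$auc,
               tolerance = 1e-12)
  ## agreement with the pROC reference implementation (fixed direction:
  ## larger score = positive class)
  proc_auc <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(y, s, levels = c(0, 1), direction = "<",
                        quiet = TRUE))))
  expect_equal(roc_auc(s, y)$auc, proc_auc, tolerance = 1e-12)
  ## single class rejected
  expect_error(roc_auc(s, rep(1, 50)), "both")
  ## subject bootstrap returns an ordered CI containing the estimate
  ids <- rep(1:10, 5)
  set.seed(26)
  r <- roc_auc(s, y, ids, n_boot = 100)
  expect_lte(r$auc_ci[1], r$auc_ci[2])
  ## curve is monotone
  expect_true(all(diff(r$sensitivity) >= 0))
  expect_true(all(diff(r$specificity) <= 0))
})

test_that("Liu cutoff equals exhaustive search and handles separation", {
  set.seed(27)
  s <- rnorm(10); y <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1)
  got <- liu_cutoff(s, y)
  ## exhaustive oracle over a fine threshold grid
  grid <- sort(unique(c(s - 1e-9, s + 1e-9, seq(min(s) - 1, max(s) + 1,
                                                length.out = 2000))))
  crit <- vapply(grid, function(t)
    mean(s[y == 1] >= t) * mean(s[y == 0] < t), 0)
  expect_equal(got$criterion, max(crit), tolerance = 1e-9)
  ## perfectly separated groups: sens = spec = 1, lowest valid midpoint
  s2 <- c(1, 2, 3, 11, 12, 13); y2 <- c(0, 0, 0, 1, 1, 1)
  got2 <- liu_cutoff(s2, y2)
  expect_equal(got2$sens, 1)
  expect_equal(got2$spec, 1)
  expect_equal(got2$cutoff, 7)      # midpoint of 3 and 11
  expect_error(liu_cutoff(s2, rep(1, 6)), "both")
})

test_that("ROI mixed model reduces to pooled OLS without between-subject
           variance and nulls out for identical series", {
  times <- c(0, 0.5, 1)
  rois <- c("nawm", "pen_prog")
  ## zero between-subject variance, exact slopes
  d <- expand.grid(subject = 1:6, roi = rois, time = times)
  slope <- ifelse(d$roi == "pen_prog", 0.06, 0.01)
  d$value <- 1 + slope * d$time
  suppressWarnings(suppressMessages(fit <- roi_longitudinal(d)))
  ols <- coef(lm(value ~ time, d[d$roi == "pen_prog", ]))[["time"]]
  got <- fit$slopes$annual_change[fit$slopes$roi == "pen_prog"]
  expect_equal(got, ols, tolerance = 1e-6)
  expect_equal(fit$contrasts$vs_ref[fit$contrasts$roi == "pen_prog"],
               0.05, tolerance = 1e-6)
  ## identical series in both ROIs: interaction exactly 0
  d2 <- d; d2$value <- 1 + 0.02 * d2$time
  suppressWarnings(suppressMessages(fit2 <- roi_longitudinal(d2)))
  expect_equal(fit2$contrasts$vs_ref, 0, tolerance = 1e-8)
  ## unidentifiable single subject rejected
  expect_error(roi_longitudinal(d[d$subject == 1, ]), "2 subjects")
})

test_that("ROI mixed model recovers an injected slope within its CI", {
  set.seed(28)
  times <- c(0, 0.25, 0.5, 0.75, 1)
  d <- expand.grid(subject = 1:8, roi = c("nawm", "pen_prog"), time = times)
  u <- rnorm(8, 0, 0.02)
  slope <- ifelse(d$roi == "pen_prog", 0.034, 0)
  d$value <- 0.2 + u[d$subject] + slope * d$time + rnorm(nrow(d), 0, 0.005)
  suppressWarnings(suppressMessages(fit <- roi_longitudinal(d)))
  ct <- fit$contrasts[fit$contrasts$roi == "pen_prog", ]
  expect_lt(abs(ct$vs_ref - 0.034), 2.5 * ct$se)
  nawm_slope <- fit$slopes[fit$slopes$roi == "nawm", ]
  expect_lt(abs(nawm_slope$annual_change), 3 * nawm_slope$se)
})

test_that("assemble_design pools penumbra voxels with conservation", {
  subj <- small_subject()
  res <- analyze_subject(subj, pipeline_options(fit_longitudinal_dwi = FALSE,
                                                n_boot = 0))
  per <- list(list(partition = res$partition, fw = res$fw,
                   fa_tissue = res$fa_tissue, md_tissue = res$md_tissue,
                   covariates = res$covariates))
  des <- assemble_design(per)
  expect_equal(nrow(des),
               sum(res$partition$pen_prog) + sum(res$partition$pen_stable))
  expect_true(all(des$outcome %in% 0:1))
  expect_true(all(is.finite(des$fw)))
  ## empty penumbra contributes zero rows
  empty <- per[[1]]
  empty$partition$pen_prog[] <- FALSE
  empty$partition$pen_stable[] <- FALSE
  expect_equal(nrow(assemble_design(list(empty))), 0L)
})
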