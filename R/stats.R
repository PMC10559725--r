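## Pooled penumbra-voxel statistics: cluster-robust logistic regression,
## ROC/AUC with subject-level bootstrap, the Liu cutoff, and ROI-level
## longitudinal mixed models.

#' Assemble the pooled voxel design table
#'
#' One row per penumbra voxel across all subjects: the binary outcome
#' (progressing = 1, stable = 0), baseline diffusion metrics at that voxel,
#' and the subject-level covariates.
#'
#' @param per_subject list; each element needs `partition` (a
#'   `roi_partition`), `fw`, `fa_tissue`, `md_tissue` (3D baseline metric
#'   maps) and `covariates` (1-row data.frame with `subject`, `age`, `sex`,
#'   `race`, `site`, `baseline_wmh_ml`).
#' @return data.frame with columns `subject`, `outcome`, `fw`, `fa_tissue`,
#'   `md_tissue`, `age`, `sex`, `race`, `site`, `baseline_wmh_ml`.
#' @export
assemble_design <- function(per_subject) {
  rows <- lapply(per_subject, function(s) {
    check_same_grid(s$partition$pen_prog, s$fw, s$fa_tissue, s$md_tissue)
    pen <- s$partition$pen_prog | s$partition$pen_stable
    idx <- which(pen)
    if (!length(idx)) return(NULL)
    df <- data.frame(
      subject = s$covariates$subject,
      outcome = as.integer(s$partition$pen_prog[idx]),
      fw = s$fw[idx], fa_tissue = s$fa_tissue[idx],
      md_tissue = s$md_tissue[idx])
    df$age <- s$covariates$age
    df$sex <- s$covariates$sex
    df$race <- s$covariates$race
    df$site <- s$covariates$site
    df$baseline_wmh_ml <- s$covariates$baseline_wmh_ml
    df
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

#' Logistic regression with cluster-robust (sandwich) standard errors
#'
#' Maximum-likelihood logistic fit with covariance
#' `V = B (sum_g s_g s_g') B` where `B` is the inverse Fisher information
#' (the model-based covariance) and `s_g` is the summed score vector of
#' cluster `g` — the standard cluster sandwich that adjusts for
#' non-independence of voxels within a subject. McFadden pseudo-R^2
#' (`1 - ll/ll_null`) is reported.
#'
#' @param formula model formula (outcome must be 0/1).
#' @param data design table, e.g. from [assemble_design()].
#' @param cluster name of the cluster id column (default `"subject"`).
#' @return object of class `logistic_clustered`: `coefficients`, `se`
#'   (cluster-robust), `vcov`, `z`, `p`, `loglik`, `loglik_null`,
#'   `pseudo_r2`, `n`, `n_clusters`, `separation` flag and the underlying
#'   `glm` fit.
#' @export
fit_logistic_clustered <- function(formula, data, cluster = "subject") {
  cl <- data[[cluster]]
  if (is.null(cl)) stop("cluster column '", cluster, "' not found")
  if (length(unique(cl)) < 2L) stop("need at least 2 clusters")
  y <- stats::model.response(stats::model.frame(formula, data))
  if (length(unique(y)) < 2L) stop("outcome must contain both classes")
  fit <- glm(formula, data = data, family = binomial(),
             control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  X <- model.matrix(fit)
  ## aliased (rank-deficient) columns are excluded from the sandwich just
  ## as glm excludes them from the fit
  keep_cols <- !is.na(coef(fit))
  X <- X[, keep_cols, drop = FALSE]
  ## polish to the exact stationary point (IRLS stops on a deviance
  ## criterion, leaving ~1e-8 in the coefficients) so the sandwich is
  ## evaluated at the true MLE
  beta <- coef(fit)[keep_cols]
  for (i in 1:8) {
    p_hat <- as.numeric(1 / (1 + exp(-X %*% beta)))
    w <- p_hat * (1 - p_hat)
    grad <- crossprod(X, fit$y - p_hat)
    if (max(abs(grad)) < 1e-12) break
    step <- tryCatch(solve(crossprod(X, w * X), grad),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)) ||
        max(abs(step)) > 10) break               # diverging (separation)
    beta <- beta + step
  }
  p_hat <- as.numeric(1 / (1 + exp(-X %*% beta)))
  separation <- any(p_hat > 1 - 1e-8) || any(p_hat < 1e-8) || !fit$converged
  if (separation)
    warning("possible complete separation: fitted probabilities at 0/1 ",
            "or non-convergence; coefficients reported with caution")
  w <- p_hat * (1 - p_hat)
  scores <- X * (fit$y - p_hat)                 # per-row score vectors
  sg <- rowsum(scores, cl)                       # per-cluster sums
  meat <- crossprod(as.matrix(sg))
  bread <- tryCatch(solve(crossprod(X, w * X)),  # (X'WX)^{-1}
                    error = function(e) summary(fit)$cov.unscaled)
  V <- bread %*% meat %*% bread
  eps <- .Machine$double.eps
  ll <- sum(fit$y * log(pmax(p_hat, eps)) +
              (1 - fit$y) * log(pmax(1 - p_hat, eps)))
  fit0 <- glm(stats::update(formula, . ~ 1), data = data, family = binomial())
  ll0 <- as.numeric(logLik(fit0))
  se <- sqrt(diag(V))
  names(beta) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  z <- beta / se
  structure(list(coefficients = beta, se = se, vcov = V, z = z,
                 p = 2 * pnorm(-abs(z)), loglik = ll, loglik_null = ll0,
                 pseudo_r2 = 1 - ll / ll0, n = nrow(X),
                 n_clusters = length(unique(cl)), separation = separation,
                 glm_fit = fit), class = "logistic_clustered")
}

#' @export
print.logistic_clustered <- function(x, ...) {
  cat("Cluster-robust logistic regression\n")
  cat(sprintf("  n = %d voxels in %d clusters; pseudo-R2 (McFadden) = %.4f\n",
              x$n, x$n_clusters, x$pseudo_r2))
  tab <- data.frame(estimate = x$coefficients, se = x$se, z = x$z, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

## Mann-Whitney AUC (ties count 1/2), rank-based.
auc_mw <- function(scores, outcomes) {
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  r <- rank(scores)
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC with subject-level bootstrap CI
#'
#' AUC is computed with the Mann-Whitney pair-count identity (ties count
#' one half). The bootstrap resamples subjects (clusters) with replacement
#' — not voxels, which would ignore within-subject dependence — and the CI
#' is the percentile interval.
#'
#' @param scores numeric predictor (larger = more likely progressing).
#' @param outcomes 0/1 outcome.
#' @param subject_ids cluster ids (required when `n_boot > 0`).
#' @param n_boot bootstrap replicates (0 = no CI).
#' @param conf confidence level.
#' @return object of class `roc_result`: `auc`, `auc_ci`, `thresholds`,
#'   `sensitivity`, `specificity`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, outcomes, subject_ids = NULL, n_boot = 0,
                    conf = 0.95) {
  keep <- is.finite(scores) & !is.na(outcomes)
  scores <- scores[keep]; outcomes <- outcomes[keep]
  if (!is.null(subject_ids)) subject_ids <- subject_ids[keep]
  if (length(unique(outcomes)) < 2L)
    stop("both outcome classes must be present")
  auc <- auc_mw(scores, outcomes)
  ## ROC curve at thresholds = unique scores (predict positive if
  ## score >= threshold), plus the all-negative endpoint
  o <- order(scores, decreasing = TRUE)
  s_sorted <- scores[o]
  y_sorted <- outcomes[o]
  tp <- cumsum(y_sorted == 1)
  fp <- cumsum(y_sorted == 0)
  last <- !duplicated(s_sorted, fromLast = TRUE)   # last row of each tie block
  n1 <- sum(outcomes == 1); n0 <- sum(outcomes == 0)
  thr <- c(Inf, s_sorted[last])
  sens <- c(0, tp[last] / n1)
  spec <- c(1, 1 - fp[last] / n0)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (is.null(subject_ids))
      stop("subject_ids required for the subject-level bootstrap")
    ids <- unique(subject_ids)
    by_id <- split(seq_along(scores), subject_ids)
    boots <- numeric(0)
    for (b in seq_len(n_boot)) {
      take <- unlist(by_id[as.character(sample(ids, replace = TRUE))],
                     use.names = FALSE)
      yb <- outcomes[take]
      if (length(unique(yb)) < 2L) next
      boots <- c(boots, auc_mw(scores[take], yb))
    }
    a <- (1 - conf) / 2
    ci <- unname(quantile(boots, c(a, 1 - a), na.rm = TRUE))
  }
  structure(list(auc = auc, auc_ci = ci, thresholds = thr,
                 sensitivity = sens, specificity = spec,
                 n_pos = n1, n_neg = n0), class = "roc_result")
}

#' Liu optimal cutoff: maximize sensitivity x specificity
#'
#' Candidate thresholds are the midpoints of consecutive sorted unique
#' scores (plus outer sentinels); a voxel is called progressing if its
#' score is at or above the cutoff. Ties in the criterion break toward the
#' lower threshold.
#'
#' @param scores numeric predictor.
#' @param outcomes 0/1 outcome (both classes required).
#' @return list with `cutoff`, `sens`, `spec`, `criterion`.
#' @export
liu_cutoff <- function(scores, outcomes) {
  if (length(unique(outcomes)) < 2L)
    stop("both outcome classes must be present")
  u <- sort(unique(scores))
  cand <- if (length(u) > 1)
    c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  else c(u - 1, u + 1)
  n1 <- sum(outcomes == 1); n0 <- sum(outcomes == 0)
  best <- c(crit = -Inf, cutoff = NA, sens = NA, spec = NA)
  for (t in cand) {
    sens <- sum(scores >= t & outcomes == 1) / n1
    spec <- sum(scores < t & outcomes == 0) / n0
    crit <- sens * spec
    if (crit > best[["crit"]] + 1e-12)
      best <- c(crit = crit, cutoff = t, sens = sens, spec = spec)
  }
  list(cutoff = unname(best[2]), sens = unname(best[3]),
       spec = unname(best[4]), criterion = unname(best[1]))
}

#' ROI-level longitudinal mixed model (tissue-by-time interaction)
#'
#' Random-intercept linear model of an ROI-mean measure on
#' `roi * time (+ covariates)` with NAWM as the reference level, fitted
#' with `lme4::lmer`. The per-ROI annual change is `time + roi:time`; the
#' difference of each ROI's change versus NAWM is the interaction
#' coefficient, reported with Bonferroni-adjusted (normal-approximation)
#' p-values.
#'
#' @param data long data.frame with columns `subject`, `roi`, `time`
#'   (years), `value`, plus any covariates.
#' @param covariates character vector of covariate column names (e.g.
#'   `c("site", "age", "sex", "race", "baseline_wmh_ml")`); default none.
#' @param ref_roi reference tissue level (default `"nawm"`).
#' @return object of class `roi_longitudinal`: `slopes` (per-ROI annual
#'   change with SE), `contrasts` (vs reference, with Bonferroni p),
#'   `model` (the lmer fit).
#' @export
roi_longitudinal <- function(data, covariates = character(0),
                             ref_roi = "nawm") {
  stopifnot(all(c("subject", "roi", "time", "value") %in% names(data)))
  if (length(unique(data$subject)) < 2L)
    stop("need at least 2 subjects for the random-intercept model")
  data$roi <- stats::relevel(factor(data$roi), ref = ref_roi)
  rhs <- "roi * time"
  if (length(covariates))
    rhs <- paste(rhs, "+", paste(covariates, collapse = " + "))
  form <- as.formula(paste("value ~", rhs, "+ (1 | subject)"))
  fit <- lme4::lmer(form, data = data, REML = TRUE)
  fe <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  rois <- levels(data$roi)
  ## per-ROI slope = time (+ roi:time when not the reference)
  slope_rows <- lapply(rois, function(rr) {
    cvec <- setNames(numeric(length(fe)), names(fe))
    cvec["time"] <- 1
    nm <- paste0("roi", rr, ":time")
    if (nm %in% names(fe)) cvec[nm] <- 1
    est <- sum(cvec * fe)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    data.frame(roi = rr, annual_change = est, se = se)
  })
  slopes <- do.call(rbind, slope_rows)
  others <- setdiff(rois, ref_roi)
  contr_rows <- lapply(others, function(rr) {
    nm <- paste0("roi", rr, ":time")
    est <- fe[[nm]]
    se <- sqrt(V[nm, nm])
    z <- est / se
    data.frame(roi = rr, vs_ref = est, se = se, z = z,
               p_bonferroni = pmin(2 * pnorm(-abs(z)) * length(others), 1))
  })
  contrasts <- do.call(rbind, contr_rows)
  rownames(slopes) <- rownames(contrasts) <- NULL
  structure(list(slopes = slopes, contrasts = contrasts, model = fit,
                 ref_roi = ref_roi), class = "roi_longitudinal")
}
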