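## End-to-end orchestration: simulate -> fit-fw -> rois -> map -> predict.
## Subjects are processed one at a time (volumes are dropped after
## analysis) so a full cohort fits comfortably in memory.

#' Analysis options for the pipeline
#'
#' @param z_thresh cluster-forming threshold on the slope Z map.
#' @param p_thresh GRF cluster-level threshold.
#' @param connectivity cluster neighbour rule.
#' @param cluster_mask `"wm"` (default: GRF search over the whole white
#'   matter mask) or `"penumbra"` (restricted).
#' @param denoise apply non-local means to the normalized FLAIR before
#'   slope fitting.
#' @param nlm_patch_radius,nlm_search_radius non-local means window sizes.
#' @param fw_opts options for the free-water fit; the pipeline default is
#'   the `"anchored"` mode (see [fw_fit_options()]).
#' @param fit_longitudinal_dwi fit free water at every timepoint (needed
#'   for the DTI mixed models), not just baseline.
#' @param predictors score columns for the voxel-wise prediction models.
#' @param covariates subject-level covariates entered in the logistic
#'   models (the clinical set; site included by default).
#' @param n_boot bootstrap replicates for AUC confidence intervals.
#' @param exclusion_dilate_mm peri-infarct exclusion: the infarct mask is
#'   dilated by this radius before subtraction.
#' @param heteroscedastic_z standardize slopes with the denoiser's
#'   per-voxel noise-scale map instead of a single global NAWM SD.
#'   Default `FALSE`: the global null follows the published method, and
#'   lesion-adjacent voxels — exactly where progression happens — would
#'   otherwise be penalized for their locally reduced averaging; boundary
#'   excursions of either sign that slip through are neutralized by the
#'   AND rule (significant increase AND new segmentation).
#' @return list of options.
#' @export
pipeline_options <- function(z_thresh = 2.3, p_thresh = 0.01,
                             connectivity = 26,
                             cluster_mask = c("wm", "penumbra"),
                             denoise = TRUE,
                             nlm_patch_radius = 1, nlm_search_radius = 2,
                             fw_opts = fw_fit_options(method = "anchored"),
                             fit_longitudinal_dwi = TRUE,
                             predictors = c("fw", "md_tissue", "fa_tissue"),
                             covariates = c("age", "sex", "race", "site",
                                            "baseline_wmh_ml"),
                             n_boot = 200,
                             exclusion_dilate_mm = 3,
                             heteroscedastic_z = FALSE) {
  list(z_thresh = z_thresh, p_thresh = p_thresh,
       connectivity = connectivity, cluster_mask = match.arg(cluster_mask),
       denoise = denoise, nlm_patch_radius = nlm_patch_radius,
       nlm_search_radius = nlm_search_radius, fw_opts = fw_opts,
       fit_longitudinal_dwi = fit_longitudinal_dwi, predictors = predictors,
       covariates = covariates, n_boot = n_boot,
       exclusion_dilate_mm = exclusion_dilate_mm,
       heteroscedastic_z = heteroscedastic_z)
}

roi_mean <- function(vol, mask) {
  if (!any(mask)) return(NA_real_)
  mean(vol[mask], na.rm = TRUE)
}

#' Analyze one subject end to end
#'
#' Runs GM-normalization, optional non-local means denoising, per-voxel
#' slope fitting, the stable-NAWM Z transform, GRF cluster correction,
#' penumbra construction and classification (AND rule), annualized growth,
#' and the baseline (plus optional longitudinal) free-water fits.
#'
#' @param subj output of [simulate_subject()] (or an equivalently shaped
#'   list built from real volumes).
#' @param opts a [pipeline_options()] list.
#' @return list with `partition`, `growth`, `zmap`, `clusters`,
#'   `fw`, `fa_tissue`, `md_tissue` (baseline maps), `roi_long` (long
#'   data.frame of per-ROI, per-timepoint means of normalized FLAIR and,
#'   when fitted, DTI metrics), `covariates`, `null_params`.
#' @export
analyze_subject <- function(subj, opts = pipeline_options()) {
  truth <- subj$truth
  config <- subj$config
  d <- truth$dim
  vs <- truth$voxel_size
  times <- config$timepoints
  gm <- truth$tissue_labels == LBL_GM
  wm <- truth$tissue_labels == LBL_WM
  seg <- subj$seg_masks
  baseline <- seg[[1]]

  exclusion <- if (any(truth$infarct_mask))
    dilate_mm(truth$infarct_mask, opts$exclusion_dilate_mm, vs)
  else truth$infarct_mask

  ## FLAIR: normalize (gain cancels), then denoise for the voxel-wise map
  norm <- lapply(subj$flair, normalize_flair, gm_mask = gm)
  proc <- if (opts$denoise)
    denoise_nlm_series(norm, patch_radius = opts$nlm_patch_radius,
                       search_radius = opts$nlm_search_radius, mask = wm)
  else norm

  ## penumbra and the stable-NAWM null region
  pconf <- penumbra_config(radius_mm = config$penumbra_radius_mm,
                           connectivity = opts$connectivity)
  penumbra <- build_penumbra(seg, baseline, wm, exclusion, pconf, vs)
  union_lesion <- Reduce(`|`, seg)
  nawm <- wm & !union_lesion & !penumbra & !exclusion

  slopes <- fit_voxel_slopes(proc, times, mask = wm)
  nullp <- estimate_null(slopes, nawm)
  zmap <- if (opts$heteroscedastic_z && !is.null(attr(proc, "noise_scale")))
    slopes_to_z(slopes, nullp, noise_scale = attr(proc, "noise_scale"),
                nawm_mask = nawm)
  else slopes_to_z(slopes, nullp)
  zmap[!wm] <- 0
  search_mask <- if (opts$cluster_mask == "penumbra") penumbra else wm
  clusters <- grf_cluster_correct(zmap, search_mask,
                                  z_thresh = opts$z_thresh,
                                  p_thresh = opts$p_thresh,
                                  connectivity = opts$connectivity)

  partition <- classify_penumbra(penumbra, seg,
                                 clusters$significant_increase,
                                 wm_mask = wm, baseline_wmh = baseline,
                                 exclusion_mask = exclusion)
  growth <- annualized_growth(partition, vs, max(times) - min(times),
                              ticv_vox = sum(truth$tissue_labels != LBL_BG))

  ## free-water fits (baseline always; longitudinal when volumes exist)
  fit_mask <- wm
  fw <- fa_tissue <- md_tissue <- NULL
  roi_masks <- list(nawm = partition$nawm,
                    pen_stable = partition$pen_stable,
                    pen_prog = partition$pen_prog,
                    wmh = partition$baseline_wmh)
  roi_rows <- list()
  add_rows <- function(rows, measure, vol, t) {
    for (rn in names(roi_masks))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj$covariates$subject, roi = rn, time = t,
        measure = measure, value = roi_mean(vol, roi_masks[[rn]]))
    rows
  }
  for (i in seq_along(norm))
    roi_rows <- add_rows(roi_rows, "flair", norm[[i]], times[i])

  if (!is.null(subj$dwi)) {
    tp_idx <- as.integer(sub("^t", "", names(subj$dwi)))
    for (j in seq_along(subj$dwi)) {
      if (!opts$fit_longitudinal_dwi && tp_idx[j] != 1L) next
      fit <- fit_freewater_singleshell(subj$dwi[[j]], subj$scheme,
                                       mask = fit_mask, opts = opts$fw_opts)
      fmap <- fit_map(fit, "f")
      famap <- fit_map(fit, "fa_tissue")
      mdmap <- fit_map(fit, "md_tissue")
      t <- times[tp_idx[j]]
      roi_rows <- add_rows(roi_rows, "fw", fmap, t)
      roi_rows <- add_rows(roi_rows, "fa_tissue", famap, t)
      roi_rows <- add_rows(roi_rows, "md_tissue", mdmap, t)
      if (tp_idx[j] == 1L) {
        fw <- fmap; fa_tissue <- famap; md_tissue <- mdmap
      }
    }
  }

  list(partition = partition, growth = growth, zmap = zmap,
       clusters = clusters, fw = fw, fa_tissue = fa_tissue,
       md_tissue = md_tissue, roi_long = do.call(rbind, roi_rows),
       covariates = subj$covariates, null_params = nullp,
       penumbra = penumbra, voxel_size = vs)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates `config$n_subjects` subjects one at a time, analyzes each
#' ([analyze_subject()]), pools penumbra voxels into the design table, fits
#' the cluster-robust logistic / ROC models per predictor (plus a
#' clinical-covariates-only model), fits the ROI-level longitudinal mixed
#' models, and returns a report.
#'
#' @param config a [cohort_config()].
#' @param opts a [pipeline_options()] list.
#' @param scheme acquisition scheme.
#' @param mixed_covariates covariates entered in the ROI mixed models
#'   (default none: with small simulated cohorts the subject-level
#'   covariates are exchangeable noise).
#' @return object of class `pipeline_report` (a list): `growth`
#'   (per-subject ml/year and the cohort median), `roc` (per predictor),
#'   `logistic` (per predictor), `liu` (FW cutoff), `mixed` (per measure),
#'   `design_rows`, `subjects` (per-subject analysis summaries).
#' @export
run_pipeline <- function(config, opts = pipeline_options(),
                         scheme = default_scheme(),
                         mixed_covariates = character(0)) {
  per_subject <- vector("list", config$n_subjects)
  roi_long <- list()
  growth_ml <- numeric(config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    subj <- simulate_subject(config, s, scheme,
                             dwi = if (opts$fit_longitudinal_dwi) "all"
                                   else "baseline")
    res <- analyze_subject(subj, opts)
    growth_ml[s] <- res$growth$ml_per_year
    roi_long[[s]] <- res$roi_long
    per_subject[[s]] <- list(partition = res$partition, fw = res$fw,
                             fa_tissue = res$fa_tissue,
                             md_tissue = res$md_tissue,
                             covariates = res$covariates,
                             growth = res$growth,
                             null_params = res$null_params)
    rm(subj, res)
  }
  design <- assemble_design(per_subject)
  roi_long <- do.call(rbind, roi_long)

  ## voxel-wise prediction models; covariates that are constant in this
  ## cohort (possible at small n) cannot enter the design matrix
  roc <- list(); logit <- list()
  set.seed(derive_seed(config$seed, 0L, 99L))
  usable_covs <- opts$covariates[vapply(opts$covariates, function(cv)
    length(unique(design[[cv]])) > 1L, TRUE)]
  if (!length(usable_covs)) usable_covs <- "1"
  covs <- paste(usable_covs, collapse = " + ")
  for (pr in opts$predictors) {
    keep <- is.finite(design[[pr]])
    dat <- design[keep, ]
    form <- as.formula(paste("outcome ~", pr, "+", covs))
    logit[[pr]] <- fit_logistic_clustered(form, dat)
    ## score = linear predictor of the metric's logistic model (the ROC of
    ## "the metric's logistic regression")
    roc[[pr]] <- roc_auc(predict(logit[[pr]]$glm_fit, type = "link"),
                         dat$outcome, dat$subject, n_boot = opts$n_boot)
  }
  form0 <- as.formula(paste("outcome ~", covs))
  logit$clinical <- fit_logistic_clustered(form0, design)
  roc$clinical <- roc_auc(predict(logit$clinical$glm_fit, type = "link"),
                          design$outcome, design$subject,
                          n_boot = opts$n_boot)
  liu <- liu_cutoff(design$fw[is.finite(design$fw)],
                    design$outcome[is.finite(design$fw)])

  ## ROI-level longitudinal mixed models
  mixed <- list()
  for (m in unique(roi_long$measure)) {
    dat <- roi_long[roi_long$measure == m & is.finite(roi_long$value), ]
    mixed[[m]] <- tryCatch(roi_longitudinal(dat, mixed_covariates),
                           error = function(e) e)
  }

  structure(list(
    growth = list(per_subject_ml = growth_ml,
                  median_ml_per_year = median(growth_ml),
                  mean_ml_per_year = mean(growth_ml)),
    roc = roc, logistic = logit, liu = liu, mixed = mixed,
    design_rows = nrow(design), design = design, roi_long = roi_long,
    subjects = per_subject, config = config),
    class = "pipeline_report")
}

#' Write the pipeline report as JSON (plus TSV tables)
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @return path of the JSON report, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  js <- list(
    growth_median_ml_per_year = report$growth$median_ml_per_year,
    growth_mean_ml_per_year = report$growth$mean_ml_per_year,
    auc = lapply(report$roc, function(r)
      list(auc = r$auc, ci = r$auc_ci)),
    pseudo_r2 = lapply(report$logistic, `[[`, "pseudo_r2"),
    liu = report$liu,
    design_rows = report$design_rows,
    mixed = lapply(report$mixed, function(m)
      if (inherits(m, "roi_longitudinal"))
        list(slopes = m$slopes, contrasts = m$contrasts) else NULL))
  path <- file.path(dir, "report.json")
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  write.table(report$roi_long, file.path(dir, "roi_long.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("WMH penumbra pipeline report\n")
  cat(sprintf("  subjects: %d, pooled penumbra voxels: %d\n",
              x$config$n_subjects, x$design_rows))
  cat(sprintf("  median detected growth: %.2f ml/year\n",
              x$growth$median_ml_per_year))
  for (nm in names(x$roc))
    cat(sprintf("  AUC(%s) = %.3f [%.3f, %.3f]\n", nm, x$roc[[nm]]$auc,
                x$roc[[nm]]$auc_ci[1], x$roc[[nm]]$auc_ci[2]))
  cat(sprintf("  Liu cutoff on FW: %.3f (sens %.2f, spec %.2f)\n",
              x$liu$cutoff, x$liu$sens, x$liu$spec))
  invisible(x)
}
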