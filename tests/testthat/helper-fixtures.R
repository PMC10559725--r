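## Shared fixtures, computed once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

## The study-condition cohort used by the acceptance tests: 8 subjects,
## 48^3 grid, 5 visits over one year, DWI at every visit, SNR 40.
acceptance_cohort <- function() {
  fixture("acceptance_report", {
    cfg <- cohort_config(seed = 424242)
    suppressWarnings(suppressMessages(
      run_pipeline(cfg, pipeline_options(n_boot = 25))))
  })
}

## A single lightweight subject (baseline DWI only) for pipeline-shaped
## unit tests.
small_subject <- function() {
  fixture("small_subject", {
    cfg <- cohort_config(n_subjects = 1, seed = 7)
    simulate_subject(cfg, 1, dwi = "baseline")
  })
}

small_config <- function() cohort_config(n_subjects = 1, seed = 7)

## Brute-force mm-distance dilation oracle: a voxel is in the dilated set
## iff its centre is within radius_mm of some mask-voxel centre.
brute_dilate <- function(mask, radius_mm, voxel_size) {
  d <- dim(mask)
  src <- which(mask, arr.ind = TRUE)
  out <- array(FALSE, d)
  all_idx <- which(array(TRUE, d), arr.ind = TRUE)
  for (r in seq_len(nrow(all_idx))) {
    p <- all_idx[r, ]
    dd <- sqrt(colSums(((t(src) - p) * voxel_size)^2))
    if (any(dd <= radius_mm)) out[p[1], p[2], p[3]] <- TRUE
  }
  out
}
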