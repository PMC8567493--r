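# Shared fixtures. Cohorts are cached per (n, seed, null) so expensive
# simulation work is shared across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached_cohort <- function(n_patients = 67, seed = 1, null = FALSE) {
  key <- paste(n_patients, seed, null, sep = "_")
  hit <- .fixture_cache[[key]]
  if (!is.null(hit)) return(hit)
  cfg <- if (null) null_generator_config(n_patients, seed)
  else generator_config(n_patients = n_patients, seed = seed)
  sim <- simulate_cohort(cfg)
  out <- list(cohort = sim$cohort, truth = sim$truth,
              thresholds = sim$thresholds,
              pixel_table1 = sim$pixel_tables[[1]])
  .fixture_cache[[key]] <- out
  out
}

# single Gaussian on a regular axis
gaussian_spectrum <- function(center, sigma, amplitude = 1,
                              wn = seq(800, 1800, by = 2)) {
  ftir_spectrum(wn, amplitude * exp(-(wn - center)^2 / (2 * sigma^2)))
}

# axis-aligned rectangular mask (rows x cols pixels) inside an H x W grid
rectangle_mask <- function(rows, cols, H = max(rows) + 10, W = max(cols) + 10) {
  m <- matrix(FALSE, H, W)
  m[rows, cols] <- TRUE
  m
}

# labels/predictions realizing exact precision and sensitivity from
# confusion counts
confusion_vectors <- function(tp, fp, fn, tn) {
  labels <- c(rep("pos", tp + fn), rep("neg", fp + tn))
  predicted <- c(rep("pos", tp), rep("neg", fn), rep("pos", fp), rep("neg", tn))
  list(predicted = predicted, labels = labels)
}
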