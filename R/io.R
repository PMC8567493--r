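# Formats and the pipeline driver.
#
# Spectral maps travel in a directory-based hierarchical array
# container mirroring the logical layout
#   /wavenumbers, /samples/<id>/absorbance, /samples/<id>/mask
# with raw little-endian doubles for arrays and a JSON metadata file per
# node carrying dims, pixel_size_um and schema_version. Round trips are
# bit-exact.

CONTAINER_SCHEMA_VERSION <- 1L

write_array_bin <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 8, endian = "little")
}

read_array_bin <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, what = "numeric", n = n, size = 8, endian = "little")
}

#' Write spectral maps to a hierarchical container
#'
#' @param maps Named list of `spectral_map` objects (names become sample
#'   ids) or a single map (id `"sample1"`).
#' @param path Container directory (created; must not already contain a
#'   container unless `overwrite`).
#' @param overwrite Replace an existing container.
#' @return `path`, invisibly.
#' @export
write_spectral_container <- function(maps, path, overwrite = FALSE) {
  if (inherits(maps, "spectral_map")) maps <- list(sample1 = maps)
  if (is.null(names(maps)) || any(!nzchar(names(maps))))
    stop("maps must be a named list")
  if (dir.exists(path)) {
    if (!overwrite) stop("container already exists: ", path)
    unlink(path, recursive = TRUE)
  }
  dir.create(file.path(path, "samples"), recursive = TRUE)
  wn <- maps[[1]]$wavenumbers
  for (m in maps)
    if (!identical(m$wavenumbers, wn))
      stop("all maps in one container must share the wavenumber axis")
  write_array_bin(wn, file.path(path, "wavenumbers.bin"))
  meta <- list(schema_version = CONTAINER_SCHEMA_VERSION,
               n_wavenumbers = length(wn),
               pixel_size_um = maps[[1]]$pixel_size,
               samples = names(maps))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (id in names(maps)) {
    m <- maps[[id]]
    d <- file.path(path, "samples", id)
    dir.create(d, recursive = TRUE)
    write_array_bin(m$absorbance, file.path(d, "absorbance.bin"))
    write_array_bin(as.numeric(m$mask), file.path(d, "mask.bin"))
    jsonlite::write_json(list(dims = dim(m$absorbance),
                              pixel_size_um = m$pixel_size),
                         file.path(d, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read spectral maps from a hierarchical container
#'
#' @param path Container directory written by
#'   [write_spectral_container()].
#' @param ids Sample ids to read (default: all).
#' @return Named list of `spectral_map` objects.
#' @export
read_spectral_container <- function(path, ids = NULL) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    stop("not a spectral container (missing meta.json): ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$schema_version) ||
      meta$schema_version != CONTAINER_SCHEMA_VERSION)
    stop("unsupported container schema version: ",
         if (is.null(meta$schema_version)) "<missing>" else meta$schema_version)
  wn_path <- file.path(path, "wavenumbers.bin")
  if (!file.exists(wn_path)) stop("container missing wavenumbers dataset")
  wn <- read_array_bin(wn_path, meta$n_wavenumbers)
  if (is.null(ids)) ids <- meta$samples
  out <- lapply(ids, function(id) {
    d <- file.path(path, "samples", id)
    smeta_path <- file.path(d, "meta.json")
    if (!file.exists(smeta_path)) stop("container missing sample: ", id)
    smeta <- jsonlite::read_json(smeta_path, simplifyVector = TRUE)
    dims <- as.integer(smeta$dims)
    if (length(dims) != 3L || dims[3] != length(wn))
      stop("sample '", id, "': absorbance dims ", paste(dims, collapse = "x"),
           " incompatible with wavenumber axis of length ", length(wn))
    ab <- array(read_array_bin(file.path(d, "absorbance.bin"), prod(dims)),
                dim = dims)
    mask_v <- read_array_bin(file.path(d, "mask.bin"), dims[1] * dims[2])
    spectral_map(wn, ab, matrix(mask_v != 0, dims[1], dims[2]),
                 pixel_size = smeta$pixel_size_um)
  })
  stats::setNames(out, ids)
}

#' Pipeline configuration
#'
#' Bundles the generator, band, threshold, booster and evaluation
#' settings of a full pipeline run. Unknown fields are rejected.
#'
#' @param generator A `generator_config`.
#' @param bands A band configuration.
#' @param threshold_mode `"computed"` (pool pixels across the cohort) or
#'   `"table_defaults"` (use [table1_thresholds()]).
#' @param booster A `booster_params`.
#' @param candidates Candidate duration cutpoints.
#' @param retention Coefficient retention threshold.
#' @param seed Pipeline seed.
#' @param n_repeats Down-sampling repeats per evaluation.
#' @param cv_folds Cross-validation folds.
#' @param mrmr_k mRMR selection size (NULL disables).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            bands = default_band_config(),
                            threshold_mode = c("computed", "table_defaults"),
                            booster = booster_params(),
                            candidates = 5:9, retention = 0.2, seed = 1L,
                            n_repeats = 20, cv_folds = 5, mrmr_k = 15) {
  threshold_mode <- match.arg(threshold_mode)
  structure(list(generator = generator, bands = bands,
                 threshold_mode = threshold_mode, booster = booster,
                 candidates = candidates, retention = retention,
                 seed = as.integer(seed), n_repeats = n_repeats,
                 cv_folds = cv_folds, mrmr_k = mrmr_k),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalars and nested sections override the defaults of
#' [pipeline_config()], [generator_config()] and [booster_params()];
#' unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$generator))
    args$generator <- do.call(generator_config, raw$generator)
  if (!is.null(raw$booster))
    args$booster <- do.call(booster_params, raw$booster)
  scalars <- c("threshold_mode", "candidates", "retention", "seed",
               "n_repeats", "cv_folds", "mrmr_k")
  unknown <- setdiff(names(raw), c("generator", "booster", scalars))
  if (length(unknown))
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  for (s in intersect(names(raw), scalars)) args[[s]] <- raw[[s]]
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)  # scratch only; hash of the serialized config
  unname(tools::md5sum(tmp))
}

write_grid_csv <- function(grid, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(grid, con, row.names = FALSE)
}

#' Run the full pipeline
#'
#' simulate -> extract -> features -> duration cutpoint sweep -> fracture
#' feature-set comparison -> importances, writing every table (CSV, with
#' the config hash in a comment line) and result object (JSON) under
#' `out_dir`, and logging seeds and the defaults in effect.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created).
#' @param log Connection or `""` for stderr-style message logging.
#' @return Invisibly, a list with the cohort, sweep, fracture grid and
#'   both importance tables.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, log = "") {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  say <- function(...) message("[ftirbone] ", ...)
  say("config hash ", hash, "; generator seed ", config$generator$seed,
      "; pipeline seed ", config$seed)

  say("stage simulate+extract: n = ", config$generator$n_patients,
      " patients, ~", config$generator$pixel_target, " pixels each")
  thr_arg <- if (config$threshold_mode == "computed") "computed"
  else table1_thresholds()
  sim <- simulate_cohort(config$generator, bands = config$bands,
                         thresholds = thr_arg)
  write_cohort_table(sim$cohort, file.path(out_dir, "cohort.csv"))
  jsonlite::write_json(
    list(config_hash = hash,
         thresholds = lapply(unclass(sim$thresholds), as.list)),
    file.path(out_dir, "thresholds.json"), auto_unbox = TRUE, digits = NA)

  say("stage duration sweep: candidates ",
      paste(config$candidates, collapse = ", "))
  sweep <- sweep_cutpoints(sim$cohort, candidates = config$candidates,
                           cv_folds = config$cv_folds,
                           n_repeats = config$n_repeats, seed = config$seed,
                           params = config$booster, mrmr_k = config$mrmr_k)
  write_grid_csv(sweep$grid, file.path(out_dir, "duration_sweep.csv"), hash)
  jsonlite::write_json(
    list(config_hash = hash, selected_cutpoint = sweep$selected,
         grid = sweep$grid),
    file.path(out_dir, "duration_sweep.json"), auto_unbox = TRUE, digits = NA)

  say("stage feature-set comparison at cutpoint ", sweep$selected)
  fs_grid <- compare_feature_sets(sim$cohort, sweep$selected,
                                  cv_folds = config$cv_folds,
                                  n_repeats = config$n_repeats,
                                  seed = config$seed, params = config$booster,
                                  mrmr_k = config$mrmr_k)
  write_grid_csv(fs_grid, file.path(out_dir, "duration_feature_sets.csv"), hash)

  say("stage fracture comparison")
  fr_grid <- compare_fracture_models(sim$cohort, cutpoint = sweep$selected,
                                     cv_folds = config$cv_folds,
                                     n_repeats = config$n_repeats,
                                     seed = config$seed,
                                     params = config$booster,
                                     mrmr_k = config$mrmr_k)
  write_grid_csv(fr_grid, file.path(out_dir, "fracture_models.csv"), hash)

  say("stage importances (retention ", config$retention, ")")
  dur_imp <- duration_importances(sim$cohort, sweep$selected,
                                  n_repeats = config$n_repeats,
                                  seed = config$seed, params = config$booster,
                                  mrmr_k = config$mrmr_k,
                                  retention = config$retention)
  fr_imp <- fracture_importances(sim$cohort, cutpoint = sweep$selected,
                                 n_repeats = config$n_repeats,
                                 seed = config$seed, params = config$booster,
                                 mrmr_k = config$mrmr_k,
                                 retention = config$retention)
  jsonlite::write_json(
    list(config_hash = hash, duration = as.data.frame(dur_imp),
         fracture = as.data.frame(fr_imp)),
    file.path(out_dir, "importances.json"), auto_unbox = TRUE, digits = NA)

  say("done; outputs in ", out_dir)
  invisible(list(cohort = sim$cohort, thresholds = sim$thresholds,
                 sweep = sweep, feature_sets = fs_grid,
                 fracture = fr_grid, duration_importances = dur_imp,
                 fracture_importances = fr_imp, config_hash = hash))
}
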