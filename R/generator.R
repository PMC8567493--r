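# Synthetic cohort generator.
#
# Generates patient tables, hyperspectral trabecular maps and fracture
# outcomes with planted, configurable effects: a right-skewed treatment
# duration distribution, piecewise-linear drift of the latent FTIR
# parameters with a slope change at a configurable change-point, reduced
# osteoclast number and activation frequency at long durations, and a
# logistic fracture mechanism driven by duration and mineral parameters
# (hip BMD deliberately absent from the default mechanism). Every draw
# is reproducible bit-for-bit from (config, seed).

# Idealized Gaussian band model used to synthesize pixel spectra:
# phosphate nu1nu3 components near 960/1020/1030/1075, carbonate nu2 near
# 872, amide I components near 1660/1690 cm^-1, on an 800-1800 cm^-1 axis
# at 2 cm^-1 spacing.
gaussian_band_model <- function() {
  list(
    wavenumbers = seq(800, 1800, by = 2),
    centers = c(p960 = 960, p1020 = 1020, p1030 = 1030, p1075 = 1075,
                c872 = 872, a1660 = 1660, a1690 = 1690),
    sigmas  = c(p960 = 13, p1020 = 4, p1030 = 4, p1075 = 12,
                c872 = 5.5, a1660 = 9, a1690 = 9),
    # fixed 960/1075 amplitudes relative to the 1020 height scale
    rel_960 = 0.6, rel_1075 = 0.5
  )
}

#' Synthetic cohort generator configuration
#'
#' Builds a validated configuration with the study defaults: 67 patients;
#' shifted-gamma treatment durations clipped to 1-14 years with median
#' close to 5; and two planted bone-quality patterns that both change at
#' the 8-year change-point. Remodeling and matrix parameters (cross-link
#' ratio up, N.Oc/B.Pm and Ac.f down) drift over the early treatment
#' years and plateau after the change-point; mineral parameters
#' (mineral-to-matrix, carbonate-to-phosphate, crystallinity) are stable
#' early, shift level at the change-point and keep drifting slowly
#' beyond it. About 325 scanned 6 x 6 um bone areas are generated per
#' patient, and fracture outcomes follow a logistic mechanism on
#' duration and the latent carbonate-to-phosphate and mineral-to-matrix
#' means (hip BMD carries no planted effect). All defaults are
#' overridable.
#'
#' @param ... Named overrides of the default fields (unknown names are an
#'   error). Fields: `n_patients`, `seed`; `duration_dist` (gamma shape,
#'   scale, min, max in years); `change_point_years`; `baselines`,
#'   `patient_sd` (latent FTIR means and their between-patient SDs);
#'   `pre_slopes`, `post_slopes` (per-parameter drift per year before /
#'   after the change-point) and `change_step` (level shift crossing
#'   it), all over the keys `mmr_mean`, `cpr_mean`,
#'   `crystallinity_mean`, `xlr_mean`, `xlr_sd`, `bmd_hip`, `n_oc_bpm`,
#'   `ac_f`; `pixel_target` (scanned 6 x 6 um areas per sample);
#'   `map_noise` (relative pixel-level SD of the planted ratios) and
#'   `map_noise_cv` (between-patient lognormal CV of that spread);
#'   `fracture_coeffs` (logistic weights on raw duration/cpr_mean/
#'   mmr_mean plus `intercept`); `covariate_ranges` and `histo_ranges`
#'   (truncated-normal mean/sd/min/max per covariate). Nested vectors
#'   and lists are replaced wholesale when supplied.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_patients = 67,
    seed = 1,
    duration_dist = list(shape = 2, scale = 2.4, min = 1, max = 14),
    change_point_years = 8,
    baselines = c(mmr = 4.3, cpr = 0.0085, crystallinity = 1.10, xlr = 3.3),
    patient_sd = c(mmr = 0.20, cpr = 3e-4, crystallinity = 0.012, xlr = 0.08),
    # Two planted patterns, both changing at the change-point: remodeling
    # and matrix parameters (xlr, N.Oc/B.Pm, Ac.f) ramp over the early
    # treatment years and plateau after it; mineral parameters (mmr, cpr,
    # crystallinity) are flat early, shift level at the change-point and
    # keep drifting slowly after it.
    pre_slopes = c(mmr_mean = 0, cpr_mean = 0,
                   crystallinity_mean = 0, xlr_mean = 0.03,
                   xlr_sd = 0, bmd_hip = 0, n_oc_bpm = -0.025, ac_f = -0.03),
    post_slopes = c(mmr_mean = 0.06, cpr_mean = 9e-5,
                    crystallinity_mean = 0.0036, xlr_mean = 0,
                    xlr_sd = 0.01, bmd_hip = 0, n_oc_bpm = 0, ac_f = 0),
    change_step = c(mmr_mean = 0.5, cpr_mean = 7.5e-4,
                    crystallinity_mean = 0.03, xlr_mean = 0,
                    xlr_sd = 0, bmd_hip = 0, n_oc_bpm = 0, ac_f = 0),
    pixel_target = 325,
    map_noise = 0.05,
    map_noise_cv = 0.25,
    # intercept calibrated (Monte Carlo over the default mechanism) so the
    # expected fracture proportion matches the 22-of-67 study rate
    fracture_coeffs = c(intercept = -7.56, duration = 0.55,
                        cpr_mean = 250, mmr_mean = 0.30),
    covariate_ranges = list(
      age       = c(mean = 60,    sd = 8,    min = 34,    max = 77),
      bmd_spine = c(mean = -2.48, sd = 0.97, min = -4.20, max = 0.70),
      bmd_hip   = c(mean = -1.90, sd = 0.88, min = -4.10, max = 1.00),
      bmi       = c(mean = 25.08, sd = 5.13, min = 15.96, max = 43.53)
    ),
    histo_ranges = list(
      bv_tv    = c(mean = 20,   sd = 5,    min = 8,    max = 35),
      tb_sp    = c(mean = 600,  sd = 150,  min = 300,  max = 1100),
      tb_th    = c(mean = 120,  sd = 25,   min = 70,   max = 180),
      ov_bv    = c(mean = 1.5,  sd = 1.0,  min = 0.1,  max = 5),
      os_bs    = c(mean = 10,   sd = 5,    min = 1,    max = 25),
      o_th     = c(mean = 8,    sd = 2,    min = 4,    max = 14),
      n_ob_bpm = c(mean = 1.5,  sd = 0.8,  min = 0.1,  max = 4),
      es_bs    = c(mean = 3,    sd = 1.5,  min = 0.5,  max = 8),
      n_oc_bpm = c(mean = 0.25, sd = 0.08, min = 0.02, max = 0.5),
      mar      = c(mean = 0.55, sd = 0.08, min = 0.3,  max = 0.8),
      ms_bs    = c(mean = 5,    sd = 2.5,  min = 0.5,  max = 12),
      ac_f     = c(mean = 0.30, sd = 0.10, min = 0.02, max = 0.6)
    )
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown generator_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  dd <- cfg$duration_dist
  if (cfg$n_patients <= 0) stop("n_patients must be positive")
  if (dd$min >= dd$max) stop("duration_dist: min must be < max")
  if (cfg$change_point_years <= dd$min || cfg$change_point_years >= dd$max)
    stop("change_point_years must lie within (duration min, duration max)")
  if (cfg$pixel_target <= 0) stop("pixel_target must be positive")
  if (cfg$map_noise < 0) stop("map_noise must be >= 0")
  if (cfg$map_noise_cv < 0) stop("map_noise_cv must be >= 0")
  if (any(cfg$patient_sd < 0)) stop("patient_sd entries must be >= 0")
  keys <- names(cfg$pre_slopes)
  if (!identical(names(cfg$post_slopes), keys) ||
      !identical(names(cfg$change_step), keys))
    stop("pre_slopes, post_slopes and change_step must share the same names")
  if (!"intercept" %in% names(cfg$fracture_coeffs))
    stop("fracture_coeffs must include an 'intercept' entry")
  for (nm in names(cfg$covariate_ranges)) {
    r <- cfg$covariate_ranges[[nm]]
    if (r[["min"]] >= r[["max"]])
      stop("covariate range '", nm, "': min must be < max")
    if (r[["sd"]] < 0) stop("covariate range '", nm, "': sd must be >= 0")
  }
  for (nm in names(cfg$histo_ranges)) {
    r <- cfg$histo_ranges[[nm]]
    if (r[["min"]] >= r[["max"]])
      stop("histomorphometry range '", nm, "': min must be < max")
  }
  invisible(TRUE)
}

#' Zero-effect generator configuration
#'
#' Convenience wrapper: all duration slopes and the change-point level
#' shifts are zero and the fracture mechanism is intercept-only (at the
#' same expected fracture rate), so cohorts carry no planted signal.
#' Used for null calibration of the models.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed.
#' @param ... Further overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
null_generator_config <- function(n_patients = 67, seed = 1, ...) {
  zero <- c(mmr_mean = 0, cpr_mean = 0, crystallinity_mean = 0,
            xlr_mean = 0, xlr_sd = 0, bmd_hip = 0, n_oc_bpm = 0, ac_f = 0)
  generator_config(n_patients = n_patients, seed = seed,
                   pre_slopes = zero, post_slopes = zero, change_step = zero,
                   fracture_coeffs = c(intercept = stats::qlogis(22 / 67),
                                       duration = 0, cpr_mean = 0,
                                       mmr_mean = 0),
                   ...)
}

# Piecewise-linear drift with an optional level shift at the
# change-point: slope `pre` before it, a step of `step` crossing it, and
# slope `post` after it. The step is what concentrates discriminability
# at the change-point itself; a continuous kink alone moves the optimal
# dichotomization cutpoint away from it.
duration_drift <- function(duration, pre, post, change_point, step = 0) {
  pre * pmin(duration, change_point) +
    step * (duration > change_point) +
    post * pmax(duration - change_point, 0)
}

# truncated-normal draws by inverse CDF (exact, no rejection loop)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  pmin(pmax(stats::qnorm(p, mean, sd), lo), hi)
}

# Elongated simply connected mask: a "stadium" (rectangle with rounded
# ends) rotated by `angle`, sized so its pixel area matches pixel_target.
stadium_mask <- function(pixel_target, angle, pixel_size = 6,
                         aspect = 4.2) {
  w <- sqrt(pixel_target * pixel_size^2 / (4 * aspect - 4 + pi))
  len <- 2 * aspect * w
  n <- ceiling((len + 4 * pixel_size) / pixel_size) + 1
  ctr <- (n - 1) / 2 * pixel_size
  u <- c(cos(angle), sin(angle))
  half <- len / 2 - w
  xs <- ((seq_len(n) - 1)) * pixel_size
  gx <- matrix(xs, n, n, byrow = TRUE) - ctr   # x varies over columns
  gy <- matrix(xs, n, n, byrow = FALSE) - ctr  # y varies over rows
  t <- pmin(pmax(gx * u[1] + gy * u[2], -half), half)
  d2 <- (gx - t * u[1])^2 + (gy - t * u[2])^2
  d2 <= w^2
}

#' Generate one synthetic spectral map
#'
#' Synthesizes a trabecular map whose per-pixel spectra are sums of
#' Gaussian bands with amplitudes solved analytically so that the
#' band-ratio extraction of [extract_pixel_table()] recovers the planted
#' pixel ratios. Pixel ratios vary around the patient's latent means with
#' relative SD `pixel_rel_sd` (0 gives an exact round trip up to band
#' overlap, within 2 percent). The mask is an elongated stadium rotated
#' by a seeded random angle; its pixel count is within about 15 percent
#' of `config$pixel_target`.
#'
#' @param latent_means Named positive numeric: `mmr`, `cpr`,
#'   `crystallinity`, `xlr`.
#' @param config A `generator_config`.
#' @param seed Integer seed for the map (angle + pixel noise).
#' @param pixel_rel_sd Relative SD of per-pixel ratio variation; defaults
#'   to `config$map_noise` for all four parameters. May be a single
#'   number or a named vector over the four parameters.
#' @return A `spectral_map` with attribute `planted`: a data.frame of the
#'   planted per-pixel ratios (0-based `row`, `col`).
#' @export
generate_spectral_map <- function(latent_means, config, seed,
                                  pixel_rel_sd = NULL) {
  need <- c("mmr", "cpr", "crystallinity", "xlr")
  if (!all(need %in% names(latent_means)))
    stop("latent_means must name ", paste(need, collapse = ", "))
  latent_means <- latent_means[need]
  if (any(latent_means <= 0)) stop("latent means must be positive")
  if (is.null(pixel_rel_sd)) pixel_rel_sd <- config$map_noise
  if (length(pixel_rel_sd) == 1L)
    pixel_rel_sd <- stats::setNames(rep(pixel_rel_sd, 4), need)

  bm <- gaussian_band_model()
  wn <- bm$wavenumbers
  if (min(wn) > min(bm$centers) - 3 * max(bm$sigmas) ||
      max(wn) < max(bm$centers) + 3 * max(bm$sigmas))
    stop("wavenumber axis does not cover all synthesis bands")

  set.seed(seed)
  angle <- stats::runif(1, 0, pi)
  mask <- stadium_mask(config$pixel_target, angle)
  idx <- which(mask, arr.ind = TRUE)
  npx <- nrow(idx)

  ratios <- sapply(need, function(p) {
    v <- latent_means[[p]] *
      pmax(1 + stats::rnorm(npx, 0, pixel_rel_sd[[p]]), 0.2)
    v
  })
  colnames(ratios) <- need

  amps <- solve_band_amplitudes(ratios, bm)
  B <- vapply(names(bm$centers), function(b)
    exp(-(wn - bm$centers[[b]])^2 / (2 * bm$sigmas[[b]]^2)),
    numeric(length(wn)))
  S <- B %*% t(amps)  # n_wn x npx

  H <- nrow(mask); W <- ncol(mask)
  arr <- array(0, dim = c(H, W, length(wn)))
  flat_idx <- idx[, 1] + H * (idx[, 2] - 1)
  arr[outer(flat_idx, (seq_along(wn) - 1L) * H * W, "+")] <- t(S)

  map <- spectral_map(wn, arr, mask, pixel_size = 6)
  attr(map, "planted") <- data.frame(row = idx[, 1] - 1, col = idx[, 2] - 1,
                                     ratios)
  attr(map, "angle") <- angle
  map
}

# Solve per-pixel Gaussian amplitudes (one row per pixel, columns in
# gaussian_band_model() order) so the analytic band areas and peak
# heights reproduce the planted ratios. The matrix (amide I) area is
# normalized to 1 in arbitrary units; the mineral area is then mmr, the
# carbonate area cpr * mmr. The 1020/1030 and 1660/1690 height pairs are
# obtained from 2 x 2 solves that account for mutual Gaussian overlap.
solve_band_amplitudes <- function(ratios, bm = gaussian_band_model()) {
  s <- bm$sigmas
  g_p <- exp(-(bm$centers[["p1030"]] - bm$centers[["p1020"]])^2 /
               (2 * s[["p1020"]]^2))
  g_a <- exp(-(bm$centers[["a1660"]] - bm$centers[["a1690"]])^2 /
               (2 * s[["a1660"]]^2))
  cry <- ratios[, "crystallinity"]; xlr <- ratios[, "xlr"]
  mmr <- ratios[, "mmr"]; cpr <- ratios[, "cpr"]

  # amide I: heights (xlr, 1) up to scale, then scale to unit area
  a1660 <- (xlr - g_a) / (1 - g_a^2)
  a1690 <- (1 - g_a * xlr) / (1 - g_a^2)
  if (any(a1660 <= 0) || any(a1690 <= 0))
    stop("cross-link ratio outside the representable range of the band model")
  sc_a <- 1 / (sqrt(2 * pi) * s[["a1660"]] * (a1660 + a1690))

  # phosphate: heights (1, crystallinity) at 1020/1030 + fixed satellites
  a1020 <- (1 - g_p * cry) / (1 - g_p^2)
  a1030 <- (cry - g_p) / (1 - g_p^2)
  if (any(a1020 <= 0) || any(a1030 <= 0))
    stop("crystallinity outside the representable range of the band model")
  area_rel <- sqrt(2 * pi) * (s[["p960"]] * bm$rel_960 +
                                s[["p1020"]] * a1020 + s[["p1030"]] * a1030 +
                                s[["p1075"]] * bm$rel_1075)
  sc_p <- mmr / area_rel
  c872 <- cpr * mmr / (sqrt(2 * pi) * s[["c872"]])

  cbind(p960 = bm$rel_960 * sc_p, p1020 = a1020 * sc_p,
        p1030 = a1030 * sc_p, p1075 = bm$rel_1075 * sc_p,
        c872 = c872, a1660 = a1660 * sc_a, a1690 = a1690 * sc_a)
}

#' Generate a synthetic patient cohort
#'
#' Draws treatment durations from a shifted gamma clipped to the
#' configured range, latent FTIR parameter means following a
#' piecewise-linear drift with a slope change at the change-point,
#' patient covariates and histomorphometric parameters from truncated
#' normals matched to the configured ranges (hip BMD t-scores always
#' within their configured bounds), and fracture outcomes from the
#' logistic mechanism. Output is identical for identical (config, seed).
#'
#' @param config A `generator_config`.
#' @return List with `patients` (one row per patient: covariates,
#'   histomorphometry, duration, fracture flag) and `truth` (planted
#'   latent means, per-parameter pixel-level relative SDs, per-patient
#'   map seeds, fracture linear predictor, change-point).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  n <- config$n_patients
  dd <- config$duration_dist
  cp <- config$change_point_years
  set.seed(config$seed)

  duration <- pmin(dd$min + stats::rgamma(n, shape = dd$shape,
                                          scale = dd$scale), dd$max)
  drift <- function(key) duration_drift(duration, config$pre_slopes[[key]],
                                        config$post_slopes[[key]], cp,
                                        config$change_step[[key]])
  latent <- data.frame(
    mmr = pmax(config$baselines[["mmr"]] + drift("mmr_mean") +
                 stats::rnorm(n, 0, config$patient_sd[["mmr"]]), 0.5),
    cpr = pmax(config$baselines[["cpr"]] + drift("cpr_mean") +
                 stats::rnorm(n, 0, config$patient_sd[["cpr"]]), 1e-4),
    crystallinity = pmax(config$baselines[["crystallinity"]] +
                           drift("crystallinity_mean") +
                           stats::rnorm(n, 0, config$patient_sd[["crystallinity"]]),
                         0.8),
    xlr = pmax(config$baselines[["xlr"]] + drift("xlr_mean") +
                 stats::rnorm(n, 0, config$patient_sd[["xlr"]]), 0.5)
  )
  # Per-parameter pixel-level relative SD: the xlr spread can drift with
  # duration, and every parameter's spread carries between-patient
  # lognormal heterogeneity (CV map_noise_cv), as within-sample spread
  # varies between biopsies.
  jitter <- function() exp(stats::rnorm(n, 0, config$map_noise_cv))
  pixel_sd <- data.frame(
    mmr = config$map_noise * jitter(),
    cpr = config$map_noise * jitter(),
    crystallinity = config$map_noise * jitter(),
    xlr = pmax(config$map_noise + drift("xlr_sd"), 0.005) * jitter()
  )

  cr <- config$covariate_ranges
  cov_draw <- function(nm) {
    r <- cr[[nm]]
    rtrunc_norm(n, r[["mean"]], r[["sd"]], r[["min"]], r[["max"]])
  }
  age <- cov_draw("age")
  bmd_spine <- cov_draw("bmd_spine")
  bmd_hip <- pmin(pmax(cov_draw("bmd_hip") + drift("bmd_hip"),
                       cr$bmd_hip[["min"]]), cr$bmd_hip[["max"]])
  bmi <- cov_draw("bmi")

  histo <- lapply(names(config$histo_ranges), function(nm) {
    r <- config$histo_ranges[[nm]]
    v <- rtrunc_norm(n, r[["mean"]], r[["sd"]], r[["min"]], r[["max"]])
    if (nm %in% c("n_oc_bpm", "ac_f"))
      v <- pmin(pmax(v + drift(nm), r[["min"]]), r[["max"]])
    v
  })
  names(histo) <- names(config$histo_ranges)
  histo <- as.data.frame(histo)
  # derived extras, excluded from the default modeling set
  histo$bfr_bs <- histo$mar * histo$ms_bs / 100 * 365
  histo$mlt <- histo$o_th / (histo$mar * histo$ms_bs / 100)

  map_seed <- sample.int(.Machine$integer.max - 1L, n)
  outcome_seed <- sample.int(.Machine$integer.max - 1L, 1L)

  mech <- data.frame(duration = duration, cpr_mean = latent$cpr,
                     mmr_mean = latent$mmr)
  fracture <- generate_fracture_outcomes(mech, config$fracture_coeffs,
                                         outcome_seed)

  patient_id <- sprintf("P%03d", seq_len(n))
  patients <- data.frame(patient_id = patient_id, age = age, bmi = bmi,
                         bmd_spine = bmd_spine, bmd_hip = bmd_hip,
                         duration = duration, histo,
                         fracture = as.integer(fracture))
  truth <- list(
    latent = data.frame(patient_id = patient_id, duration = duration,
                        latent, map_seed = map_seed),
    pixel_sd = cbind(patient_id = patient_id, pixel_sd),
    change_point_years = cp,
    fracture_lp = attr(fracture, "linear_predictor"),
    outcome_seed = outcome_seed,
    config = config
  )
  list(patients = patients, truth = truth)
}

#' Draw fracture outcomes from the logistic mechanism
#'
#' The linear predictor is `intercept + sum(coef * column)` over the
#' non-intercept names of `coeffs`; fracture flags are Bernoulli draws
#' from its logistic transform, reproducible under `seed`.
#'
#' @param patients Data.frame containing every covariate named in
#'   `coeffs` (besides `intercept`).
#' @param coeffs Named numeric vector with an `intercept` entry.
#' @param seed Integer seed.
#' @return Integer 0/1 vector with attribute `linear_predictor`.
#' @export
generate_fracture_outcomes <- function(patients, coeffs, seed) {
  if (!"intercept" %in% names(coeffs))
    stop("fracture coefficients must include 'intercept'")
  vars <- setdiff(names(coeffs), "intercept")
  missing <- setdiff(vars, names(patients))
  if (length(missing))
    stop("missing covariate(s) for the fracture mechanism: ",
         paste(missing, collapse = ", "))
  lp <- rep(coeffs[["intercept"]], nrow(patients))
  for (v in vars) lp <- lp + coeffs[[v]] * patients[[v]]
  set.seed(seed)
  flags <- as.integer(stats::runif(nrow(patients)) < stats::plogis(lp))
  attr(flags, "linear_predictor") <- lp
  flags
}

#' Simulate a full cohort with extracted features
#'
#' Convenience driver: generates the cohort, synthesizes one spectral map
#' per patient, extracts the pixel tables, computes cohort-pooled (or
#' fixed) category thresholds, assembles the 44 infrared features per
#' patient and binds them to the patient table.
#'
#' @param config A `generator_config`.
#' @param bands Band configuration for extraction.
#' @param thresholds `"computed"` (pool pixels across the cohort) or a
#'   thresholds object such as [table1_thresholds()].
#' @param keep_maps Keep the spectral maps in the result (memory-heavy).
#' @return List with `cohort` (features + covariates table), `patients`,
#'   `truth`, `thresholds`, `pixel_tables`, and optionally `maps`.
#' @export
simulate_cohort <- function(config = generator_config(),
                            bands = default_band_config(),
                            thresholds = "computed",
                            keep_maps = FALSE) {
  gen <- generate_cohort(config)
  n <- nrow(gen$patients)
  pixel_tables <- vector("list", n)
  maps <- if (keep_maps) vector("list", n) else NULL
  for (i in seq_len(n)) {
    lm_i <- unlist(gen$truth$latent[i, c("mmr", "cpr", "crystallinity", "xlr")])
    sd_i <- unlist(gen$truth$pixel_sd[i, c("mmr", "cpr", "crystallinity", "xlr")])
    map <- generate_spectral_map(lm_i, config,
                                 seed = gen$truth$latent$map_seed[i],
                                 pixel_rel_sd = sd_i)
    pixel_tables[[i]] <- extract_pixel_table(map, bands)
    if (keep_maps) maps[[i]] <- map
  }
  names(pixel_tables) <- gen$patients$patient_id
  thr <- if (identical(thresholds, "computed"))
    cohort_thresholds(pixel_tables) else thresholds
  feats <- lapply(pixel_tables, assemble_ir_features, thresholds = thr)
  cohort <- build_cohort_table(feats, gen$patients)
  out <- list(cohort = cohort, patients = gen$patients, truth = gen$truth,
              thresholds = thr, pixel_tables = pixel_tables)
  if (keep_maps) out$maps <- stats::setNames(maps, gen$patients$patient_id)
  out
}
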