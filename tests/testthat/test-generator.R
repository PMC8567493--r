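# Synthetic cohort generator: configuration validation, planted
# structure, covariate envelopes, determinism, fracture mechanism.

test_that("generator configuration is validated", {
  expect_error(generator_config(n_patients = 0), "positive")
  expect_error(generator_config(duration_dist = list(shape = 2, scale = 2,
                                                     min = 5, max = 5)),
               "min must be <")
  expect_error(generator_config(change_point_years = 20), "change_point")
  expect_error(generator_config(pixel_target = -1), "pixel_target")
  expect_error(generator_config(map_noise = -0.1), "map_noise")
  expect_error(generator_config(nonsense_field = 1), "unknown")
  expect_error(generator_config(fracture_coeffs = c(duration = 1)),
               "intercept")
})

test_that("zero slopes, steps and noise give identical latent means", {
  zero <- c(mmr_mean = 0, cpr_mean = 0, crystallinity_mean = 0, xlr_mean = 0,
            xlr_sd = 0, bmd_hip = 0, n_oc_bpm = 0, ac_f = 0)
  cfg <- generator_config(n_patients = 30, seed = 5, pre_slopes = zero,
                          post_slopes = zero, change_step = zero,
                          patient_sd = c(mmr = 0, cpr = 0,
                                         crystallinity = 0, xlr = 0))
  lat <- generate_cohort(cfg)$truth$latent
  for (p in c("mmr", "cpr", "crystallinity", "xlr"))
    expect_equal(diff(range(lat[[p]])), 0)
})

test_that("covariates honour the configured envelopes", {
  pts <- cached_cohort(67, 1)$cohort
  expect_equal(nrow(pts), 67)
  expect_true(all(pts$bmd_hip >= -4.10 & pts$bmd_hip <= 1.00))
  expect_true(all(pts$bmd_spine >= -4.20 & pts$bmd_spine <= 0.70))
  expect_true(all(pts$duration >= 1 & pts$duration <= 14))
  expect_true(all(pts$age >= 34 & pts$age <= 77))
  expect_true(all(pts$bmi >= 15.96 & pts$bmi <= 43.53))
  expect_true(all(pts$n_oc_bpm >= 0.02 & pts$n_oc_bpm <= 0.5))
})

test_that("a positive post-change cpr slope raises long-duration means", {
  # Monte-Carlo sign check at n = 500 over 20 seeds: forced by construction
  zero <- c(mmr_mean = 0, cpr_mean = 0, crystallinity_mean = 0, xlr_mean = 0,
            xlr_sd = 0, bmd_hip = 0, n_oc_bpm = 0, ac_f = 0)
  post <- zero; post[["cpr_mean"]] <- 5e-4
  ok <- vapply(1:20, function(s) {
    tr <- generate_cohort(generator_config(n_patients = 500, seed = s,
                                           pre_slopes = zero,
                                           post_slopes = post,
                                           change_step = zero))$truth$latent
    mean(tr$cpr[tr$duration > 8]) > mean(tr$cpr[tr$duration <= 8])
  }, logical(1))
  expect_true(all(ok))
})

test_that("cohorts, maps and outcomes are bit-reproducible under seed", {
  cfg <- generator_config(n_patients = 12, seed = 123)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1, g2)

  lm0 <- c(mmr = 4.4, cpr = 0.009, crystallinity = 1.12, xlr = 3.4)
  m1 <- generate_spectral_map(lm0, cfg, seed = 77)
  m2 <- generate_spectral_map(lm0, cfg, seed = 77)
  expect_identical(m1$absorbance, m2$absorbance)
  expect_identical(m1$mask, m2$mask)
})

test_that("planted cross-link symmetry: xlr = 1 gives equal amide heights", {
  cfg <- generator_config()
  map <- generate_spectral_map(c(mmr = 4.4, cpr = 0.009,
                                 crystallinity = 1.12, xlr = 1),
                               cfg, seed = 9, pixel_rel_sd = 0)
  tb <- extract_pixel_table(map)
  expect_equal(mean(tb$xlr), 1, tolerance = 0.02)
})

test_that("spectral map inputs are validated", {
  cfg <- generator_config()
  expect_error(generate_spectral_map(c(mmr = -1, cpr = 0.009,
                                       crystallinity = 1.1, xlr = 3),
                                     cfg, seed = 1), "positive")
  expect_error(generate_spectral_map(c(mmr = 4, cpr = 0.01), cfg, seed = 1),
               "must name")
})

test_that("fracture mechanism matches its logistic form", {
  tab <- data.frame(duration = runif(10000, 1, 14),
                    cpr_mean = 0.009, mmr_mean = 4.4)
  # all-zero coefficients: rate converges to logistic(0) = 0.5
  f0 <- generate_fracture_outcomes(tab, c(intercept = 0, duration = 0,
                                          cpr_mean = 0, mmr_mean = 0),
                                   seed = 4)
  expect_equal(mean(f0), 0.5, tolerance = 0.02)

  # strongly negative intercept: no fractures
  fneg <- generate_fracture_outcomes(tab, c(intercept = -50), seed = 4)
  expect_equal(sum(fneg), 0)

  # dominant duration effect: fractured patients have longer durations
  ok <- vapply(1:20, function(s) {
    tt <- data.frame(duration = runif(500, 1, 14))
    fl <- generate_fracture_outcomes(tt, c(intercept = -7.5, duration = 1),
                                     seed = s)
    mean(tt$duration[fl == 1]) > mean(tt$duration[fl == 0])
  }, logical(1))
  expect_true(all(ok))

  expect_error(generate_fracture_outcomes(tab[, 1, drop = FALSE],
                                          c(intercept = 0, cpr_mean = 1),
                                          seed = 1),
               "cpr_mean")
})

test_that("fracture rate tracks the calibrated study proportion", {
  rates <- vapply(1:6, function(s)
    mean(generate_cohort(generator_config(n_patients = 500,
                                          seed = s))$patients$fracture),
    numeric(1))
  expect_equal(mean(rates), 22 / 67, tolerance = 0.05)
})
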