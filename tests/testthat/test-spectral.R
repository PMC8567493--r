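# Band integration, peak heights and per-pixel ratio computation.

test_that("spectrum construction validates its axis", {
  expect_error(ftir_spectrum(c(1000), 1), "at least 2")
  expect_error(ftir_spectrum(c(1000, 999), c(1, 2)), "strictly increasing")
  expect_error(ftir_spectrum(c(-5, 10), c(1, 2)), "negative")
  expect_error(ftir_spectrum(c(1, 2, 3), c(1, 2)), "length")
})

test_that("integrate_band matches analytic areas", {
  wn <- seq(800, 1800, by = 1)
  zero <- ftir_spectrum(wn, rep(0, length(wn)))
  expect_equal(integrate_band(zero, c(900, 1200)), 0)

  # unit top-hat exactly spanning a 50 cm^-1 band, sampled at 1 cm^-1
  hat <- ftir_spectrum(wn, as.numeric(wn >= 1000 & wn <= 1050))
  expect_equal(integrate_band(hat, c(1000, 1050)), 50, tolerance = 1 / 50)

  # Gaussian, A = 1, sigma = 5, centred in a wide band
  g <- gaussian_spectrum(1100, 5, wn = wn)
  expect_equal(integrate_band(g, c(1000, 1200)), 5 * sqrt(2 * pi),
               tolerance = 0.01)

  # linear in absorbance scaling
  g3 <- ftir_spectrum(wn, 3 * g$absorbance)
  expect_equal(integrate_band(g3, c(1000, 1200)),
               3 * integrate_band(g, c(1000, 1200)))

  expect_error(integrate_band(g, c(700, 900)), "outside")
  expect_error(integrate_band(g, c(1200, 1000)), "lo must be <")
})

test_that("peak_height takes the window maximum", {
  wn <- seq(800, 1800, by = 2)
  const <- ftir_spectrum(wn, rep(0.7, length(wn)))
  expect_equal(peak_height(const, 1030, 4), 0.7)

  tri <- ftir_spectrum(wn, pmax(0, 1 - abs(wn - 1030) / 20))
  expect_equal(peak_height(tri, 1030, 6), 1)

  # two-Gaussian fixture, window isolating one component, against a
  # brute-force maximum on a 10x oversampled axis
  ab2 <- function(x) 0.8 * exp(-(x - 1020)^2 / 32) + 1.1 * exp(-(x - 1060)^2 / 50)
  sp <- ftir_spectrum(wn, ab2(wn))
  fine <- seq(1014, 1026, by = 0.2)
  expect_equal(peak_height(sp, 1020, 6), max(ab2(fine)), tolerance = 0.005)

  expect_error(peak_height(sp, 1020, -1), "half_window")
})

test_that("pixel parameters are ratios of configured bands", {
  cfg <- generator_config()
  planted <- c(mmr = 4.4, cpr = 0.009, crystallinity = 1.12, xlr = 3.4)
  map <- generate_spectral_map(planted, cfg, seed = 11, pixel_rel_sd = 0)
  i <- which(map$mask, arr.ind = TRUE)[1, ]
  sp <- ftir_spectrum(map$wavenumbers, map$absorbance[i[1], i[2], ])
  pp <- compute_pixel_params(sp)
  for (p in names(planted))
    expect_equal(pp[[p]], unname(planted[p]), tolerance = 0.02)
  expect_true(pp$valid)
  expect_equal(pp$area_um2, 36)

  # scale invariance
  pp10 <- compute_pixel_params(ftir_spectrum(sp$wavenumbers, 10 * sp$absorbance))
  expect_equal(pp10[1:4], pp[1:4])

  # zero mineral band: mmr 0 by convention, cpr flagged invalid
  amide_only <- ftir_spectrum(sp$wavenumbers,
                         exp(-(sp$wavenumbers - 1660)^2 / 162) +
                           0.5 * exp(-(sp$wavenumbers - 1690)^2 / 162))
  pz <- compute_pixel_params(amide_only)
  expect_equal(pz$mmr, 0)
  expect_true(is.na(pz$cpr))
  expect_false(pz$valid)
})

test_that("vectorized map extraction agrees with the per-spectrum path", {
  cfg <- generator_config()
  map <- generate_spectral_map(c(mmr = 4.1, cpr = 0.0095,
                                 crystallinity = 1.15, xlr = 3.1),
                               cfg, seed = 21, pixel_rel_sd = 0.05)
  tb <- extract_pixel_table(map)
  pick <- tb[c(1, nrow(tb) %/% 2, nrow(tb)), ]
  for (k in seq_len(nrow(pick))) {
    sp <- ftir_spectrum(map$wavenumbers,
                   map$absorbance[pick$row[k] + 1, pick$col[k] + 1, ])
    ref <- compute_pixel_params(sp)
    for (p in c("mmr", "cpr", "crystallinity", "xlr"))
      expect_equal(pick[[p]][k], ref[[p]], tolerance = 1e-10)
  }
})
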