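# Categorization thresholds, area-normalized category statistics and
# the 44-feature assembly.

test_that("threshold rule matches the hand-computed oracle", {
  thr <- compute_category_thresholds(c(1, 2, 3, 4))
  expect_equal(thr[["low"]], 1.5 - sd(c(1, 2)), tolerance = 1e-6)
  expect_equal(thr[["high"]], 3.5 + sd(c(3, 4)), tolerance = 1e-6)
  expect_equal(unname(thr), c(0.7928932, 4.2071068), tolerance = 1e-6)

  cc <- compute_category_thresholds(rep(2.5, 8))
  expect_equal(cc[["low"]], 2.5)
  expect_equal(cc[["high"]], 2.5)

  expect_error(compute_category_thresholds(c(1, 2, 3)), "at least 4")
})

test_that("adding values below the low threshold never raises it", {
  set.seed(42)
  for (i in 1:20) {
    v <- rnorm(30, 10, 2)
    thr <- compute_category_thresholds(v)
    v2 <- c(v, runif(5, thr[["low"]] - 5, thr[["low"]] - 0.01))
    thr2 <- compute_category_thresholds(v2)
    expect_lte(thr2[["low"]], thr[["low"]])
  }
})

test_that("reference thresholds carry the fixed cut values", {
  thr <- table1_thresholds()
  expect_equal(unname(thr$mmr), c(3.580, 5.230))
  expect_equal(unname(thr$cpr), c(0.008, 0.010))
  expect_equal(unname(thr$crystallinity), c(1.072, 1.164))
  expect_equal(unname(thr$xlr), c(3.065, 3.769))
})

test_that("categorization uses strict inequalities, boundaries medium", {
  thr <- table1_thresholds()$mmr
  expect_equal(as.character(categorize(3.580, thr)), "med")
  expect_equal(as.character(categorize(3.579, thr)), "low")
  expect_equal(as.character(categorize(5.230, thr)), "med")
  expect_equal(as.character(categorize(5.231, thr)), "high")
})

test_that("category statistics equal a brute-force enumeration", {
  # 10-pixel fixture with known 3 low / 5 medium / 2 high mmr split
  tb <- data.frame(mmr = c(1, 1.5, 2, 4, 4.2, 4.4, 4.6, 4.8, 6.5, 7),
                   cpr = 0.009, crystallinity = 1.1, xlr = 3.4, valid = TRUE)
  thr <- structure(list(mmr = c(low = 3, high = 6),
                        cpr = c(low = 0, high = 1),
                        crystallinity = c(low = 0, high = 2),
                        xlr = c(low = 0, high = 4)),
                   class = "category_thresholds")
  st <- category_area_stats(tb, thr)
  m <- st[st$parameter == "mmr", ]
  expect_equal(m$n_pixels, c(3, 5, 2))
  expect_equal(m$area_um2, c(3, 5, 2) * 36)
  expect_equal(m$area_fraction, c(0.3, 0.5, 0.2))
  low <- tb$mmr[tb$mmr < 3]; med <- tb$mmr[tb$mmr >= 3 & tb$mmr <= 6]
  high <- tb$mmr[tb$mmr > 6]
  expect_equal(m$norm_mean, c(mean(low) * 0.3, mean(med) * 0.5,
                              mean(high) * 0.2), tolerance = 1e-9)
  expect_equal(m$norm_sd, c(sd(low) * 0.3, sd(med) * 0.5, sd(high) * 0.2),
               tolerance = 1e-9)
  # conservation per parameter
  for (p in c("mmr", "cpr", "crystallinity", "xlr")) {
    expect_equal(sum(st$area_fraction[st$parameter == p]), 1, tolerance = 1e-9)
    expect_equal(sum(st$area_um2[st$parameter == p]),
                 attr(st, "total_bone_area_um2"))
  }
  # an all-medium parameter has its plain mean as normalized mean
  cpr_row <- st[st$parameter == "cpr" & st$category == "med", ]
  expect_equal(cpr_row$area_fraction, 1)
  expect_equal(cpr_row$norm_mean, mean(tb$cpr))

  expect_error(category_area_stats(tb[0, ], thr), "no valid pixels")
})

test_that("44 features assemble in canonical order and match direct stats", {
  fx <- cached_cohort(67, 1)
  feats <- assemble_ir_features(fx$pixel_table1, fx$thresholds)
  expect_length(feats, 44)
  expect_identical(names(feats), ir_feature_names())
  expect_length(ir_feature_names(), 44)
  expect_length(histo_feature_names(), 12)

  tb <- fx$pixel_table1[fx$pixel_table1$valid, ]
  expect_equal(unname(feats["mmr_mean"]), mean(tb$mmr), tolerance = 1e-9)
  expect_equal(unname(feats["xlr_sd"]), sd(tb$xlr), tolerance = 1e-9)

  # permutation invariance
  perm <- fx$pixel_table1[sample(nrow(fx$pixel_table1)), ]
  expect_equal(assemble_ir_features(perm, fx$thresholds), feats)
})

test_that("uniform pixel tables have zero overall-SD features", {
  tb <- data.frame(mmr = rep(4.4, 20), cpr = 0.009, crystallinity = 1.1,
                   xlr = 3.4, valid = TRUE)
  feats <- assemble_ir_features(tb, table1_thresholds())
  expect_equal(unname(feats[c("mmr_sd", "cpr_sd", "crystallinity_sd",
                              "xlr_sd")]), rep(0, 4))
})

test_that("cohort table assembly validates keys and round-trips as CSV", {
  fx <- cached_cohort(67, 1)
  expect_equal(nrow(fx$cohort), 67)
  expect_true(all(ir_feature_names() %in% names(fx$cohort)))
  expect_false(anyNA(fx$cohort))

  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_cohort_table(fx$cohort, p1)
  back <- read_cohort_table(p1)
  write_cohort_table(back, p2)
  expect_identical(readLines(p1), readLines(p2))

  pts <- data.frame(patient_id = c("P001", "P002"), duration = c(2, 9))
  feats <- list(P001 = assemble_ir_features(
    data.frame(mmr = c(4, 4.4), cpr = 0.009, crystallinity = 1.1,
               xlr = 3.4, valid = TRUE), table1_thresholds()))
  expect_error(build_cohort_table(feats, pts), "P002")
  pts_dup <- data.frame(patient_id = c("P001", "P001"), duration = 1:2)
  expect_error(build_cohort_table(feats, pts_dup), "duplicate")
})
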