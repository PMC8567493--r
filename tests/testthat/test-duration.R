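# Duration dichotomization, cutpoint sweep and feature-set comparison.

test_that("dichotomization boundary rule: duration <= cutpoint is first", {
  expect_equal(as.character(dichotomize_duration(5, 8)), "first_period")
  expect_equal(as.character(dichotomize_duration(14, 8)), "second_period")
  expect_equal(as.character(dichotomize_duration(8, 8)), "first_period")
  expect_equal(as.character(dichotomize_duration(8.5, 8)), "second_period")
  expect_equal(as.character(dichotomize_duration(8.5, 9)), "first_period")
  expect_error(dichotomize_duration(0.5, 8), "below 1 year")
})

test_that("single-candidate sweeps select that candidate", {
  fx <- cached_cohort(67, 1)
  sw <- sweep_cutpoints(fx$cohort, candidates = 8, n_repeats = 2, seed = 1)
  expect_equal(sw$selected, 8)
  expect_equal(nrow(sw$grid), 1)
})

test_that("the sweep grid covers candidates and selects the max AUC", {
  fx <- cached_cohort(67, 1)
  sw <- sweep_cutpoints(fx$cohort, candidates = 6:8, n_repeats = 3, seed = 2)
  expect_equal(sw$grid$cutpoint, 6:8)
  expect_equal(sw$selected, sw$grid$cutpoint[which.max(sw$grid$auc)])
  expect_true(all(sw$grid$auc >= 0 & sw$grid$auc <= 1))
})

test_that("cutpoint selection is invariant to patient row order", {
  fx <- cached_cohort(67, 1)
  sw1 <- sweep_cutpoints(fx$cohort, candidates = 7:8, n_repeats = 3, seed = 4)
  set.seed(1)
  perm <- fx$cohort[sample(nrow(fx$cohort)), ]
  sw2 <- sweep_cutpoints(perm, candidates = 7:8, n_repeats = 3, seed = 4)
  expect_equal(sw1$selected, sw2$selected)
})

test_that("infeasible candidates are skipped with a warning", {
  fx <- cached_cohort(67, 1)
  small <- fx$cohort[fx$cohort$duration <= 10, ]
  expect_warning(sw <- sweep_cutpoints(small, candidates = c(8, 9),
                                       n_repeats = 2, seed = 1),
                 "skipped")
  expect_false(9 %in% sw$grid$cutpoint)
  expect_error(suppressWarnings(
    sweep_cutpoints(fx$cohort[fx$cohort$duration <= 5, ],
                    candidates = 9, n_repeats = 2, seed = 1)),
    "no candidate")
})

test_that("feature-set comparison validates names and deduplicates", {
  fx <- cached_cohort(67, 1)
  expect_error(compare_feature_sets(fx$cohort, 8, sets = "bogus"),
               "valid sets")
  expect_warning(grid <- compare_feature_sets(
    fx$cohort, 8, sets = c("histomorphometry", "histomorphometry"),
    n_repeats = 2, seed = 1), "duplicate")
  expect_equal(nrow(grid), 1)

  g1 <- compare_feature_sets(fx$cohort, 8, sets = c("histomorphometry", "ir"),
                             n_repeats = 2, seed = 9)
  g2 <- compare_feature_sets(fx$cohort, 8, sets = c("histomorphometry", "ir"),
                             n_repeats = 2, seed = 9)
  expect_identical(g1, g2)
  expect_equal(g1$feature_set, c("histomorphometry", "ir"))
})

test_that("feature sets with planted infrared signal outrank histomorphometry-only", {
  # mineral drift is planted in the IR features; remodeling drift is
  # turned off so histomorphometry carries no signal
  zero_remodel <- c(mmr_mean = 0, cpr_mean = 0, crystallinity_mean = 0,
                    xlr_mean = 0.03, xlr_sd = 0.01, bmd_hip = 0,
                    n_oc_bpm = 0, ac_f = 0)
  ok <- vapply(1:5, function(s) {
    cfg <- generator_config(n_patients = 120, seed = s,
                            pre_slopes = replace(zero_remodel, "xlr_mean", 0),
                            post_slopes = zero_remodel)
    sim <- simulate_cohort(cfg)
    g <- compare_feature_sets(sim$cohort, 8,
                              sets = c("histomorphometry", "ir", "ir_histo"),
                              n_repeats = 4, seed = s)
    all(g$auc[g$feature_set %in% c("ir", "ir_histo")] >
          g$auc[g$feature_set == "histomorphometry"])
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("duration importances recover planted drift signs", {
  fx <- cached_cohort(200, 3)
  imp <- duration_importances(fx$cohort, 8, n_repeats = 10, seed = 3)
  expect_gt(imp$coefficient[imp$feature == "cpr_mean"], 0)
  expect_lt(imp$coefficient[imp$feature == "n_oc_bpm"], 0)
  expect_true(any(imp$retained))
})
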