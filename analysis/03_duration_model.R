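#!/usr/bin/env Rscript
# Duration model: cutpoint sweep and feature-set comparison.
#
# Dichotomizes treatment duration at candidate cutpoints 5-9 years and
# evaluates a balanced, repeatedly cross-validated boosted-linear model
# per candidate (mRMR-reduced infrared + histomorphometry + BMI
# features). The candidate with maximal mean AUC is the selected
# change-point. At that cutpoint the candidate feature sets are compared
# and signed coefficient importances (retention |c| > 0.2) are reported.
# Runs on the default 67-patient cohort and on a 200-patient cohort,
# where the planted change-point is recovered much more stably.

library(ftirbone)

out <- "results"
dir.create(out, showWarnings = FALSE)

for (n in c(67, 200)) {
  sim <- simulate_cohort(generator_config(n_patients = n))
  sw <- sweep_cutpoints(sim$cohort, n_repeats = 20, seed = 1)
  cat(sprintf("\nn = %d: selected cutpoint %d y\n", n, sw$selected))
  print(round(sw$grid, 3))
  utils::write.csv(sw$grid,
                   file.path(out, sprintf("duration_sweep_n%d.csv", n)),
                   row.names = FALSE)
  if (n == 200) {
    fs <- compare_feature_sets(sim$cohort, sw$selected, n_repeats = 20,
                               seed = 1)
    cat("\nfeature-set comparison at the selected cutpoint:\n")
    print(round(fs[, c("auc", "accuracy")], 3))
    utils::write.csv(fs, file.path(out, "duration_feature_sets.csv"),
                     row.names = FALSE)

    imp <- duration_importances(sim$cohort, sw$selected, n_repeats = 20,
                                seed = 1)
    cat("\nretained duration-model coefficients (vs second period):\n")
    print(imp[imp$retained, ], row.names = FALSE)
    utils::write.csv(imp, file.path(out, "duration_importances.csv"),
                     row.names = FALSE)
  }
}
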