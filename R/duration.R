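# Treatment-duration stage: dichotomize the continuous duration at a
# candidate cutpoint, sweep candidates 5..9 years by cross-validated AUC,
# compare feature sets at the selected cutpoint, and report signed
# coefficient importances relative to second-period membership.

#' Dichotomize treatment duration at a cutpoint
#'
#' `first_period` iff duration <= cutpoint, else `second_period`
#' (boundary values belong to the first period; fractional durations just
#' above the cutpoint fall in the second period).
#'
#' @param duration_years Numeric durations, all >= 1.
#' @param cutpoint Cutpoint in years.
#' @return Factor with levels `first_period`, `second_period`.
#' @export
dichotomize_duration <- function(duration_years, cutpoint) {
  if (any(duration_years < 1)) stop("durations below 1 year are not supported")
  factor(ifelse(duration_years <= cutpoint, "first_period", "second_period"),
         levels = c("first_period", "second_period"))
}

#' Named duration-model feature sets
#'
#' The candidate feature sets compared for the duration outcome:
#' histomorphometry alone, infrared alone, their union, and the union
#' plus patient age, BMI, hip BMD t-score, or hip BMD + BMI. Spine BMD is
#' stored in the cohort table but excluded from every modeling set.
#'
#' @return Named list of character vectors of cohort-table column names.
#' @export
duration_feature_sets <- function() {
  ir <- ir_feature_names(); hist_ <- histo_feature_names()
  list(
    histomorphometry       = hist_,
    ir                     = ir,
    ir_histo               = c(ir, hist_),
    ir_histo_age           = c(ir, hist_, "age"),
    ir_histo_bmi           = c(ir, hist_, "bmi"),
    ir_histo_bmd_hip       = c(ir, hist_, "bmd_hip"),
    ir_histo_bmd_hip_bmi   = c(ir, hist_, "bmd_hip", "bmi"),
    all                    = c(ir, hist_, "age", "bmi", "bmd_hip")
  )
}

#' Sweep duration cutpoints by cross-validated AUC
#'
#' Evaluates one repeated balanced cross-validation per candidate
#' cutpoint (labels re-dichotomized each time) and selects the candidate
#' with maximal mean AUC (ties break to the smaller cutpoint). Candidates
#' leaving either duration category with fewer than `min_class` patients
#' are skipped with a warning; if all are skipped, an error is raised.
#'
#' @param cohort Cohort table from [build_cohort_table()].
#' @param feature_set Feature columns; default the infrared +
#'   histomorphometry + BMI set.
#' @param candidates Candidate cutpoints in years (default 5:9).
#' @param cv_folds,n_repeats,seed,params,mrmr_k Passed to
#'   [cross_validated_eval()].
#' @param min_class Minimum patients per category (default 5).
#' @return List of class `sweep_result`: `grid` (one row per evaluated
#'   candidate, Table-style layout), `selected` (cutpoint), `evals`,
#'   `feature_set`.
#' @export
sweep_cutpoints <- function(cohort,
                            feature_set = duration_feature_sets()$ir_histo_bmi,
                            candidates = 5:9, cv_folds = 5, n_repeats = 50,
                            seed = 1L, params = booster_params(),
                            mrmr_k = 15, min_class = 5) {
  evals <- list()
  for (cp in sort(candidates)) {
    lab <- dichotomize_duration(cohort$duration, cp)
    cnt <- table(lab)
    if (min(cnt) < max(min_class, cv_folds)) {
      warning("cutpoint ", cp, " skipped: smallest category has ",
              min(cnt), " patients")
      next
    }
    tab <- cohort
    tab$duration_cat <- lab
    evals[[as.character(cp)]] <- cross_validated_eval(
      tab, feature_set, "duration_cat", cv_folds = cv_folds,
      n_repeats = n_repeats, seed = seed, params = params, mrmr_k = mrmr_k)
  }
  if (!length(evals)) stop("no candidate cutpoint is evaluable")
  grid <- do.call(rbind, lapply(names(evals), function(cp) {
    e <- evals[[cp]]
    data.frame(cutpoint = as.numeric(cp), auc = e$auc, accuracy = e$accuracy,
               first_precision = e$class1[["precision"]],
               first_sensitivity = e$class1[["sensitivity"]],
               first_f1 = e$class1[["f1"]],
               second_precision = e$class2[["precision"]],
               second_sensitivity = e$class2[["sensitivity"]],
               second_f1 = e$class2[["f1"]])
  }))
  selected <- grid$cutpoint[which.max(grid$auc)]
  structure(list(grid = grid, selected = selected, evals = evals,
                 feature_set = feature_set),
            class = "sweep_result")
}

#' Compare feature sets at a fixed duration cutpoint
#'
#' @param cohort Cohort table.
#' @param cutpoint Duration cutpoint in years.
#' @param sets Names from [duration_feature_sets()]; duplicates are
#'   dropped with a warning, unknown names are an error.
#' @param cv_folds,n_repeats,seed,params,mrmr_k Passed through.
#' @return Data.frame grid, one row per set, same metric layout as the
#'   sweep grid.
#' @export
compare_feature_sets <- function(cohort, cutpoint,
                                 sets = setdiff(names(duration_feature_sets()), "all"),
                                 cv_folds = 5, n_repeats = 50, seed = 1L,
                                 params = booster_params(), mrmr_k = 15) {
  known <- duration_feature_sets()
  bad <- setdiff(sets, names(known))
  if (length(bad))
    stop("unknown feature set(s): ", paste(bad, collapse = ", "),
         "; valid sets: ", paste(names(known), collapse = ", "))
  if (anyDuplicated(sets)) {
    warning("duplicate feature set names dropped")
    sets <- unique(sets)
  }
  tab <- cohort
  tab$duration_cat <- dichotomize_duration(cohort$duration, cutpoint)
  grid <- do.call(rbind, lapply(sets, function(nm) {
    e <- cross_validated_eval(tab, known[[nm]], "duration_cat",
                              cv_folds = cv_folds, n_repeats = n_repeats,
                              seed = seed, params = params, mrmr_k = mrmr_k)
    data.frame(feature_set = nm, auc = e$auc, accuracy = e$accuracy,
               first_precision = e$class1[["precision"]],
               first_sensitivity = e$class1[["sensitivity"]],
               first_f1 = e$class1[["f1"]],
               second_precision = e$class2[["precision"]],
               second_sensitivity = e$class2[["sensitivity"]],
               second_f1 = e$class2[["f1"]])
  }))
  rownames(grid) <- NULL
  grid
}

# average standardized coefficients over repeated balanced fits on the
# full (down-sampled) table; features never selected by mRMR average 0
repeated_coefficients <- function(table, feature_set, label, n_repeats,
                                  seed, params, mrmr_k) {
  lev <- levels(factor(table[[label]]))
  acc <- stats::setNames(numeric(length(feature_set)), feature_set)
  for (r in seq_len(n_repeats)) {
    seed_r <- seed + r - 1L
    bal <- downsample_balance(table, label, seed = seed_r)
    feats <- feature_set
    if (!is.null(mrmr_k) && mrmr_k < length(feature_set))
      feats <- mrmr_select(bal[, feature_set, drop = FALSE],
                           factor(bal[[label]], levels = lev), k = mrmr_k)
    Z <- standardize_features(as.matrix(bal[, feats, drop = FALSE]))
    p_r <- params; p_r$seed <- seed_r
    fit <- fit_classifier(Z, factor(bal[[label]], levels = lev) == lev[2], p_r)
    acc[feats] <- acc[feats] + fit$coefficients
  }
  acc / n_repeats
}

#' Duration-model coefficient importances
#'
#' Fits the boosted-linear classifier on repeated balanced draws of the
#' whole cohort (standardized features, optional mRMR reduction per
#' draw), averages the per-feature coefficients over draws, and applies
#' the retention rule. Signs are reported relative to second-period
#' membership (positive = higher values at long durations).
#'
#' @param cohort Cohort table.
#' @param cutpoint Duration cutpoint in years.
#' @param feature_set Feature columns (default all modeling features).
#' @param n_repeats,seed,params,retention Tuning knobs.
#' @param mrmr_k Optional mRMR reduction per draw; `NULL` (default) fits
#'   on all parameters so every coefficient is estimated before the
#'   retention rule is applied.
#' @return An `importance_table` (see [extract_importances()]).
#' @export
duration_importances <- function(cohort, cutpoint,
                                 feature_set = duration_feature_sets()$all,
                                 n_repeats = 50, seed = 1L,
                                 params = booster_params(), mrmr_k = NULL,
                                 retention = 0.2) {
  tab <- cohort
  tab$duration_cat <- dichotomize_duration(cohort$duration, cutpoint)
  coefs <- repeated_coefficients(tab, feature_set, "duration_cat",
                                 n_repeats, seed, params, mrmr_k)
  extract_importances(coefs, retention = retention)
}
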