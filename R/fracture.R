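# Fracture stage: low-energy fracture as the binary outcome, compared
# across feature sets that include treatment duration as a categorical
# or continuous predictor, with signed coefficient importances.

#' Named fracture-model feature sets
#'
#' Candidate predictor sets for the fracture outcome: histomorphometry
#' alone, duration alone (categorical at the supplied cutpoint, or
#' continuous), infrared alone, and unions of infrared with
#' histomorphometry and/or continuous duration. The `all` set adds the
#' patient covariates (age, BMI, hip BMD) so their non-retention is
#' testable.
#'
#' @param cutpoint Cutpoint (years) defining the categorical duration
#'   column `duration_cat01`.
#' @return Named list of character vectors of cohort-table column names.
#' @export
fracture_feature_sets <- function(cutpoint = 8) {
  ir <- ir_feature_names(); hist_ <- histo_feature_names()
  list(
    histomorphometry            = hist_,
    duration_categorical        = "duration_cat01",
    duration_continuous         = "duration",
    ir                          = ir,
    ir_histo                    = c(ir, hist_),
    ir_duration_continuous      = c(ir, "duration"),
    ir_histo_duration_continuous = c(ir, hist_, "duration"),
    all                         = c(ir, hist_, "duration", "age", "bmi",
                                    "bmd_hip")
  )
}

# add the 0/1 categorical-duration predictor used by the fracture models
with_duration_cat01 <- function(cohort, cutpoint) {
  cohort$duration_cat01 <-
    as.integer(dichotomize_duration(cohort$duration, cutpoint) ==
                 "second_period")
  cohort
}

#' Compare fracture models across feature sets
#'
#' One repeated balanced cross-validation per requested feature set, with
#' down-sampling on the fracture flag; the grid reports AUC, accuracy and
#' per-class (no-fracture / fracture) precision, sensitivity and F-1.
#'
#' @param cohort Cohort table with a 0/1 `fracture` column.
#' @param specs Names from [fracture_feature_sets()]; duplicates are
#'   dropped with a warning, unknown names are an error.
#' @param cutpoint Cutpoint (years) for the categorical-duration set.
#' @param cv_folds,n_repeats,seed,params,mrmr_k Passed to
#'   [cross_validated_eval()].
#' @return Data.frame grid, one row per spec.
#' @export
compare_fracture_models <- function(cohort,
                                    specs = setdiff(names(fracture_feature_sets()), "all"),
                                    cutpoint = 8, cv_folds = 5,
                                    n_repeats = 50, seed = 1L,
                                    params = booster_params(), mrmr_k = 15) {
  known <- fracture_feature_sets(cutpoint)
  bad <- setdiff(specs, names(known))
  if (length(bad))
    stop("unknown fracture model spec(s): ", paste(bad, collapse = ", "),
         "; valid specs: ", paste(names(known), collapse = ", "))
  if (anyDuplicated(specs)) {
    warning("duplicate fracture model specs dropped")
    specs <- unique(specs)
  }
  if (length(unique(cohort$fracture)) != 2)
    stop("both fracture classes must be present")
  tab <- with_duration_cat01(cohort, cutpoint)
  tab$fracture_lab <- factor(ifelse(tab$fracture == 1, "fracture",
                                    "no_fracture"),
                             levels = c("no_fracture", "fracture"))
  grid <- do.call(rbind, lapply(specs, function(nm) {
    e <- cross_validated_eval(tab, known[[nm]], "fracture_lab",
                              cv_folds = cv_folds, n_repeats = n_repeats,
                              seed = seed, params = params,
                              mrmr_k = if (length(known[[nm]]) > 1) mrmr_k else NULL)
    data.frame(feature_set = nm, auc = e$auc, accuracy = e$accuracy,
               no_fracture_precision = e$class1[["precision"]],
               no_fracture_sensitivity = e$class1[["sensitivity"]],
               no_fracture_f1 = e$class1[["f1"]],
               fracture_precision = e$class2[["precision"]],
               fracture_sensitivity = e$class2[["sensitivity"]],
               fracture_f1 = e$class2[["f1"]])
  }))
  rownames(grid) <- NULL
  grid
}

#' Fracture-model coefficient importances
#'
#' Averages standardized boosted-linear coefficients over repeated
#' balanced draws (down-sampling on the fracture flag) and applies the
#' retention rule. Signs are relative to fracture membership (positive =
#' higher values in patients who fractured).
#'
#' @param cohort Cohort table with a 0/1 `fracture` column.
#' @param feature_set Feature columns (default the `all` set, so patient
#'   covariates compete for retention).
#' @param cutpoint Cutpoint for the categorical-duration column.
#' @param n_repeats,seed,params,retention Tuning knobs.
#' @param mrmr_k Optional mRMR reduction per draw; `NULL` (default) fits
#'   on all parameters so every coefficient is estimated before the
#'   retention rule is applied.
#' @return An `importance_table` (see [extract_importances()]).
#' @export
fracture_importances <- function(cohort,
                                 feature_set = fracture_feature_sets()$all,
                                 cutpoint = 8, n_repeats = 50, seed = 1L,
                                 params = booster_params(), mrmr_k = NULL,
                                 retention = 0.2) {
  tab <- with_duration_cat01(cohort, cutpoint)
  tab$fracture_lab <- factor(ifelse(tab$fracture == 1, "fracture",
                                    "no_fracture"),
                             levels = c("no_fracture", "fracture"))
  coefs <- repeated_coefficients(tab, feature_set, "fracture_lab",
                                 n_repeats, seed, params, mrmr_k)
  extract_importances(coefs, retention = retention)
}
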