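# Metrics, down-sampling, mRMR, the boosted classifier and
# cross-validated evaluation.

test_that("AUC equals brute-force pairwise concordance", {
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(auc(rep(5, 8), c(0, 1, 0, 1, 0, 1, 0, 1)), 0.5)

  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    g <- outer(pos, neg, ">"); t <- outer(pos, neg, "==")
    (sum(g) + 0.5 * sum(t)) / (length(pos) * length(neg))
  }
  set.seed(7)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq_len(5), n, replace = TRUE) + rnorm(n, 0, 0.01)
    expect_equal(auc(s, y), brute(s, y), tolerance = 1e-12)
  }
  expect_error(auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  y <- rbinom(40, 1, 0.4); y[1:2] <- c(0, 1)
  s <- rnorm(40) + y
  expect_equal(auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("class metrics reproduce harmonic-mean F-1 values", {
  # p = s = 0.9 by construction
  cv <- confusion_vectors(tp = 9, fp = 1, fn = 1, tn = 9)
  m <- class_metrics(cv$predicted, cv$labels, "pos")
  expect_equal(unname(m), c(0.9, 0.9, 0.9))

  # printed-pair fixtures: (0.80, 0.96) -> 0.87 and (0.88, 0.90) -> 0.89
  cv1 <- confusion_vectors(tp = 48, fp = 12, fn = 2, tn = 38)
  m1 <- class_metrics(cv1$predicted, cv1$labels, "pos")
  expect_equal(unname(m1[c("precision", "sensitivity")]), c(0.80, 0.96))
  expect_equal(round(m1[["f1"]], 2), 0.87)

  cv2 <- confusion_vectors(tp = 396, fp = 54, fn = 44, tn = 106)
  m2 <- class_metrics(cv2$predicted, cv2$labels, "pos")
  expect_equal(unname(m2[c("precision", "sensitivity")]), c(0.88, 0.90))
  expect_equal(round(m2[["f1"]], 2), 0.89)

  # zero denominators report 0, warning once each for precision and
  # sensitivity
  expect_warning(
    expect_warning(z <- class_metrics(rep("neg", 4), rep("neg", 4), "pos"),
                   "zero denominator"),
    "zero denominator")
  expect_equal(unname(z), c(0, 0, 0))
})

test_that("down-sampling balances classes deterministically", {
  tab <- data.frame(id = 1:67, y = rep(c("no", "yes"), c(45, 22)))
  bal <- downsample_balance(tab, "y", seed = 3)
  expect_equal(as.integer(table(bal$y)), c(22L, 22L))
  expect_identical(bal, downsample_balance(tab, "y", seed = 3))
  # already balanced input is unchanged in class counts
  tb2 <- data.frame(y = rep(c("a", "b"), each = 10))
  expect_equal(as.integer(table(downsample_balance(tb2, "y", 1)$y)),
               c(10L, 10L))
  expect_error(downsample_balance(data.frame(y = rep("a", 5)), "y", 1),
               "two non-empty classes")
})

test_that("mRMR prefers relevant, non-redundant features", {
  set.seed(5)
  n <- 120
  lab <- rbinom(n, 1, 0.5)
  A <- lab + rnorm(n, 0, 0.05)
  feats <- data.frame(noise1 = rnorm(n), A = A, A_copy = A + rnorm(n, 0, 1e-4),
                      B = lab + rnorm(n, 0, 0.8), noise2 = rnorm(n))
  expect_equal(mrmr_select(feats, lab, k = 1), "A")
  expect_setequal(mrmr_select(feats[c("A", "A_copy", "B")], lab, k = 2),
                  c("A", "B"))
  expect_equal(sort(mrmr_select(feats, lab, k = 99)), sort(names(feats)))
  expect_error(mrmr_select(feats, lab, k = 0), "k must be")
})

test_that("the boosted-linear classifier separates and is deterministic", {
  set.seed(2)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(f1 = y * 4 + rnorm(n, 0, 0.3), f2 = rnorm(n))
  Z <- standardize_features(X)
  fit <- fit_classifier(Z, y, booster_params(seed = 9))
  expect_gte(auc(predict(fit, Z), y), 0.99)
  fit2 <- fit_classifier(Z, y, booster_params(seed = 9))
  expect_identical(fit$coefficients, fit2$coefficients)
  expect_gt(fit$coefficients[["f1"]], abs(fit$coefficients[["f2"]]))

  Xb <- Z; Xb[1, 1] <- NA
  expect_error(fit_classifier(Xb, y), "NA")
})

test_that("tree booster exposes surrogate coefficients behind the contract", {
  set.seed(3)
  n <- 80
  y <- rbinom(n, 1, 0.5)
  X <- cbind(s = y * 2 + rnorm(n), n1 = rnorm(n))
  fit <- fit_classifier(standardize_features(X), y,
                        booster_params(booster_kind = "tree", n_rounds = 50))
  expect_named(fit$coefficients, c("s", "n1"))
  expect_gt(abs(fit$coefficients[["s"]]), abs(fit$coefficients[["n1"]]))
})

test_that("uninformative features give chance-level cross-validated AUC", {
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    tab <- as.data.frame(matrix(rnorm(200 * 6), 200))
    tab$y <- factor(rep(c("a", "b"), each = 100))
    suppressWarnings(cross_validated_eval(
      tab, paste0("V", 1:6), "y", n_repeats = 3, seed = s,
      params = booster_params(n_rounds = 50))$auc)
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.1)
})

test_that("cross-validated evaluation is reproducible and well-formed", {
  fx <- cached_cohort(67, 1)
  tab <- fx$cohort
  tab$dc <- dichotomize_duration(tab$duration, 8)
  e1 <- cross_validated_eval(tab, histo_feature_names(), "dc",
                             n_repeats = 3, seed = 5, mrmr_k = 6)
  e2 <- cross_validated_eval(tab, histo_feature_names(), "dc",
                             n_repeats = 3, seed = 5, mrmr_k = 6)
  expect_equal(e1$auc, e2$auc)
  expect_equal(e1$class2, e2$class2)
  for (v in c(e1$auc, e1$accuracy, e1$class1, e1$class2))
    expect_true(all(v >= 0 & v <= 1))
  # F-1 invariant on every per-repeat record
  for (r in e1$per_repeat) for (cl in c("class1", "class2")) {
    p <- r[[cl]][["precision"]]; s <- r[[cl]][["sensitivity"]]
    f_exp <- if (p + s > 0) 2 * p * s / (p + s) else 0
    expect_equal(r[[cl]][["f1"]], f_exp)
  }
  expect_error(cross_validated_eval(tab, "age", "dc", cv_folds = 40),
               "cv_folds")
})

test_that("importance tables sort, retain and warn correctly", {
  imp <- extract_importances(c(a = 0.3, b = -0.25, c = 0.1))
  expect_equal(imp$feature, c("a", "b", "c"))
  expect_equal(imp$retained, c(TRUE, TRUE, FALSE))
  expect_warning(imp0 <- extract_importances(c(a = 0.05, b = -0.1)),
                 "retention")
  expect_false(any(imp0$retained))
})
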