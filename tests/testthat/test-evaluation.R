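test_that("decision threshold equals the training frequency of the positive class", {
  expect_equal(decision_threshold(rep(c("ADHD", "control"), each = 29), "ADHD"),
               0.5)
  expect_equal(decision_threshold(c(rep("ADHD", 29), rep("non", 48)), "ADHD"),
               29 / 77)
  expect_error(decision_threshold(rep("ADHD", 5), "ADHD"), "both classes")
  # tie at the threshold goes to the positive (patient) class
  expect_true(categorize(0.5, 0.5))
  expect_false(categorize(0.4999, 0.5))
})

test_that("confusion metrics reproduce worked clinical examples", {
  cm <- confusion_metrics(TP = 22, FN = 7, TN = 24, FP = 5)
  expect_equal(round(cm$sensitivity, 1), 75.9)
  expect_equal(round(cm$specificity, 1), 82.8)
  expect_equal(round(cm$ppv, 1), 81.5)
  expect_equal(round(cm$npv, 1), 77.4)
  expect_equal(round(cm$balanced_accuracy, 1), 79.3)

  cm2 <- confusion_metrics(TP = 25, FN = 4, TN = 16, FP = 3)
  expect_equal(round(cm2$ppv, 1), 89.3)
  expect_equal(round(cm2$npv, 1), 80.0)
  expect_equal(round(cm2$balanced_accuracy, 1), 85.2)

  all_right <- confusion_metrics(TP = 10, FN = 0, TN = 8, FP = 0)
  expect_equal(all_right$balanced_accuracy, 100)
  expect_equal(all_right$ppv, 100)
})

test_that("confusion metrics match hand formulas for every table with totals <= 12", {
  # exhaustive enumeration over all nonnegative count tables, computed
  # from label/prediction vectors so counting and ratios are both checked
  for (TP in 0:6) for (FN in 0:(6 - TP)) for (TN in 0:6) for (FP in 0:(6 - TN)) {
    if (TP + FN == 0 || TN + FP == 0) next
    truth <- c(rep("pos", TP + FN), rep("neg", TN + FP))
    pred <- c(rep("pos", TP), rep("neg", FN), rep("neg", TN), rep("pos", FP))
    cm <- suppressWarnings(
      confusion_metrics(data.frame(true = truth, predicted = pred), "pos"))
    expect_identical(c(cm$TP, cm$FP, cm$TN, cm$FN), c(TP, FP, TN, FN))
    expect_equal(cm$sensitivity, 100 * TP / (TP + FN))
    expect_equal(cm$specificity, 100 * TN / (TN + FP))
    expect_equal(cm$balanced_accuracy,
                 (100 * TP / (TP + FN) + 100 * TN / (TN + FP)) / 2)
    if (TP + FP > 0) expect_equal(cm$ppv, 100 * TP / (TP + FP))
    else expect_true(is.na(cm$ppv))
    if (TN + FN > 0) expect_equal(cm$npv, 100 * TN / (TN + FN))
    else expect_true(is.na(cm$npv))
  }
  expect_warning(confusion_metrics(TP = 0, FN = 0, TN = 3, FP = 1),
                 "sensitivity undefined")
})

test_that("multiclass balanced accuracy is the mean of per-class sensitivities", {
  res <- data.frame(
    true = rep(c("a", "b", "c"), times = c(4, 4, 4)),
    predicted = c("a", "a", "b", "a", "b", "b", "c", "b", "c", "c", "a", "c"),
    stringsAsFactors = FALSE)
  m <- multiclass_metrics(res)
  sens_by_hand <- c(3 / 4, 3 / 4, 3 / 4) * 100
  expect_equal(m$per_class$sensitivity, sens_by_hand)
  expect_equal(m$balanced_accuracy, mean(sens_by_hand))
  # simulated predictions at arbitrary confusion structure
  set.seed(31)
  truth <- sample(letters[1:3], 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.7, truth, sample(letters[1:3], 60, TRUE))
  m2 <- multiclass_metrics(data.frame(true = truth, predicted = pred))
  by_hand <- vapply(letters[1:3], function(cl)
    100 * mean(pred[truth == cl] == cl), numeric(1))
  expect_equal(m2$balanced_accuracy, mean(by_hand))
})

test_that("AUC equals the brute-force pairwise comparison oracle", {
  set.seed(32)
  for (rep in 1:10) {
    n <- sample(6:14, 1)
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1] <- !lab[1]
    # coarse scores force ties
    sc <- round(runif(n), 1)
    got <- roc_auc(scores = sc, labels = lab)
    expect_identical(got$auc, pairwise_auc(sc, lab))
    expect_true(all(diff(got$curve$tpr) >= 0))
    expect_true(all(diff(got$curve$fpr) >= 0))
  }
  expect_equal(roc_auc(scores = c(0.9, 0.8, 0.2, 0.1),
                       labels = c(TRUE, TRUE, FALSE, FALSE))$auc, 1.0)
  # independent library cross-check on one instance
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(33)
    sc <- runif(20); lab <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    lab[1:2] <- c(TRUE, FALSE)
    ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores = sc, labels = lab)$auc, ref,
                 tolerance = 1e-12)
  }
  expect_warning(
    flat <- roc_auc(scores = rep(0.5, 6),
                    labels = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)),
    "constant")
  expect_equal(flat$auc, 0.5)
})

test_that("target information scores baseline at 0, perfection at 1", {
  truth <- rep(c("p", "n"), each = 10)
  base <- data.frame(true = truth, prob_positive = 0.5)
  expect_equal(target_information(base, "p"), 0)
  perfect <- data.frame(true = truth,
                        prob_positive = rep(c(1 - 1e-15, 1e-15), each = 10))
  expect_equal(target_information(perfect, "p"), 1, tolerance = 1e-9)
  two <- data.frame(true = c("p", "n"), prob_positive = c(0.8, 0.2))
  expect_equal(target_information(two, "p"), 1 + log2(0.8), tolerance = 1e-12)
  # unbalanced baseline emitting the class frequency is also 0
  truth_u <- rep(c("p", "n"), times = c(3, 9))
  base_u <- data.frame(true = truth_u, prob_positive = 0.25)
  expect_equal(target_information(base_u, "p"), 0, tolerance = 1e-12)
  expect_warning(
    target_information(data.frame(true = "p", prob_positive = 0), "p"),
    "floored")
})

test_that("probability-covariate correlations match the textbook formula per group", {
  man <- data.frame(subject_id = sprintf("s%d", 1:10),
                    group = rep(c("g1", "g2"), each = 5),
                    age_years = c(11, 14, 12, 16, 13, 15, 10, 13, 12, 17),
                    iq = c(101, 96, 104, 99, 110, 95, 102, 98, 107, 100),
                    cprs_t = rnorm(10, 60, 8), sdq_hi = rnorm(10, 5, 2))
  res <- data.frame(subject_id = man$subject_id,
                    true = man$group,
                    prob_positive = c(0.8, 0.6, 0.7, 0.55, 0.9,
                                      0.3, 0.45, 0.2, 0.35, 0.5))
  tab <- probability_covariate_correlation(res, man)
  r_hand <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  g1 <- man$group == "g1"
  expect_equal(tab$r[tab$group == "g1" & tab$covariate == "age_years"],
               r_hand(res$prob_positive[g1], man$age_years[g1]),
               tolerance = 1e-12)
  expect_equal(tab$r[tab$group == "g2" & tab$covariate == "iq"],
               r_hand(res$prob_positive[!g1], man$iq[!g1]),
               tolerance = 1e-12)
  # covariate identical to the probability: r = 1
  man2 <- man; man2$iq <- res$prob_positive
  tab2 <- probability_covariate_correlation(res, man2, covariates = "iq")
  expect_equal(tab2$r, rep(1, 2), tolerance = 1e-12)
  # zero-variance covariate flagged, not silently zero
  man3 <- man; man3$iq <- 100
  w <- capture_warnings(
    tab3 <- probability_covariate_correlation(res, man3, covariates = "iq"))
  expect_match(w, "zero variance", all = TRUE)
  expect_length(w, 2)  # one per group
  expect_true(all(is.na(tab3$r)))
})

test_that("cross-validation fold structure follows the design", {
  cp <- cluster_patterns(c(ADHD = 6, control = 6), sep = 6, seed = 41)
  K <- linear_kernel(cp$X, normalize = TRUE)
  age <- rnorm(12, 14, 2)
  res <- loo_cv_binary(K, cp$labels, "ADHD", cv_scheme("leave-one-pair"),
                       age = age)
  expect_equal(nrow(res), 12)
  expect_equal(length(unique(res$fold)), 6)  # one fold per matched pair
  expect_true(all(table(res$fold, res$true) == 1))  # each fold: 1 of each
  expect_true(all(res$threshold == 0.5))
  # every subject predicted exactly once
  expect_false(anyNA(res$prob_positive))
  # unbalanced: one fold per subject, thresholds shift with the held-out
  cp2 <- cluster_patterns(c(ADHD = 5, control = 4, ASD = 3), sep = 6, seed = 42)
  lab2 <- ifelse(cp2$labels == "ADHD", "ADHD", "non-ADHD")
  res2 <- loo_cv_binary(linear_kernel(cp2$X, normalize = TRUE), lab2, "ADHD")
  expect_equal(res2$fold, 1:12)
  expect_equal(res2$threshold,
               ifelse(lab2 == "ADHD", 4 / 11, 5 / 11), tolerance = 1e-12)
  # perfectly separable cohort: all categorical predictions correct
  expect_identical(res$predicted, res$true)
  expect_identical(res2$predicted, res2$true)
})

test_that("multiclass cross-validation recovers separable classes", {
  cp <- cluster_patterns(c(A = 5, B = 5, C = 4), sep = 8, seed = 43)
  res <- loo_cv_multiclass(linear_kernel(cp$X, normalize = TRUE), cp$labels,
                           n_draws = 2000L)
  expect_equal(nrow(res), 14)
  probs <- as.matrix(res[, paste0("prob_", c("A", "B", "C"))])
  expect_equal(rowSums(probs), rep(1, 14), tolerance = 1e-9)
  expect_identical(res$predicted, res$true)
  m <- multiclass_metrics(res)
  expect_equal(m$balanced_accuracy, 100)
})
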