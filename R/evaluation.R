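#' Cross-validation scheme
#'
#' Balanced two-group designs use leave-one-pair-out: each fold holds out
#' one matched patient/control pair, so the training set stays balanced
#' and the 0.5 decision threshold is exact.  Unbalanced binary and
#' multiclass designs use leave-one-subject-out.
#'
#' @param mode `"leave-one-pair"` or `"leave-one-subject"`.
#' @param pairing optional two-column integer matrix of subject indices
#'   (one row per matched pair).  When omitted for the paired mode, pairs
#'   are derived by sorting each group by `age` rank (the matching
#'   variable) and pairing by rank; with no ages, by within-group order.
#' @return Object of class `cv_scheme`.
#' @export
cv_scheme <- function(mode = c("leave-one-pair", "leave-one-subject"),
                      pairing = NULL) {
  mode <- match.arg(mode)
  structure(list(mode = mode, pairing = pairing), class = "cv_scheme")
}

# Derive matched pairs for a balanced two-group design: rank each group
# by age and pair equal ranks.
derive_pairing <- function(labels, age = NULL) {
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2)
    stop("leave-one-pair cross-validation needs exactly two groups")
  i1 <- which(labels == lev[1]); i2 <- which(labels == lev[2])
  if (length(i1) != length(i2))
    stop("leave-one-pair cross-validation needs balanced groups (",
         length(i1), " vs ", length(i2), ")")
  if (is.null(age)) age <- seq_along(labels)
  cbind(i1[order(age[i1])], i2[order(age[i2])])
}

cv_folds <- function(labels, scheme, age = NULL) {
  if (scheme$mode == "leave-one-subject")
    return(lapply(seq_along(labels), identity))
  pairing <- scheme$pairing
  if (is.null(pairing)) pairing <- derive_pairing(labels, age)
  if (nrow(pairing) * 2L != length(labels) ||
      length(unique(as.vector(pairing))) != length(labels))
    stop("pairing must partition all subjects into disjoint pairs")
  lapply(seq_len(nrow(pairing)), function(i) as.integer(pairing[i, ]))
}

#' Categorical decision threshold from training-class frequencies
#'
#' The probabilistic predictions are thresholded at the training-set
#' frequency of the positive class (0.5 for balanced classes), which
#' compensates for class imbalance.  A prediction exactly at the
#' threshold is assigned to the positive (patient) class.
#'
#' @param train_labels training labels.
#' @param positive_label the patient class.
#' @return Threshold in (0, 1).
#' @export
decision_threshold <- function(train_labels, positive_label) {
  f <- mean(as.character(train_labels) == positive_label)
  if (f <= 0 || f >= 1) stop("both classes must be present in training")
  f
}

#' @rdname decision_threshold
#' @param p predicted probability of the positive class.
#' @param threshold decision threshold.
#' @export
categorize <- function(p, threshold) p >= threshold

#' Leave-one-out cross-validated binary GP classification
#'
#' Runs the full cross-validation loop: for each fold, the held-out unit
#' (matched pair or single subject) is removed, the kernel's training
#' block is (optionally) mean-centered with respect to the training
#' subjects only, the EP classifier is fitted, and the held-out subjects
#' receive predictive probabilities; the categorical prediction uses that
#' fold's training-class frequency as threshold.
#'
#' @param K [linear_kernel()] result or n x n kernel matrix over all
#'   subjects.
#' @param labels length-n vector of two group labels.
#' @param positive_label the patient class (mapped to +1).
#' @param scheme a [cv_scheme()].
#' @param age optional ages for pair matching.
#' @param center mean-center the kernel in feature space within each
#'   training fold.
#' @param subject_ids optional ids for the output table.
#' @param scale_grid optional vector of kernel scales; when given, each
#'   fold refits at every scale and keeps the one maximizing the EP log
#'   marginal likelihood of its own training set (no test leakage).
#'   `NULL` uses the kernel as supplied.
#' @param bias constant added to every kernel entry after centering and
#'   scaling.  It acts as a learnable intercept: without it a centered
#'   zero-mean GP cannot represent the class-frequency offset, and
#'   predictive probabilities compress around 0.5, which miscalibrates
#'   frequency thresholding in unbalanced designs.
#' @param ... passed to [fit_gpc_binary_ep()].
#' @return `data.frame` with one row per subject: `subject_id`, `fold`,
#'   `true`, `prob_positive`, `threshold`, `predicted`.
#' @export
loo_cv_binary <- function(K, labels, positive_label,
                          scheme = cv_scheme("leave-one-subject"),
                          age = NULL, center = TRUE, subject_ids = NULL,
                          scale_grid = NULL, bias = 1, ...) {
  Kv <- kernel_values(K)
  n <- length(labels)
  stopifnot(nrow(Kv) == n)
  labels <- as.character(labels)
  if (!positive_label %in% labels)
    stop("positive_label '", positive_label, "' not found in labels")
  folds <- cv_folds(labels, scheme, age)
  if (is.null(subject_ids)) subject_ids <- sprintf("sub-%03d", seq_len(n))
  out <- data.frame(subject_id = subject_ids, fold = NA_integer_,
                    true = labels, prob_positive = NA_real_,
                    threshold = NA_real_, predicted = NA_character_,
                    stringsAsFactors = FALSE)
  for (fi in seq_along(folds)) {
    test <- folds[[fi]]
    train <- setdiff(seq_len(n), test)
    Kc <- if (center) center_kernel(Kv, train) else Kv
    fit_at <- function(s) fit_gpc_binary_ep(
      s * Kc[train, train, drop = FALSE] + bias,
      labels[train], positive_label, ...)
    if (is.null(scale_grid)) {
      s_best <- 1
      post <- fit_at(1)
    } else {
      fits <- lapply(scale_grid, fit_at)
      best <- which.max(vapply(fits, function(f) f$lml, numeric(1)))
      s_best <- scale_grid[best]
      post <- fits[[best]]
    }
    p <- predict_gpc_binary(post,
                            s_best * Kc[train, test, drop = FALSE] + bias,
                            s_best * diag(Kc)[test] + bias)
    thr <- decision_threshold(labels[train], positive_label)
    out$fold[test] <- fi
    out$prob_positive[test] <- p
    out$threshold[test] <- thr
    neg <- setdiff(unique(labels), positive_label)
    out$predicted[test] <- ifelse(categorize(p, thr), positive_label,
                                  if (length(neg) == 1) neg else "negative")
  }
  out
}

#' Leave-one-subject-out cross-validated multiclass GP classification
#'
#' @param K kernel over all subjects.
#' @param labels class labels (>= 3 classes).
#' @param center mean-center the kernel within each training fold.
#' @param subject_ids optional ids.
#' @param n_draws,seed Monte Carlo settings for
#'   [predict_gpc_multiclass()].
#' @param scale_grid optional kernel-scale grid, selected per fold by the
#'   Laplace log marginal likelihood of the training set.
#' @param bias constant kernel offset serving as a per-class learnable
#'   intercept, as in [loo_cv_binary()].
#' @param ... passed to [fit_gpc_multiclass_laplace()].
#' @return `data.frame` with `subject_id`, `fold`, `true`, one
#'   `prob_<class>` column per class, and `predicted` (argmax of the
#'   training-frequency-adjusted probabilities, the multiclass analogue
#'   of frequency thresholding).
#' @export
loo_cv_multiclass <- function(K, labels, center = TRUE, subject_ids = NULL,
                              n_draws = 10000L, seed = 1L,
                              scale_grid = NULL, bias = 1, ...) {
  Kv <- kernel_values(K)
  n <- length(labels)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (is.null(subject_ids)) subject_ids <- sprintf("sub-%03d", seq_len(n))
  probs <- matrix(NA_real_, n, length(classes),
                  dimnames = list(NULL, classes))
  predicted <- character(n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    Kc <- if (center) center_kernel(Kv, train) else Kv
    fit_at <- function(s) fit_gpc_multiclass_laplace(
      s * Kc[train, train, drop = FALSE] + bias, labels[train], ...)
    if (is.null(scale_grid)) {
      s_best <- 1
      post <- fit_at(1)
    } else {
      fits <- lapply(scale_grid, fit_at)
      best <- which.max(vapply(fits, function(f) f$lml, numeric(1)))
      s_best <- scale_grid[best]
      post <- fits[[best]]
    }
    p <- predict_gpc_multiclass(post, s_best * Kc[train, i] + bias,
                                s_best * diag(Kc)[i] + bias,
                                n_draws = n_draws,
                                seed = derive_seed(seed, paste0("fold", i)))
    probs[i, post$classes] <- p[1, ]
    freq <- vapply(classes, function(cl) mean(labels[train] == cl),
                   numeric(1))
    predicted[i] <- classes[which.max(probs[i, ] / freq)]
  }
  out <- data.frame(subject_id = subject_ids, fold = seq_len(n),
                    true = labels, stringsAsFactors = FALSE)
  colnames(probs) <- paste0("prob_", classes)
  cbind(out, as.data.frame(probs), predicted = predicted,
        stringsAsFactors = FALSE)
}

#' Confusion counts and categorical performance metrics
#'
#' Sensitivity and specificity are the proportions of patients and
#' controls with the correct label; balanced accuracy is their unweighted
#' mean, which accommodates class imbalance.  All percentages are stored
#' at full precision and printed to one decimal.
#'
#' @param results a cross-validation result table (`true`/`predicted`
#'   columns), or `NULL` when counts are given directly.
#' @param positive_label the patient class.
#' @param TP,FP,TN,FN integer counts, alternative to `results`.
#' @return Object of class `confusion_summary`: counts and
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `balanced_accuracy` in
#'   percent.  Metrics with an empty denominator are `NA` and flagged
#'   with a warning, never silently 0.
#' @export
confusion_metrics <- function(results = NULL, positive_label = NULL,
                              TP = NULL, FP = NULL, TN = NULL, FN = NULL) {
  if (!is.null(results)) {
    stopifnot(!is.null(positive_label))
    pos <- results$true == positive_label
    hit <- results$predicted == results$true
    TP <- sum(pos & hit); FN <- sum(pos & !hit)
    TN <- sum(!pos & hit); FP <- sum(!pos & !hit)
  }
  stopifnot(!is.null(TP), !is.null(FP), !is.null(TN), !is.null(FN),
            TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: empty denominator")
      return(NA_real_)
    }
    100 * num / den
  }
  sens <- ratio(TP, TP + FN, "sensitivity")
  spec <- ratio(TN, TN + FP, "specificity")
  structure(
    list(TP = TP, FP = FP, TN = TN, FN = FN,
         sensitivity = sens, specificity = spec,
         ppv = ratio(TP, TP + FP, "PPV"),
         npv = ratio(TN, TN + FN, "NPV"),
         balanced_accuracy = (sens + spec) / 2),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(
    "TP %d  FP %d  TN %d  FN %d\nsensitivity %.1f%%  specificity %.1f%%\nPPV %.1f%%  NPV %.1f%%  balanced accuracy %.1f%%\n",
    x$TP, x$FP, x$TN, x$FN, x$sensitivity, x$specificity, x$ppv, x$npv,
    x$balanced_accuracy))
  invisible(x)
}

#' Multiclass per-class metrics
#'
#' Each class is scored one-vs-rest: sensitivity is the proportion of
#' that class correctly labeled, PPV the precision of calls for it.
#' Multiclass balanced accuracy is the unweighted mean of the per-class
#' sensitivities.
#'
#' @param results table with `true` and `predicted` columns.
#' @return List with `per_class` (data.frame: class, n, sensitivity,
#'   ppv) and `balanced_accuracy`, in percent.
#' @export
multiclass_metrics <- function(results) {
  classes <- sort(unique(results$true))
  per <- do.call(rbind, lapply(classes, function(cl) {
    is_cl <- results$true == cl
    called <- results$predicted == cl
    data.frame(class = cl, n = sum(is_cl),
               sensitivity = 100 * sum(is_cl & called) / sum(is_cl),
               ppv = if (sum(called) == 0) NA_real_ else
                 100 * sum(is_cl & called) / sum(called),
               stringsAsFactors = FALSE)
  }))
  list(per_class = per, balanced_accuracy = mean(per$sensitivity))
}

#' ROC curve and AUC from probabilistic predictions
#'
#' The curve traces true against false positive rate as the decision
#' threshold varies over the predicted probabilities.  The AUC is
#' computed as the normalized Mann-Whitney U statistic (ties count 1/2),
#' which equals the trapezoidal area under the empirical curve.
#'
#' @param results table with `true` and `prob_positive`, or use `scores`
#'   and `labels` directly.
#' @param positive_label the patient class.
#' @param scores,labels alternative direct inputs.
#' @return List with `curve` (data.frame: threshold, fpr, tpr) and
#'   `auc`.
#' @export
roc_auc <- function(results = NULL, positive_label = NULL,
                    scores = NULL, labels = NULL) {
  if (!is.null(results)) {
    scores <- results$prob_positive
    labels <- results$true == positive_label
  } else {
    labels <- as.logical(labels)
  }
  n1 <- sum(labels); n2 <- sum(!labels)
  stopifnot(n1 >= 1, n2 >= 1)
  if (length(unique(scores)) == 1L) {
    warning("constant prediction scores: AUC is 0.5 by convention")
    auc <- 0.5
  } else {
    r <- rank(scores)
    auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(scores[labels] >= t), numeric(1)))
  list(curve = curve, auc = auc)
}

#' Target information of probabilistic predictions
#'
#' Mean information gain over a baseline that always predicts the class
#' frequencies, in bits per test case:
#' `TI = H(class frequencies) + mean(log2 q_i)` where `q_i` is the
#' probability the classifier assigned to subject i's true class and `H`
#' is the Shannon entropy of the class frequencies.  The baseline scores
#' 0; a perfectly confident, perfectly accurate classifier on balanced
#' classes scores 1.
#'
#' @param results binary CV table (`true`, `prob_positive`) or multiclass
#'   table (`prob_<class>` columns).
#' @param positive_label patient class for binary tables.
#' @return Bits per test case.
#' @export
target_information <- function(results, positive_label = NULL) {
  if ("prob_positive" %in% names(results)) {
    stopifnot(!is.null(positive_label))
    q <- ifelse(results$true == positive_label,
                results$prob_positive, 1 - results$prob_positive)
  } else {
    pcols <- grep("^prob_", names(results), value = TRUE)
    classes <- sub("^prob_", "", pcols)
    q <- vapply(seq_len(nrow(results)), function(i)
      results[[paste0("prob_", results$true[i])]][i], numeric(1))
    stopifnot(all(results$true %in% classes))
  }
  if (any(q <= 0)) {
    warning(sum(q <= 0), " zero predicted probabilities floored at ",
            "machine epsilon")
    q <- pmax(q, .Machine$double.eps)
  }
  freq <- table(results$true) / nrow(results)
  H <- -sum(freq * log2(freq))
  H + mean(log2(q))
}

#' Correlate predictive probabilities with covariates, per group
#'
#' Pearson correlation of each subject's predicted patient probability
#' with demographic/clinical covariates, computed within each diagnostic
#' group separately.
#'
#' @param results binary CV table with `subject_id` and `prob_positive`.
#' @param manifest cohort manifest with `subject_id`, `group` and the
#'   covariate columns.
#' @param covariates covariate column names.
#' @return `data.frame` with `group`, `covariate`, `n`, `r`, `p`;
#'   zero-variance covariates yield `NA` with a warning.
#' @export
probability_covariate_correlation <- function(
    results, manifest,
    covariates = c("age_years", "iq", "cprs_t", "sdq_hi")) {
  m <- merge(results, manifest, by = "subject_id", sort = FALSE)
  missing_cov <- setdiff(covariates, names(m))
  if (length(missing_cov) > 0)
    stop("covariates not in manifest: ", paste(missing_cov, collapse = ", "))
  rows <- list()
  for (g in sort(unique(m$group))) {
    sub <- m[m$group == g, ]
    for (cv in covariates) {
      x <- sub[[cv]]
      if (anyNA(x)) stop("covariate ", cv, " has missing values in ", g)
      if (sd(x) == 0 || sd(sub$prob_positive) == 0) {
        warning("zero variance for ", cv, " in group ", g,
                ": correlation undefined")
        rows[[length(rows) + 1]] <- data.frame(
          group = g, covariate = cv, n = nrow(sub),
          r = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
      } else {
        ct <- cor.test(sub$prob_positive, x, method = "pearson")
        rows[[length(rows) + 1]] <- data.frame(
          group = g, covariate = cv, n = nrow(sub),
          r = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
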