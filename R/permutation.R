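#' Permutation test of cross-validated balanced accuracy
#'
#' Permutes the diagnostic labels across the whole sample (preserving
#' group sizes), repeats the entire cross-validation procedure for each
#' permutation, and compares the observed balanced accuracy against the
#' permutation distribution.  For paired schemes the pairing is re-derived
#' after each permutation (age-rank matching on the permuted groups), so
#' every permutation runs the same procedure as the observed analysis.
#'
#' The p-value counts permutations whose accuracy is at least the
#' observed one, divided by the number of permutations, so `p = 0` is
#' representable; the positively biased but never-zero estimate
#' `(b + 1) / (m + 1)` is reported alongside.
#'
#' @param K kernel over all subjects ([linear_kernel()] result or
#'   matrix).
#' @param labels group labels.
#' @param positive_label patient class (binary designs).
#' @param scheme a [cv_scheme()]; multiclass designs always use
#'   leave-one-subject-out.
#' @param design `"binary"` or `"multiclass"`.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed; the permutation stream is fully determined by
#'   it.
#' @param age optional ages for pair matching.
#' @param center mean-center kernels within training folds.
#' @param ... further arguments passed to the CV drivers.
#' @return Object of class `permutation_result`: `observed`, `permuted`
#'   (length `n_perm`), `p_value`, `p_value_smoothed`, `seed`.
#' @export
permutation_test <- function(K, labels, positive_label = NULL,
                             scheme = cv_scheme("leave-one-subject"),
                             design = c("binary", "multiclass"),
                             n_perm = 1000L, seed = 1L, age = NULL,
                             center = TRUE, ...) {
  design <- match.arg(design)
  stopifnot(n_perm >= 1)
  labels <- as.character(labels)
  stat <- function(lab) {
    if (design == "binary") {
      res <- loo_cv_binary(K, lab, positive_label, scheme = scheme,
                           age = age, center = center, ...)
      confusion_metrics(res, positive_label)$balanced_accuracy
    } else {
      res <- loo_cv_multiclass(K, lab, center = center, ...)
      multiclass_metrics(res)$balanced_accuracy
    }
  }
  observed <- stat(labels)
  permuted <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(b) stat(sample(labels)), numeric(1))
  })
  structure(
    list(observed = observed, permuted = permuted,
         p_value = mean(permuted >= observed),
         p_value_smoothed = (sum(permuted >= observed) + 1) / (n_perm + 1),
         n_perm = n_perm, seed = seed, design = design),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation test (%s): observed balanced accuracy %.1f%%\n%d permutations: p = %.4g (smoothed %.4g)\n",
    x$design, x$observed, x$n_perm, x$p_value, x$p_value_smoothed))
  invisible(x)
}
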