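#' Linear kernel matrix over subjects
#'
#' `K = scale * X X' + bias` over the rows of a pattern matrix.  For a
#' linear kernel, computing K once on the full cohort and slicing
#' train/test blocks per cross-validation fold is mathematically identical
#' to recomputing it per fold, so all cross-validation in the package
#' slices this one matrix.
#'
#' @param patterns a [pattern_matrix()] or a numeric subjects-by-features
#'   matrix.
#' @param scale kernel scale (> 0).
#' @param bias constant offset added to every entry (>= 0).
#' @param normalize if `TRUE`, divide by the mean diagonal (after scaling)
#'   so the average self-similarity is 1; a pure conditioning choice that
#'   leaves the classifier's decision structure intact.
#' @return Object of class `kernel_matrix`: `values` (n x n), and
#'   provenance flags `centered`, `scaled`.
#' @export
linear_kernel <- function(patterns, scale = 1, bias = 0, normalize = FALSE) {
  X <- if (inherits(patterns, "pattern_matrix")) patterns$values else patterns
  stopifnot(is.matrix(X), nrow(X) >= 2, scale > 0, bias >= 0)
  if (!all(is.finite(X))) stop("pattern matrix contains non-finite entries")
  K <- scale * tcrossprod(X) + bias
  if (normalize) K <- K / mean(diag(K))
  K <- (K + t(K)) / 2  # exact symmetry against rounding
  structure(list(values = K, centered = FALSE, scaled = normalize),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat("<kernel_matrix> ", nrow(x$values), " x ", ncol(x$values),
      if (x$centered) ", centered", if (x$scaled) ", scaled", "\n", sep = "")
  invisible(x)
}

# Center a kernel in feature space with respect to a training subset.
# For K = X X', feature centering X - 1 m' (m = training feature mean)
# gives Ktilde[i,j] = K[i,j] - r_i - r_j + rbar with r_i the mean of
# K[i, train] and rbar the training-block mean.  Applying the same map to
# every row keeps train and test blocks consistent.
center_kernel <- function(K, train_idx = seq_len(nrow(K))) {
  r <- rowMeans(K[, train_idx, drop = FALSE])
  rbar <- mean(K[train_idx, train_idx])
  Kc <- K - outer(r, rep(1, ncol(K))) - outer(rep(1, nrow(K)), r) + rbar
  (Kc + t(Kc)) / 2
}

kernel_values <- function(K) {
  if (inherits(K, "kernel_matrix")) K$values else K
}
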