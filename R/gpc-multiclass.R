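#' Fit a multiclass Gaussian process classifier (Laplace approximation)
#'
#' Softmax (multinomial logistic) likelihood over C latent functions with
#' a shared kernel, approximated by a Gaussian centered at the posterior
#' mode.  The mode is found by Newton iterations exploiting the
#' block structure of the softmax Hessian; convergence is declared when
#' the gradient of the log posterior at the current iterate falls below
#' `tol` in max-norm.
#'
#' @param K a [linear_kernel()] result or n x n PSD matrix, shared across
#'   classes.
#' @param y class labels (factor or character), at least 3 classes, every
#'   class present; or an n x C one-hot matrix with column names.
#' @param tol convergence tolerance on the gradient max-norm.
#' @param max_iter maximum Newton iterations.
#' @return Object of class `gp_multiclass_posterior`: latent mode `f_hat`
#'   (n x C), fitted class probabilities `pi_hat`, dual coefficients
#'   `a` (= Y - pi_hat at the mode), per-class `E` matrices and the
#'   cross-class factor `M` needed for prediction, class names, the
#'   Laplace log marginal likelihood, and an iteration trace.
#' @export
fit_gpc_multiclass_laplace <- function(K, y, tol = 1e-6, max_iter = 50L) {
  Kv <- kernel_values(K)
  n <- nrow(Kv)
  if (is.matrix(y)) {
    Y <- y
    classes <- colnames(Y)
    if (is.null(classes)) classes <- paste0("class", seq_len(ncol(Y)))
  } else {
    classes <- sort(unique(as.character(y)))
    Y <- outer(as.character(y), classes, `==`) * 1
    colnames(Y) <- classes
  }
  C <- length(classes)
  if (C < 3) stop("multiclass classifier requires >= 3 classes; use the ",
                  "binary EP classifier for 2")
  if (any(colSums(Y) == 0)) stop("every class must be present in training")
  if (nrow(Y) != n) stop("label rows do not match kernel size")

  f <- matrix(0, n, C)
  trace <- numeric(0)
  converged <- FALSE
  a <- matrix(0, n, C)
  E <- vector("list", C)
  Mchol <- NULL
  logdet_sum <- 0
  for (iter in seq_len(max_iter)) {
    fmax <- apply(f, 1, max)
    P <- exp(f - fmax)
    P <- P / rowSums(P)
    grad <- Y - P  # gradient of the log likelihood wrt f
    # Newton step in the whitened system, one Cholesky per class:
    # E_c = sqrt(D_c) (I + sqrt(D_c) K sqrt(D_c))^{-1} sqrt(D_c)
    logdet_sum <- 0
    Esum <- matrix(0, n, n)
    for (cc in seq_len(C)) {
      sqrtD <- sqrt(P[, cc])
      Bc <- diag(n) + (sqrtD %o% sqrtD) * Kv
      Lc <- t(chol(Bc))
      logdet_sum <- logdet_sum + sum(log(diag(Lc)))
      E[[cc]] <- sqrtD * backsolve(t(Lc), forwardsolve(Lc, diag(sqrtD, n)))
      Esum <- Esum + E[[cc]]
    }
    Mchol <- t(chol(Esum))
    # b = W f + grad with W = D - Pi Pi'
    Pf <- rowSums(P * f)
    b <- P * f - P * Pf + grad
    cvec <- matrix(0, n, C)
    for (cc in seq_len(C)) cvec[, cc] <- E[[cc]] %*% (Kv %*% b[, cc])
    s <- rowSums(cvec)
    tt <- backsolve(t(Mchol), forwardsolve(Mchol, s))
    for (cc in seq_len(C)) a[, cc] <- b[, cc] - cvec[, cc] + E[[cc]] %*% tt
    f_new <- Kv %*% a
    f <- f_new
    # gradient of log posterior at the new mode candidate: (Y - pi) - a
    fmax <- apply(f, 1, max)
    P <- exp(f - fmax)
    P <- P / rowSums(P)
    gnorm <- max(abs((Y - P) - a))
    trace <- c(trace, gnorm)
    if (gnorm < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("multiclass Laplace Newton iterations did not converge in ",
         max_iter, " iterations; gradient trace: ",
         paste(format(trace, digits = 3), collapse = ", "))
  # refresh the Hessian factors at the converged mode (the loop computed
  # them at the previous iterate)
  logdet_sum <- 0
  Esum <- matrix(0, n, n)
  for (cc in seq_len(C)) {
    sqrtD <- sqrt(P[, cc])
    Bc <- diag(n) + (sqrtD %o% sqrtD) * Kv
    Lc <- t(chol(Bc))
    logdet_sum <- logdet_sum + sum(log(diag(Lc)))
    E[[cc]] <- sqrtD * backsolve(t(Lc), forwardsolve(Lc, diag(sqrtD, n)))
    Esum <- Esum + E[[cc]]
  }
  Mchol <- t(chol(Esum))
  loglik <- sum(Y * f) - sum(log(rowSums(exp(f - apply(f, 1, max)))) +
                               apply(f, 1, max))
  # log|I + K_blk W| factorizes as sum_c log|B_c| + log|sum_c E_c|; the
  # second piece comes from the Cholesky of the cross-class factor M
  lml <- -0.5 * sum(a * f) + loglik - logdet_sum -
    sum(log(diag(Mchol)))
  structure(
    list(f_hat = f, pi_hat = P, a = a, Y = Y, classes = classes,
         E = E, Mchol = Mchol, K = Kv, lml = lml,
         iterations = length(trace), trace = trace, converged = converged),
    class = "gp_multiclass_posterior"
  )
}

#' @export
print.gp_multiclass_posterior <- function(x, ...) {
  cat("<gp_multiclass_posterior> n =", nrow(x$f_hat), "| classes:",
      paste(x$classes, collapse = ", "), "| Newton iterations:",
      x$iterations, "\n")
  invisible(x)
}

#' Multiclass predictive class probabilities
#'
#' Latent predictive mean and cross-class covariance follow from the
#' Laplace mode; the softmax expectation over the latent predictive
#' Gaussian has no closed form, so it is evaluated by fixed-seed
#' Monte Carlo (default 10,000 draws), making predictions reproducible.
#'
#' @param post a [fit_gpc_multiclass_laplace()] posterior.
#' @param k_star length-n vector (or n x m matrix) of train-test kernel
#'   values, shared across classes.
#' @param k_star_star test self-covariance(s), length m.
#' @param n_draws Monte Carlo draws over the latent predictive Gaussian.
#' @param seed RNG seed for the draws.
#' @return m x C matrix of class probabilities; rows sum to 1.
#' @export
predict_gpc_multiclass <- function(post, k_star, k_star_star,
                                   n_draws = 10000L, seed = 1L) {
  stopifnot(inherits(post, "gp_multiclass_posterior"))
  Ks <- if (is.matrix(k_star)) k_star else matrix(k_star, ncol = 1)
  n <- nrow(post$f_hat); C <- length(post$classes)
  if (nrow(Ks) != n) stop("k_star must have one row per training subject")
  m <- ncol(Ks)
  kss <- rep_len(as.numeric(k_star_star), m)
  out <- matrix(NA_real_, m, C, dimnames = list(NULL, post$classes))
  grad <- post$Y - post$pi_hat
  with_local_seed(seed, {
    Z <- matrix(rnorm(n_draws * C), n_draws, C)
    for (j in seq_len(m)) {
      ks <- Ks[, j]
      mu <- as.numeric(crossprod(grad, ks))
      Sig <- matrix(0, C, C)
      bvec <- matrix(0, n, C)
      for (cc in seq_len(C)) bvec[, cc] <- post$E[[cc]] %*% ks
      Minv_b <- apply(bvec, 2, function(bc)
        backsolve(t(post$Mchol), forwardsolve(post$Mchol, bc)))
      for (cc in seq_len(C)) {
        for (dd in seq_len(C)) {
          Sig[cc, dd] <- crossprod(bvec[, cc], Minv_b[, dd])
        }
        Sig[cc, cc] <- Sig[cc, cc] + kss[j] - sum(ks * bvec[, cc])
      }
      Sig <- (Sig + t(Sig)) / 2
      ee <- eigen(Sig, symmetric = TRUE)
      rot <- ee$vectors %*% (sqrt(pmax(ee$values, 0)) * t(ee$vectors))
      F <- Z %*% rot + matrix(mu, n_draws, C, byrow = TRUE)
      Fmax <- apply(F, 1, max)
      Pm <- exp(F - Fmax)
      Pm <- Pm / rowSums(Pm)
      out[j, ] <- colMeans(Pm)
    }
  })
  out / rowSums(out)
}
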