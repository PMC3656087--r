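#' Fit a binary Gaussian process classifier by expectation propagation
#'
#' Zero-mean GP prior with the supplied kernel and a probit (cumulative
#' Gaussian) likelihood.  Expectation propagation iterates moment-matching
#' site updates until the largest change in any site parameter falls below
#' `tol`; updates are damped for stability on near-separable problems.
#' The approximate posterior is summarized by nonnegative site precisions
#' and site natural means, from which all predictive quantities and the EP
#' approximation to the log marginal likelihood are reproducible.
#'
#' @param K a [linear_kernel()] result or an n x n PSD matrix.
#' @param y labels: a numeric +1/-1 vector, or any vector with exactly two
#'   levels together with `positive_label`.
#' @param positive_label which label maps to +1 (by convention the
#'   patient class); defaults to the first of `sort(unique(y))` for
#'   non-numeric labels.
#' @param tol convergence tolerance on the maximum site-parameter change.
#' @param max_sweeps maximum EP sweeps over all sites.
#' @param damping multiplicative damping of site updates in (0, 1].
#' @return Object of class `gp_binary_posterior` with site parameters
#'   (`tau_site`, `nu_site`), dual coefficients `alpha`, Cholesky factor
#'   `L` of `I + S^1/2 K S^1/2`, `sW`, labels `y_pm`, the EP log marginal
#'   likelihood `lml`, and convergence diagnostics.
#' @export
fit_gpc_binary_ep <- function(K, y, positive_label = NULL,
                              tol = 1e-6, max_sweeps = 100L, damping = 0.8) {
  Kv <- kernel_values(K)
  stopifnot(is.matrix(Kv), nrow(Kv) == ncol(Kv))
  if (!all(is.finite(Kv))) stop("kernel matrix contains non-finite entries")
  if (max(abs(Kv - t(Kv))) > 1e-10) stop("kernel matrix is not symmetric")
  if (is.numeric(y) && all(y %in% c(-1, 1))) {
    y_pm <- as.numeric(y)
    if (is.null(positive_label)) positive_label <- "+1"
  } else {
    lev <- sort(unique(as.character(y)))
    if (length(lev) != 2) stop("need exactly two classes, got ", length(lev))
    if (is.null(positive_label)) positive_label <- lev[1]
    if (!positive_label %in% lev)
      stop("positive_label '", positive_label, "' not among labels")
    y_pm <- ifelse(as.character(y) == positive_label, 1, -1)
  }
  if (length(unique(y_pm)) < 2)
    stop("single-class training labels: both classes must be present")
  if (length(y_pm) != nrow(Kv)) stop("label length does not match kernel")

  fit <- ep_probit_fit(Kv, y_pm, tol, as.integer(max_sweeps), damping)
  if (!fit$converged)
    stop("EP did not converge in ", max_sweeps,
         " sweeps (last max site-parameter change ",
         format(fit$max_delta, digits = 4), ")")
  structure(
    list(tau_site = as.numeric(fit$tau_site),
         nu_site = as.numeric(fit$nu_site),
         alpha = as.numeric(fit$alpha),
         L = fit$L, sW = as.numeric(fit$sW),
         y_pm = y_pm, positive_label = positive_label,
         K = Kv, lml = fit$lml,
         sweeps = fit$sweeps, max_delta = fit$max_delta,
         converged = fit$converged),
    class = "gp_binary_posterior"
  )
}

#' @export
print.gp_binary_posterior <- function(x, ...) {
  cat("<gp_binary_posterior> n =", length(x$y_pm),
      "| EP converged in", x$sweeps, "sweeps | log evidence",
      format(x$lml, digits = 6), "\n")
  invisible(x)
}

#' Predictive probability of the positive class
#'
#' Integrates the probit likelihood against the latent predictive
#' Gaussian: `p = Phi(mu* / sqrt(1 + var*))`.  Negative predictive
#' variances arising from rounding are clamped at zero with a warning.
#'
#' @param post a [fit_gpc_binary_ep()] posterior.
#' @param k_star train-test kernel values: length-n vector for one test
#'   point or an n x m matrix for m points.
#' @param k_star_star test self-covariances (length m).
#' @return Numeric vector of probabilities, strictly inside (0, 1).
#' @export
predict_gpc_binary <- function(post, k_star, k_star_star) {
  stopifnot(inherits(post, "gp_binary_posterior"))
  Ks <- if (is.matrix(k_star)) k_star else matrix(k_star, ncol = 1)
  if (nrow(Ks) != length(post$y_pm))
    stop("k_star must have one row per training subject")
  kss <- rep_len(as.numeric(k_star_star), ncol(Ks))
  pr <- ep_probit_predict(post$L, post$sW, post$alpha, Ks, kss)
  if (pr$n_clamped > 0)
    warning(pr$n_clamped, " negative predictive variance(s) clamped at 0")
  eps <- .Machine$double.eps
  pmin(pmax(as.numeric(pr$prob), eps), 1 - eps)
}

# Latent predictive mean at arbitrary points (used by the representer
# identity between kernel-space and voxel-space computations).
latent_mean_gpc_binary <- function(post, k_star) {
  Ks <- if (is.matrix(k_star)) k_star else matrix(k_star, ncol = 1)
  as.numeric(crossprod(Ks, post$alpha))
}

#' Serialize / restore a fitted posterior
#'
#' Stores every field needed to reproduce predictions (site parameters,
#' Cholesky factors, labels, kernel) in a single RDS archive.
#'
#' @param post a fitted posterior (binary or multiclass).
#' @param path archive path.
#' @return `path` (write) or the restored posterior (read).
#' @export
write_posterior <- function(post, path) {
  saveRDS(post, path)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) readRDS(path)
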