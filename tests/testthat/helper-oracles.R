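# Independent oracles and small fixture builders used across the suite.

# Gauss-Hermite rule by the Golub-Welsch eigenvalue method.
gh_rule <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# Exact (to quadrature accuracy) posterior predictive probability of the
# positive class for a probit GP: tensor-product Gauss-Hermite over the
# n-dimensional latent prior, independent of the EP implementation.
quadrature_predict <- function(K, y, k_star, k_star_star, n_nodes = 25) {
  n <- length(y)
  q <- gh_rule(n_nodes)
  Lk <- t(chol(K + 1e-12 * diag(n)))
  grid <- as.matrix(expand.grid(rep(list(seq_len(n_nodes)), n)))
  W <- apply(matrix(q$w[grid], nrow(grid), n), 1, prod)
  F <- sqrt(2) * matrix(q$x[grid], nrow(grid), n) %*% t(Lk)
  lik <- apply(pnorm(F * matrix(y, nrow(grid), n, byrow = TRUE)), 1, prod)
  Kinv_ks <- solve(K + 1e-12 * diag(n), k_star)
  mu_c <- F %*% Kinv_ks
  s2_c <- k_star_star - sum(k_star * Kinv_ks)
  sum(W * lik * pnorm(mu_c / sqrt(1 + s2_c))) / sum(W * lik)
}

# Brute-force pairwise AUC: P(score_pos > score_neg) + 0.5 P(equal).
pairwise_auc <- function(scores, is_pos) {
  sp <- scores[is_pos]
  sn <- scores[!is_pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# A tiny, fast cohort spec for pipeline-level tests.
tiny_spec <- function(seed = 1L, effects = NULL,
                      group_sizes = c(ADHD = 8L, control = 8L, ASD = 5L),
                      shape = c(16L, 16L, 16L), noise_sd = 0.4) {
  if (is.null(effects)) {
    effects <- if (all(shape >= 16))
      list(effect_blob(c(7, 8, 7), 8, -0.25, "ADHD"),
           effect_blob(c(10, 9, 10), 8, -0.25, "ASD"))
    else list()
  }
  cohort_spec(group_sizes = group_sizes, image_shape = shape,
              voxel_size_mm = 4, smoothing_fwhm_mm = 8,
              subject_noise_sd = noise_sd, effects = effects, seed = seed)
}

# Linearly separable Gaussian-cluster pattern rows (one cluster per
# class), for classifier recovery tests without the imaging stack.
cluster_patterns <- function(n_per_class, n_feat = 12, sep = 6, seed = 1) {
  set.seed(seed)
  C <- length(n_per_class)
  centers <- matrix(0, C, n_feat)
  for (cc in seq_len(C)) centers[cc, cc] <- sep
  X <- do.call(rbind, lapply(seq_len(C), function(cc) {
    matrix(rnorm(n_per_class[cc] * n_feat), n_per_class[cc], n_feat) +
      matrix(centers[cc, ], n_per_class[cc], n_feat, byrow = TRUE)
  }))
  labels <- rep(names(n_per_class), times = n_per_class)
  list(X = X, labels = labels)
}
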