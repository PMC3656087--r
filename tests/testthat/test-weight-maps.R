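# Minimal pattern_matrix over a full grid for weight-map tests.
flat_patterns <- function(X, shape) {
  vols <- lapply(seq_len(nrow(X)), function(i)
    brain_volume(array(X[i, ], shape)))
  mask <- build_mask(vols, threshold = -Inf, min_fraction = 1)
  pattern_matrix(vols, mask)
}

test_that("two orthonormal opposite-label points give w along their difference", {
  X <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  pats <- flat_patterns(X, c(4, 1, 1))
  post <- fit_gpc_binary_ep(tcrossprod(X), c(1, -1), positive_label = "+1")
  wm <- compute_weight_vector(post, pats, centered = FALSE)
  dir <- X[1, ] - X[2, ]
  cosine <- sum(wm$weights * dir) / sqrt(sum(wm$weights^2) * sum(dir^2))
  expect_gt(cosine, 0.999)
})

test_that("representer identity: latent means from w equal kernel-space means", {
  set.seed(61)
  X <- matrix(rnorm(10 * 25), 10, 25)
  shape <- c(5, 5, 1)
  pats <- flat_patterns(X, c(5, 5, 1))
  y <- rep(c("pat", "ctl"), each = 5)
  Kc <- neurogpc:::center_kernel(tcrossprod(X))
  post <- fit_gpc_binary_ep(Kc, y, positive_label = "pat")
  wm <- compute_weight_vector(post, pats, centered = TRUE)
  f_kernel <- neurogpc:::latent_mean_gpc_binary(post, Kc)
  Xc <- sweep(X, 2, colMeans(X))
  f_voxel <- as.numeric(Xc %*% wm$weights)
  expect_lt(max(abs(f_kernel - f_voxel)), 1e-8)
})

test_that("a constant image offset leaves the centered-kernel weight direction unchanged", {
  set.seed(62)
  X <- matrix(rnorm(8 * 16), 8, 16)
  y <- rep(c("pat", "ctl"), 4)
  w_of <- function(Xi) {
    pats <- flat_patterns(Xi, c(4, 4, 1))
    post <- fit_gpc_binary_ep(neurogpc:::center_kernel(tcrossprod(Xi)),
                              y, positive_label = "pat")
    compute_weight_vector(post, pats, centered = TRUE)$weights
  }
  w1 <- w_of(X)
  w2 <- w_of(X + 5)
  cosine <- sum(w1 * w2) / sqrt(sum(w1^2) * sum(w2^2))
  expect_gt(cosine, 0.9999)
})

test_that("thresholding retains voxels by fraction of the pooled maximum |w|", {
  w <- c(1.0, 0.5, 0.39, -0.8, -0.2)
  vols <- list(brain_volume(array(1, c(5, 1, 1))))
  mask <- build_mask(vols, 0, 1)
  map <- structure(list(weights = w, volume = unvectorize(w, mask),
                        mask = mask, positive_class = "pat",
                        threshold_fraction = 0), class = "weight_map")
  thr <- threshold_weight_map(map, 0.4)
  expect_equal(thr$weights, c(1.0, 0.5, 0, -0.8, 0))
  expect_equal(threshold_weight_map(map, 0)$weights, w)
  expect_equal(threshold_weight_map(map, 1)$weights, c(1, 0, 0, 0, 0))
  # per-sign variant keeps each sign's own scale
  ps <- threshold_weight_map(map, 0.4, per_sign = TRUE)
  expect_equal(ps$weights, c(1.0, 0.5, 0, -0.8, -0.2 * 0))
  # round-trip through the rendered volume is exact
  again <- thr$volume$data[mask$indices]
  expect_identical(unname(again), thr$weights)
})

test_that("weight maps recover an injected discriminative blob", {
  spec <- tiny_spec(seed = 71L,
                    effects = list(effect_blob(c(7, 8, 7), 9, -0.3, "ADHD")),
                    group_sizes = c(ADHD = 12L, control = 12L))
  cohort <- generate_cohort(spec)
  mask <- build_mask(cohort$volumes)
  pats <- pattern_matrix(cohort$volumes, mask,
                         subject_ids = cohort$manifest$subject_id)
  K <- linear_kernel(pats, normalize = TRUE)
  Kc <- neurogpc:::center_kernel(K$values)
  post <- fit_gpc_binary_ep(Kc, cohort$manifest$group, "ADHD")
  wm <- compute_weight_vector(post, pats)
  # true blob voxels within the mask
  co <- arrayInd(mask$indices, dim(mask$data))
  d2 <- colSums((t(co) - c(7, 8, 7))^2) * spec$voxel_size_mm^2
  blob <- d2 <= 9^2
  k <- sum(blob)
  top <- order(abs(wm$weights), decreasing = TRUE)[seq_len(k)]
  overlap <- sum(top %in% which(blob))
  # hypergeometric chance level for drawing k of V with k marked
  p_hyper <- phyper(overlap - 1, k, length(blob) - k, k, lower.tail = FALSE)
  expect_lt(p_hyper, 0.01)
  # ADHD has reduced volume there, so blob weights point away from ADHD
  expect_lt(median(wm$weights[blob]), 0)
})

test_that("multiclass weight maps localize class effects and permute with labels", {
  spec <- tiny_spec(seed = 72L,
                    group_sizes = c(ADHD = 10L, control = 10L, ASD = 10L))
  cohort <- generate_cohort(spec)
  mask <- build_mask(cohort$volumes)
  pats <- pattern_matrix(cohort$volumes, mask)
  Kc <- neurogpc:::center_kernel(linear_kernel(pats, normalize = TRUE)$values)
  post <- fit_gpc_multiclass_laplace(Kc, cohort$manifest$group)
  maps <- multiclass_weight_maps(post, pats)
  expect_named(maps, c("ADHD", "ASD", "control"))
  co <- arrayInd(mask$indices, dim(mask$data))
  in_blob <- function(center, r) {
    colSums((t(co) - center)^2) * spec$voxel_size_mm^2 <= r^2
  }
  adhd_blob <- in_blob(c(7, 8, 7), 8)
  k <- sum(adhd_blob)
  top_adhd <- order(abs(maps$ADHD$weights), decreasing = TRUE)[seq_len(k)]
  expect_lt(phyper(sum(top_adhd %in% which(adhd_blob)) - 1, k,
                   length(adhd_blob) - k, k, lower.tail = FALSE), 0.01)
  # control has no injected effect: its map should be weakest
  expect_lt(max(abs(maps$control$weights)),
            max(abs(maps$ADHD$weights)))
  # relabeling classes permutes maps exactly
  relab <- c(ADHD = "ASD", ASD = "control", control = "ADHD")[
    cohort$manifest$group]
  post2 <- fit_gpc_multiclass_laplace(Kc, relab)
  maps2 <- multiclass_weight_maps(post2, pats)
  expect_equal(maps2$ASD$weights, maps$ADHD$weights, tolerance = 1e-6)
})
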