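grid_patterns <- function(X, shape) {
  vols <- lapply(seq_len(nrow(X)), function(i)
    brain_volume(array(X[i, ], shape)))
  mask <- build_mask(vols, threshold = -Inf, min_fraction = 1)
  pattern_matrix(vols, mask)
}

test_that("voxel-wise t matches the textbook pooled-variance formula", {
  # one voxel, groups (1,2,3) vs (4,5,6): t = -3.674, df = 4
  X <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  pats <- grid_patterns(cbind(X, X), c(2, 1, 1))
  tm <- voxelwise_ttest(pats, rep(c("g1", "g2"), each = 3),
                        groups = c("g1", "g2"))
  expect_equal(tm$df, 4L)
  expect_equal(unname(tm$t[1]), -3.674, tolerance = 5e-4)
  # cross-check against stats::t.test at full precision
  tt <- t.test(X[1:3], X[4:6], var.equal = TRUE)
  expect_equal(unname(tm$t[1]), unname(tt$statistic), tolerance = 1e-12)
})

test_that("swapping group labels negates the t map exactly", {
  set.seed(81)
  X <- matrix(rnorm(10 * 27), 10, 27)
  pats <- grid_patterns(X, c(3, 3, 3))
  lab <- rep(c("a", "b"), each = 5)
  t1 <- voxelwise_ttest(pats, lab, groups = c("a", "b"))$t
  t2 <- voxelwise_ttest(pats, lab, groups = c("b", "a"))$t
  expect_equal(t1, -t2, tolerance = 1e-12)
})

test_that("zero-variance voxels are masked out and counted", {
  set.seed(82)
  X <- matrix(rnorm(8 * 8), 8, 8)
  X[, 3] <- 1  # constant in both groups
  pats <- grid_patterns(X, c(2, 2, 2))
  tm <- voxelwise_ttest(pats, rep(c("a", "b"), 4))
  expect_equal(tm$n_zero_variance, 1L)
  expect_true(is.na(tm$t[3]))
  expect_equal(tm$volume$data[3], 0)
})

test_that("connectivity: a single isolated suprathreshold voxel forms one cluster of extent 1", {
  set.seed(83)
  n <- 12
  X <- matrix(rnorm(n * 64, sd = 0.05), n, 64)
  # one voxel with a huge group difference, far from everything
  X[1:6, 22] <- X[1:6, 22] + 10
  pats <- grid_patterns(X, c(4, 4, 4))
  ct <- cluster_inference(pats, rep(c("a", "b"), each = 6),
                          groups = c("a", "b"),
                          cluster_forming_p = 0.001, n_perm = 50, seed = 1)
  expect_equal(nrow(ct$clusters), 1)
  expect_equal(ct$clusters$extent_voxels, 1L)
  expect_equal(ct$clusters$direction, "positive")
  expect_lt(ct$clusters$p_fwe, 0.05)
})

test_that("26-connectivity merges diagonal neighbors", {
  dims <- c(4, 4, 4)
  # voxels (1,1,1) and (2,2,2) touch diagonally; (4,4,4) is isolated
  idx <- c(1L,
           1L + 1L + 1L * 4L + 1L * 16L,
           64L)
  memb <- neurogpc:::connected_components_26(idx, dims)
  expect_equal(memb[1], memb[2])
  expect_false(memb[3] == memb[1])
})

test_that("cluster count and extents shrink as the forming threshold tightens", {
  spec <- tiny_spec(seed = 84L,
                    effects = list(effect_blob(c(8, 8, 8), 12, -0.3, "ADHD")),
                    group_sizes = c(ADHD = 14L, control = 14L))
  cohort <- generate_cohort(spec)
  pats <- pattern_matrix(cohort$volumes, build_mask(cohort$volumes))
  lab <- cohort$manifest$group
  ct_loose <- cluster_inference(pats, lab, groups = c("control", "ADHD"),
                                cluster_forming_p = 0.01, n_perm = 20,
                                seed = 2)
  ct_tight <- cluster_inference(pats, lab, groups = c("control", "ADHD"),
                                cluster_forming_p = 0.0005, n_perm = 20,
                                seed = 2)
  expect_lte(sum(ct_tight$clusters$extent_voxels),
             sum(ct_loose$clusters$extent_voxels))
  expect_lte(max(ct_tight$clusters$extent_voxels, 0),
             max(ct_loose$clusters$extent_voxels, 0))
})

test_that("an injected blob is detected as a significant cluster overlapping it", {
  spec <- tiny_spec(seed = 85L,
                    effects = list(effect_blob(c(8, 8, 8), 12, -0.3, "ADHD")),
                    group_sizes = c(ADHD = 16L, control = 16L))
  cohort <- generate_cohort(spec)
  mask <- build_mask(cohort$volumes)
  pats <- pattern_matrix(cohort$volumes, mask)
  ct <- cluster_inference(pats, cohort$manifest$group,
                          groups = c("control", "ADHD"),
                          cluster_forming_p = 0.001, n_perm = 99, seed = 3)
  sig <- ct$clusters$p_fwe < 0.05
  expect_true(any(sig))
  # Dice between the largest significant cluster and the true blob
  co <- arrayInd(mask$indices, dim(mask$data))
  blob <- which(colSums((t(co) - c(8, 8, 8))^2) * 16 <= 144)
  best <- ct$cluster_voxels[[which(sig)[1]]]
  dice <- 2 * length(intersect(best, blob)) / (length(best) + length(blob))
  expect_gt(dice, 0.3)
  # the permutation null is reproducible under the same seed
  ct2 <- cluster_inference(pats, cohort$manifest$group,
                           groups = c("control", "ADHD"),
                           cluster_forming_p = 0.001, n_perm = 99, seed = 3)
  expect_identical(ct$max_extent_null, ct2$max_extent_null)
})

test_that("no suprathreshold voxels yields an empty table, not an error", {
  set.seed(86)
  X <- matrix(rnorm(8 * 27, sd = 1), 8, 27)
  pats <- grid_patterns(X, c(3, 3, 3))
  ct <- cluster_inference(pats, rep(c("a", "b"), 4),
                          cluster_forming_p = 1e-6, n_perm = 10, seed = 1)
  expect_equal(nrow(ct$clusters), 0)
})

test_that("global volume comparisons match direct t-tests and flag missing data", {
  set.seed(87)
  man <- data.frame(subject_id = sprintf("s%d", 1:6),
                    group = rep(c("ctl", "pat"), each = 3),
                    GM_ml = c(790, 800, 780, 750, 745, 752),
                    WM_ml = rnorm(6, 500, 20),
                    CSF_ml = rnorm(6, 330, 15))
  man$TIV_ml <- man$GM_ml + man$WM_ml + man$CSF_ml
  tab <- global_volume_ttests(man, groups = c("ctl", "pat"))
  ref <- t.test(man$GM_ml[1:3], man$GM_ml[4:6], var.equal = TRUE)
  expect_equal(tab$t[tab$measure == "GM_ml"], unname(ref$statistic),
               tolerance = 1e-12)
  expect_equal(tab$p[tab$measure == "GM_ml"], ref$p.value, tolerance = 1e-12)
  expect_equal(tab$df, rep(4, 4))
  man$WM_ml[2] <- NA
  expect_warning(tab2 <- global_volume_ttests(man, groups = c("ctl", "pat")),
                 "missing WM_ml for subject\\(s\\): s2")
  expect_equal(tab2$df[tab2$measure == "WM_ml"], 3)
})

test_that("null voxel-wise p-values are calibrated", {
  # no effect: the fraction of voxels exceeding the p<0.001 two-sided
  # threshold matches the nominal rate across replicates
  set.seed(88)
  exceed <- 0; total <- 0
  for (r in 1:30) {
    X <- matrix(rnorm(12 * 125), 12, 125)
    pats <- grid_patterns(X, c(5, 5, 5))
    tm <- voxelwise_ttest(pats, rep(c("a", "b"), each = 6))
    tc <- qt(1 - 0.001 / 2, tm$df)
    exceed <- exceed + sum(abs(tm$t) > tc)
    total <- total + length(tm$t)
  }
  expect_lt(abs(exceed / total - 0.001), 3 * sqrt(0.001 / total))
})
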