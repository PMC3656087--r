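#' Voxel-wise two-sample t-test over a pattern matrix
#'
#' Pooled-variance two-sample t statistic per masked voxel for the
#' contrast `groups[1] - groups[2]`, the conventional mass-univariate
#' VBM comparison.  Voxels with zero pooled variance have an undefined
#' statistic; they are removed from the statistic map and counted.
#'
#' @param patterns a [pattern_matrix()].
#' @param group_labels length-n group labels (exactly two groups used).
#' @param groups optional length-2 character vector selecting and
#'   ordering the contrast; defaults to the sorted labels.
#' @return Object of class `t_map`: per-voxel `t` (NA where undefined),
#'   `df`, `contrast`, group sizes, `n_zero_variance`, the `mask`, and
#'   the statistic rendered as a [brain_volume()] (`volume`).
#' @export
voxelwise_ttest <- function(patterns, group_labels, groups = NULL) {
  stopifnot(inherits(patterns, "pattern_matrix"))
  group_labels <- as.character(group_labels)
  if (is.null(groups)) groups <- sort(unique(group_labels))
  stopifnot(length(groups) == 2)
  i1 <- which(group_labels == groups[1])
  i2 <- which(group_labels == groups[2])
  if (length(i1) < 2 || length(i2) < 2)
    stop("each group needs n >= 2 for a two-sample t-test")
  X <- patterns$values
  t_stat <- pooled_t(X[i1, , drop = FALSE], X[i2, , drop = FALSE])
  nzv <- sum(!is.finite(t_stat))
  t_stat[!is.finite(t_stat)] <- NA_real_
  tv <- t_stat
  tv[is.na(tv)] <- 0
  structure(
    list(t = t_stat, df = length(i1) + length(i2) - 2L,
         contrast = paste(groups[1], ">", groups[2]),
         n1 = length(i1), n2 = length(i2), n_zero_variance = nzv,
         mask = patterns$mask, volume = unvectorize(tv, patterns$mask)),
    class = "t_map"
  )
}

# Vectorized pooled-variance two-sample t over the columns of X1/X2.
pooled_t <- function(X1, X2) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  ss1 <- colSums(X1^2) - n1 * m1^2
  ss2 <- colSums(X2^2) - n2 * m2^2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  out <- (m1 - m2) / se
  out[se == 0] <- NA_real_
  out
}

#' @export
print.t_map <- function(x, ...) {
  cat("<t_map> contrast", x$contrast, "| df =", x$df,
      "| t range [", format(min(x$t, na.rm = TRUE), digits = 3), ",",
      format(max(x$t, na.rm = TRUE), digits = 3), "]\n")
  invisible(x)
}

# Connected components of a voxel set under 26-connectivity.  `idx` are
# linear indices into an array of dimension `dims`; returns an integer
# component label per voxel.
connected_components_26 <- function(idx, dims) {
  nv <- length(idx)
  if (nv == 0) return(integer(0))
  if (nv == 1) return(1L)
  co <- arrayInd(idx, dims)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  # keep lexicographically positive half to avoid duplicate edges
  half <- offsets[offsets[, 3] > 0 |
                    (offsets[, 3] == 0 & offsets[, 2] > 0) |
                    (offsets[, 3] == 0 & offsets[, 2] == 0 &
                       offsets[, 1] > 0), , drop = FALSE]
  edges <- NULL
  for (r in seq_len(nrow(half))) {
    nb <- sweep(co, 2, -half[r, ])
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
      (nb[ok, 3] - 1L) * dims[1] * dims[2]
    hit <- match(nb_lin, idx)
    found <- !is.na(hit)
    if (any(found))
      edges <- rbind(edges, cbind(which(ok)[found], hit[found]))
  }
  if (is.null(edges)) return(seq_len(nv))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nv - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(nv)]
}

# Cluster suprathreshold voxels of a t vector (per sign, 26-connectivity).
# Returns a data.frame of clusters plus the per-voxel assignment.
find_clusters <- function(t_stat, mask, t_crit) {
  dims <- dim(mask$data)
  out <- list()
  assign_idx <- list()
  for (dir in c("positive", "negative")) {
    sel <- if (dir == "positive") which(t_stat >= t_crit)
    else which(t_stat <= -t_crit)
    if (length(sel) == 0) next
    lin <- mask$indices[sel]
    memb <- connected_components_26(lin, dims)
    for (k in sort(unique(memb))) {
      vox <- sel[memb == k]
      peak <- vox[which.max(abs(t_stat[vox]))]
      pco <- arrayInd(mask$indices[peak], dims)
      out[[length(out) + 1]] <- data.frame(
        direction = dir, extent_voxels = length(vox),
        peak_t = t_stat[peak],
        peak_vx = pco[1], peak_vy = pco[2], peak_vz = pco[3],
        stringsAsFactors = FALSE)
      assign_idx[[length(assign_idx) + 1]] <- vox
    }
  }
  if (length(out) == 0)
    return(list(table = NULL, voxels = list()))
  list(table = do.call(rbind, out), voxels = assign_idx)
}

#' Cluster-level inference by permutation of the maximum cluster extent
#'
#' Thresholds the voxel-wise |t| map at the two-sided cluster-forming
#' p-value, extracts connected components (26-connectivity, per sign),
#' and assigns each cluster a family-wise-error-corrected p-value from
#' the permutation distribution of the maximum cluster extent obtained
#' by relabeling groups and recomputing the full statistic map.
#' Uncorrected cluster p-values come from the pooled null distribution
#' of all permutation cluster extents.  This permutation scheme replaces
#' random-field-theory corrections: it is assumption-free and controls
#' the same family-wise error rate.
#'
#' @param patterns a [pattern_matrix()].
#' @param group_labels two-group labels.
#' @param groups optional contrast order as in [voxelwise_ttest()].
#' @param cluster_forming_p two-sided voxel-level p defining the |t|
#'   threshold, in (0, 0.5).
#' @param n_perm number of group relabelings (>= 100 recommended).
#' @param seed RNG seed for the permutation stream.
#' @return Object of class `cluster_table`: `clusters` (data.frame with
#'   peak voxel and mm coordinates, extent, uncorrected and corrected p,
#'   direction), the observed `t_map`, `t_crit`, the null
#'   `max_extent_null`, and per-cluster voxel lists.  An empty table
#'   (zero rows) when nothing survives the threshold.
#' @export
cluster_inference <- function(patterns, group_labels, groups = NULL,
                              cluster_forming_p = 0.001,
                              n_perm = 1000L, seed = 1L) {
  stopifnot(cluster_forming_p > 0, cluster_forming_p < 0.5, n_perm >= 1)
  group_labels <- as.character(group_labels)
  if (is.null(groups)) groups <- sort(unique(group_labels))
  tmap <- voxelwise_ttest(patterns, group_labels, groups)
  t_crit <- qt(1 - cluster_forming_p / 2, tmap$df)
  t_obs <- tmap$t
  t_obs[is.na(t_obs)] <- 0
  obs <- find_clusters(t_obs, patterns$mask, t_crit)

  X <- patterns$values
  in_groups <- group_labels %in% groups
  Xg <- X[in_groups, , drop = FALSE]
  lab <- group_labels[in_groups]
  n1 <- sum(lab == groups[1])
  null_max <- numeric(n_perm)
  null_extents <- integer(0)
  with_local_seed(seed, {
    for (b in seq_len(n_perm)) {
      pidx <- sample(nrow(Xg))
      i1 <- pidx[seq_len(n1)]
      i2 <- pidx[-seq_len(n1)]
      tb <- pooled_t(Xg[i1, , drop = FALSE], Xg[i2, , drop = FALSE])
      tb[!is.finite(tb)] <- 0
      cl <- find_clusters(tb, patterns$mask, t_crit)
      ext <- if (is.null(cl$table)) integer(0) else cl$table$extent_voxels
      null_max[b] <- if (length(ext)) max(ext) else 0
      null_extents <- c(null_extents, ext)
    }
  })

  if (is.null(obs$table)) {
    clusters <- data.frame(direction = character(0),
                           extent_voxels = integer(0), peak_t = numeric(0),
                           peak_vx = integer(0), peak_vy = integer(0),
                           peak_vz = integer(0), peak_x_mm = numeric(0),
                           peak_y_mm = numeric(0), peak_z_mm = numeric(0),
                           p_uncorrected = numeric(0), p_fwe = numeric(0))
  } else {
    tb <- obs$table
    vs <- patterns$mask$voxel_size_mm
    tb$peak_x_mm <- (tb$peak_vx - 1) * vs[1] + patterns$mask$origin[1]
    tb$peak_y_mm <- (tb$peak_vy - 1) * vs[2] + patterns$mask$origin[2]
    tb$peak_z_mm <- (tb$peak_vz - 1) * vs[3] + patterns$mask$origin[3]
    tb$p_fwe <- vapply(tb$extent_voxels,
                       function(e) mean(null_max >= e), numeric(1))
    tb$p_uncorrected <- vapply(tb$extent_voxels, function(e) {
      if (length(null_extents) == 0) 0 else mean(null_extents >= e)
    }, numeric(1))
    ord <- order(tb$extent_voxels, decreasing = TRUE)
    clusters <- tb[ord, c("direction", "extent_voxels", "peak_t",
                          "peak_vx", "peak_vy", "peak_vz",
                          "peak_x_mm", "peak_y_mm", "peak_z_mm",
                          "p_uncorrected", "p_fwe")]
    rownames(clusters) <- NULL
    obs$voxels <- obs$voxels[ord]
  }
  structure(
    list(clusters = clusters, t_map = tmap, t_crit = t_crit,
         cluster_forming_p = cluster_forming_p,
         max_extent_null = null_max, cluster_voxels = obs$voxels,
         n_perm = n_perm, seed = seed),
    class = "cluster_table"
  )
}

#' @export
print.cluster_table <- function(x, ...) {
  cat("<cluster_table>", nrow(x$clusters), "cluster(s) at |t| >",
      format(x$t_crit, digits = 4),
      sprintf("(voxel p < %g two-sided), %d permutations\n",
              x$cluster_forming_p, x$n_perm))
  if (nrow(x$clusters) > 0)
    print(x$clusters[, c("direction", "extent_voxels", "peak_t",
                         "p_uncorrected", "p_fwe")], digits = 3)
  invisible(x)
}

#' Group comparisons of global tissue volumes
#'
#' Two-sample pooled-variance t-test per global measure (GM, WM, CSF,
#' TIV in ml), mirroring the conventional global-volume table of a VBM
#' study.
#'
#' @param manifest data.frame with a `group` column and the measure
#'   columns.
#' @param groups length-2 contrast order (first minus second).
#' @param measures measure column names.
#' @return `data.frame`: measure, per-group mean and SD, t, df, p.
#' @export
global_volume_ttests <- function(manifest, groups = NULL,
                                 measures = c("GM_ml", "WM_ml",
                                              "CSF_ml", "TIV_ml")) {
  if (is.null(groups)) groups <- sort(unique(manifest$group))
  stopifnot(length(groups) == 2, all(measures %in% names(manifest)))
  rows <- lapply(measures, function(ms) {
    x <- manifest[[ms]]
    if (anyNA(x)) {
      bad <- manifest$subject_id[is.na(x)]
      warning("missing ", ms, " for subject(s): ",
              paste(bad, collapse = ", "), "; dropped")
    }
    keep <- !is.na(x)
    x1 <- x[keep & manifest$group == groups[1]]
    x2 <- x[keep & manifest$group == groups[2]]
    tt <- t.test(x1, x2, var.equal = TRUE)
    data.frame(measure = ms,
               mean_1 = mean(x1), sd_1 = sd(x1),
               mean_2 = mean(x2), sd_2 = sd(x2),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- groups
  out
}
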