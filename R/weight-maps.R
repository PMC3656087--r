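#' Voxel-space discriminative weight map of a binary GP classifier
#'
#' For a linear kernel, the latent predictive mean is `f(x*) = x*' w`
#' with `w = X' alpha`, where `alpha` are the dual coefficients of the
#' fitted posterior; the weight vector is therefore an image in voxel
#' space.  Positive weights mark voxels whose larger grey-matter volume
#' pushes a prediction toward the positive (patient) class, negative
#' weights toward the other class.  If the training kernel was
#' mean-centered, the same centering is applied to the patterns so the
#' representer identity `f_train = K alpha = X w` holds exactly.
#'
#' @param posterior a [fit_gpc_binary_ep()] posterior trained on
#'   `patterns` rows `train_idx`.
#' @param patterns the [pattern_matrix()] the kernel was built from.
#' @param train_idx rows of `patterns` the posterior was trained on
#'   (default all, matching the displayed whole-sample maps).
#' @param centered whether the training kernel was mean-centered.
#' @return Object of class `weight_map`: per-voxel `weights` (fixed mask
#'   ordering), the rendered `volume`, `positive_class`, and
#'   `threshold_fraction` (0 = unthresholded).
#' @export
compute_weight_vector <- function(posterior, patterns,
                                  train_idx = NULL, centered = TRUE) {
  stopifnot(inherits(posterior, "gp_binary_posterior"),
            inherits(patterns, "pattern_matrix"))
  X <- patterns$values
  if (is.null(train_idx)) train_idx <- seq_len(nrow(X))
  if (length(train_idx) != length(posterior$alpha))
    stop("train_idx length must match the posterior's training size")
  Xt <- X[train_idx, , drop = FALSE]
  if (centered) Xt <- sweep(Xt, 2, colMeans(Xt))
  w <- as.numeric(crossprod(Xt, posterior$alpha))
  structure(
    list(weights = w, volume = unvectorize(w, patterns$mask),
         mask = patterns$mask, positive_class = posterior$positive_label,
         threshold_fraction = 0),
    class = "weight_map"
  )
}

#' @export
print.weight_map <- function(x, ...) {
  cat("<weight_map> positive class:", x$positive_class,
      "| max |w| =", format(max(abs(x$weights)), digits = 4),
      if (x$threshold_fraction > 0)
        paste0("| thresholded at ", 100 * x$threshold_fraction,
               "% of max |w|"),
      "\n")
  invisible(x)
}

#' Threshold a weight map at a fraction of its maximum absolute weight
#'
#' Retains voxels with `|w| >= fraction * max|w|`, the maximum pooled
#' across signs so that both strong positive and strong negative weights
#' survive, and zeroes the rest.  `per_sign = TRUE` instead applies the
#' fraction to each sign's own maximum.
#'
#' @param map a [compute_weight_vector()] result.
#' @param fraction threshold fraction in `[0, 1]` (0.4 reproduces the
#'   conventional 40%-of-maximum display).
#' @param per_sign use per-sign maxima instead of the pooled maximum.
#' @return A thresholded `weight_map`.
#' @export
threshold_weight_map <- function(map, fraction = 0.4, per_sign = FALSE) {
  stopifnot(inherits(map, "weight_map"), fraction >= 0, fraction <= 1)
  w <- map$weights
  if (per_sign) {
    keep <- (w > 0 & w >= fraction * max(c(w[w > 0], 0))) |
      (w < 0 & -w >= fraction * max(c(-w[w < 0], 0)))
  } else {
    keep <- abs(w) >= fraction * max(abs(w))
  }
  w[!keep] <- 0
  structure(
    list(weights = w, volume = unvectorize(w, map$mask), mask = map$mask,
         positive_class = map$positive_class, threshold_fraction = fraction),
    class = "weight_map"
  )
}

#' Per-class weight maps of a multiclass GP classifier
#'
#' At the Laplace mode the class-c latent predictive mean is
#' `k*' (y_c - pi_c)`, so the class-wise dual coefficients back-project
#' to one voxel-space weight pattern per class.  A high positive weight
#' for a class marks a voxel contributing toward predictions of that
#' class relative to the others.
#'
#' @param posterior a [fit_gpc_multiclass_laplace()] posterior.
#' @param patterns the [pattern_matrix()] used for training.
#' @param train_idx training rows (default all).
#' @param centered whether the training kernel was mean-centered.
#' @return Named list of `weight_map`s, one per class.
#' @export
multiclass_weight_maps <- function(posterior, patterns,
                                   train_idx = NULL, centered = TRUE) {
  stopifnot(inherits(posterior, "gp_multiclass_posterior"),
            inherits(patterns, "pattern_matrix"))
  X <- patterns$values
  if (is.null(train_idx)) train_idx <- seq_len(nrow(X))
  Xt <- X[train_idx, , drop = FALSE]
  if (centered) Xt <- sweep(Xt, 2, colMeans(Xt))
  maps <- lapply(seq_along(posterior$classes), function(cc) {
    w <- as.numeric(crossprod(Xt, posterior$a[, cc]))
    structure(
      list(weights = w, volume = unvectorize(w, patterns$mask),
           mask = patterns$mask, positive_class = posterior$classes[cc],
           threshold_fraction = 0),
      class = "weight_map"
    )
  })
  names(maps) <- posterior$classes
  maps
}

#' Table of the strongest-weight voxels
#'
#' @param map a `weight_map`.
#' @param n number of voxels to list.
#' @return `data.frame` ordered by `|weight|`: voxel indices, world-mm
#'   coordinates, weight.
#' @export
weight_map_table <- function(map, n = 20L) {
  ord <- order(abs(map$weights), decreasing = TRUE)[seq_len(min(n, length(map$weights)))]
  idx <- map$mask$indices[ord]
  co <- arrayInd(idx, dim(map$mask$data))
  mm <- sweep((co - 1) * rep(map$mask$voxel_size_mm, each = nrow(co)), 2,
              -map$mask$origin)
  data.frame(vx = co[, 1], vy = co[, 2], vz = co[, 3],
             x_mm = mm[, 1], y_mm = mm[, 2], z_mm = mm[, 3],
             weight = map$weights[ord])
}

#' Write a weight map as NIfTI
#'
#' Thresholded maps get a `_thr<fraction>` suffix before the extension.
#'
#' @param map a `weight_map`.
#' @param path base output path (`.nii` or `.nii.gz`).
#' @return The path written, invisibly.
#' @export
write_weight_map <- function(map, path) {
  if (map$threshold_fraction > 0) {
    path <- sub("(\\.nii(\\.gz)?)$",
                sprintf("_thr%g\\1", map$threshold_fraction), path)
  }
  write_volume(map$volume, path)
  invisible(path)
}
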