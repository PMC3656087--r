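#' Build an analysis mask from a cohort of volumes
#'
#' A voxel enters the mask iff its intensity exceeds `threshold` in at
#' least `min_fraction` of the subjects.  The default (> 0.05 in >= 90% of
#' subjects) excludes empty background that carries no signal and would
#' only inflate kernel computation; "whole-brain" analyses always carry
#' such an implicit in-brain mask.
#'
#' Voxel linear ordering within the mask is fixed: the first array axis
#' varies fastest (x, then y, then z), i.e. R's native column-major order
#' of `which()`.  All pattern matrices and weight maps use this ordering,
#' which makes voxel-space round trips exact.
#'
#' @param volumes list of [brain_volume()]s on a common grid.
#' @param threshold intensity a voxel must exceed to count as present.
#' @param min_fraction minimum fraction of subjects in which it must be
#'   present.
#' @return Object of class `brain_mask`: logical array `data`, integer
#'   vector `indices` (linear voxel indices, fixed order), and the grid
#'   geometry.
#' @export
build_mask <- function(volumes, threshold = 0.05, min_fraction = 0.9) {
  stopifnot(length(volumes) >= 1)
  ref <- volumes[[1]]
  counts <- array(0L, dim(ref$data))
  for (v in volumes) {
    if (!identical(dim(v$data), dim(ref$data)))
      stop("all volumes must share the same shape to build a mask")
    counts <- counts + (v$data > threshold)
  }
  keep <- counts >= min_fraction * length(volumes)
  if (!any(keep)) stop("analysis mask is empty: no voxel exceeds ",
                       threshold, " in ", min_fraction, " of subjects")
  structure(
    list(data = keep, indices = which(keep),
         voxel_size_mm = ref$voxel_size_mm, origin = ref$origin),
    class = "brain_mask"
  )
}

#' @export
print.brain_mask <- function(x, ...) {
  cat("<brain_mask> ", length(x$indices), " of ", length(x$data),
      " voxels in mask\n", sep = "")
  invisible(x)
}

#' Vectorize a cohort into a subjects-by-voxels pattern matrix
#'
#' Rows follow the order of `volumes` (and hence the manifest); columns
#' follow the mask's fixed voxel ordering.  This matrix is the input
#' representation for all classifiers and voxel-wise tests.
#'
#' @param volumes list of [brain_volume()]s.
#' @param mask a [build_mask()] result on the same grid.
#' @param subject_ids optional character vector of row names.
#' @return Object of class `pattern_matrix`: numeric matrix `values`
#'   (n_subjects x n_voxels), the `mask`, and `subject_ids`.
#' @export
pattern_matrix <- function(volumes, mask, subject_ids = NULL) {
  stopifnot(inherits(mask, "brain_mask"))
  n <- length(volumes)
  X <- matrix(NA_real_, n, length(mask$indices))
  for (i in seq_len(n)) {
    v <- volumes[[i]]
    if (!identical(dim(v$data), dim(mask$data)))
      stop("volume ", i, " shape does not match mask")
    X[i, ] <- v$data[mask$indices]
  }
  if (is.null(subject_ids)) subject_ids <- sprintf("sub-%03d", seq_len(n))
  rownames(X) <- subject_ids
  structure(list(values = X, mask = mask, subject_ids = subject_ids),
            class = "pattern_matrix")
}

#' @export
print.pattern_matrix <- function(x, ...) {
  cat("<pattern_matrix> ", nrow(x$values), " subjects x ", ncol(x$values),
      " voxels\n", sep = "")
  invisible(x)
}

#' Render a per-voxel vector back into a volume
#'
#' Inverse of the mask vectorization: masked voxels receive the vector's
#' values under the fixed ordering, out-of-mask voxels are 0.
#'
#' @param values numeric vector, one value per mask voxel.
#' @param mask a [build_mask()] result.
#' @return A [brain_volume()].
#' @export
unvectorize <- function(values, mask) {
  stopifnot(inherits(mask, "brain_mask"),
            length(values) == length(mask$indices))
  arr <- array(0, dim(mask$data))
  arr[mask$indices] <- values
  brain_volume(arr, mask$voxel_size_mm, mask$origin)
}

#' Write a mask as a 0/1 NIfTI volume
#' @param mask a [build_mask()] result.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  write_volume(brain_volume(array(as.numeric(mask$data), dim(mask$data)),
                            mask$voxel_size_mm, mask$origin), path)
}
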