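#' Construct a brain volume
#'
#' A `brain_volume` is the package's carrier for any 3D scalar field on a
#' voxel grid: modulated grey-matter maps, analysis masks rendered as 0/1
#' images, t-statistic maps and discriminative weight maps.  Geometry is
#' world millimetres: the voxel-to-world affine is diagonal in the voxel
#' sizes plus a translation, which is all the synthetic pipeline needs.
#'
#' @param data 3D numeric array of voxel values (all finite).
#' @param voxel_size_mm positive voxel edge lengths, length 1 or 3, in mm.
#' @param origin world-mm coordinate of voxel (1,1,1), length 3.
#' @return An object of class `brain_volume`.
#' @export
brain_volume <- function(data, voxel_size_mm = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D volume, got ", length(dim(data)), " dimensions")
  if (!all(is.finite(data))) {
    stop("volume contains ", sum(!is.finite(data)), " non-finite voxel values")
  }
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm,
         origin = rep_len(as.numeric(origin), 3L)),
    class = "brain_volume"
  )
}

#' @export
print.brain_volume <- function(x, ...) {
  cat("<brain_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(format(x$voxel_size_mm), collapse = " x "),
      " mm\n  range: [", format(min(x$data)), ", ", format(max(x$data)),
      "]\n", sep = "")
  invisible(x)
}

#' @export
dim.brain_volume <- function(x) dim(x$data)

#' Read a 3D NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param reference optional `brain_volume` whose grid the file must match;
#'   a shape or voxel-size mismatch is a hard error naming the file.
#' @return A [brain_volume()].
#' @export
load_volume <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1L]
  } else if (length(d) != 3L) {
    stop("expected 3D volume in ", path, ", got ", length(d), " dimensions")
  }
  arr <- as.array(img)
  if (!all(is.finite(arr)))
    stop("volume ", path, " contains ", sum(!is.finite(arr)),
         " non-finite voxel values")
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  vol <- brain_volume(arr, voxel_size_mm = abs(pd[1:3]))
  if (!is.null(reference)) {
    if (!identical(dim(vol$data), dim(reference$data)))
      stop("volume ", path, " shape (", paste(dim(vol$data), collapse = "x"),
           ") does not match cohort reference (",
           paste(dim(reference$data), collapse = "x"), ")")
    if (max(abs(vol$voxel_size_mm - reference$voxel_size_mm)) > 1e-4)
      stop("volume ", path, " voxel size does not match cohort reference")
  }
  vol
}

#' Write a brain volume as NIfTI-1
#'
#' @param vol a [brain_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "brain_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

# 1D zero-padded Gaussian convolution matrix for an axis of length n,
# sigma in voxel units.  Truncated at 4 sigma; rows integrate the kernel
# exactly as written (mass is conserved for interior sources, lost at
# edges as with zero padding).
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  off <- -r:r
  k <- exp(-off^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  A <- matrix(0, n, n)
  for (m in seq_along(off)) {
    j <- seq_len(n) + off[m]
    ok <- j >= 1L & j <= n
    A[cbind(which(ok), j[ok])] <- A[cbind(which(ok), j[ok])] + k[m]
  }
  A
}

#' Smooth a volume with an isotropic Gaussian kernel
#'
#' Separable Gaussian convolution with per-axis standard deviation
#' `fwhm_mm / (2 sqrt(2 log 2))` expressed in world mm, so anisotropic
#' voxel grids are handled by per-axis sigmas in voxel units.  Boundaries
#' use zero padding, matching the zero background of masked morphometry
#' images.  `fwhm_mm = 0` is the identity.
#'
#' @param vol a [brain_volume()].
#' @param fwhm_mm full width at half maximum of the kernel, in mm (>= 0).
#' @return Smoothed [brain_volume()] on the same grid.
#' @export
smooth_volume <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "brain_volume"))
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(vol)
  sig_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  x <- vol$data
  d <- dim(x)
  for (ax in 1:3) {
    sig_vox <- sig_mm / vol$voxel_size_mm[ax]
    A <- gauss_conv_matrix(d[ax], sig_vox)
    x <- aperm(x, c(ax, setdiff(1:3, ax)))
    dd <- dim(x)
    x <- array(A %*% matrix(x, nrow = dd[1]), dim = dd)
    x <- aperm(x, order(c(ax, setdiff(1:3, ax))))
  }
  brain_volume(x, vol$voxel_size_mm, vol$origin)
}

#' Global tissue volumes and total intracranial volume
#'
#' For modulated segmentations, voxel intensity is local tissue volume in
#' voxel units, so the global tissue volume is the image sum times the
#' voxel volume.  Total intracranial volume (TIV) is the sum of the grey
#' matter, white matter and CSF compartments.
#'
#' @param gm,wm,csf [brain_volume()]s on the same grid.
#' @return Named list with `GM_ml`, `WM_ml`, `CSF_ml`, `TIV_ml`.
#' @export
global_volumes <- function(gm, wm, csf) {
  vols <- list(gm, wm, csf)
  for (v in vols) stopifnot(inherits(v, "brain_volume"))
  same <- vapply(vols[-1], function(v) {
    identical(dim(v$data), dim(gm$data)) &&
      max(abs(v$voxel_size_mm - gm$voxel_size_mm)) < 1e-8
  }, logical(1))
  if (!all(same)) stop("GM/WM/CSF volumes must share grid shape and voxel size")
  vox_ml <- prod(gm$voxel_size_mm) / 1000  # mm^3 -> ml
  out <- lapply(vols, function(v) sum(v$data) * vox_ml)
  names(out) <- c("GM_ml", "WM_ml", "CSF_ml")
  out$TIV_ml <- out$GM_ml + out$WM_ml + out$CSF_ml
  out
}
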