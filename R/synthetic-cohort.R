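#' Localized group effect for the synthetic cohort generator
#'
#' Describes a spherical region in which one group's grey-matter volume is
#' increased or decreased by a signed fraction of the local template mean.
#' Effects are multiplicative so they scale with local grey-matter density,
#' as in modulated VBM data, and keep intensities nonnegative.
#'
#' @param center voxel coordinate of the sphere center (3 integers,
#'   1-based).
#' @param radius_mm sphere radius in mm (> 0).
#' @param amplitude signed fractional change of the local template
#'   intensity inside the sphere (e.g. -0.12 for a 12% volume reduction).
#' @param target_group group label the effect applies to.
#' @return Object of class `effect_blob`.
#' @export
effect_blob <- function(center, radius_mm, amplitude, target_group) {
  stopifnot(length(center) == 3, radius_mm > 0, is.character(target_group))
  structure(list(center = as.integer(center), radius_mm = radius_mm,
                 amplitude = amplitude, target_group = target_group),
            class = "effect_blob")
}

default_covariate_model <- function() {
  # Per-group normal means/SDs for the demographic and clinical covariates
  # of a three-group adolescent cohort (control / ADHD / ASD): age in
  # years, full-scale IQ, Conners' parent rating ADHD T-score, SDQ
  # hyperactivity-impulsive/inattention subscale.
  list(
    control = list(age_years = c(14.4, 2.48), iq = c(109, 10.4),
                   cprs_t = c(46.6, 6.54), sdq_hi = c(2.00, 1.77)),
    ADHD    = list(age_years = c(13.8, 1.84), iq = c(97.2, 6.91),
                   cprs_t = c(75.8, 7.29), sdq_hi = c(8.32, 2.09)),
    ASD     = list(age_years = c(14.9, 1.86), iq = c(113, 15.7),
                   cprs_t = c(58.7, 7.51), sdq_hi = c(4.74, 1.91))
  )
}

default_effects <- function() {
  # ADHD: two regional grey-matter reductions; ASD: one reduction and one
  # increase at distinct sites, so all three groups are mutually
  # discriminable.  Amplitudes are free parameters of the simulation (no
  # published effect sizes exist for these contrasts); the defaults give a
  # clearly detectable but not trivially separable multivariate signal.
  list(
    effect_blob(c(10, 14, 12), 12, -0.12, "ADHD"),
    effect_blob(c(22, 18, 20), 10, -0.10, "ADHD"),
    effect_blob(c(16,  8, 18), 12, -0.12, "ASD"),
    effect_blob(c(14, 24, 14), 10, +0.10, "ASD")
  )
}

#' Specification of a synthetic morphometry cohort
#'
#' Defines the study conditions the generator emulates: three diagnostic
#' groups (ADHD n=29, control n=29, ASD n=19 by default), smoothed
#' (8-mm FWHM) modulated grey-matter volume maps on a desk-scale 32^3 grid
#' of 4-mm voxels, localized multiplicative group effects, and per-group
#' covariate distributions.
#'
#' @param group_sizes named integer vector of subjects per group (each
#'   count at least 1).
#' @param image_shape grid dimensions (3 integers, each >= 8).
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param smoothing_fwhm_mm Gaussian smoothing FWHM in mm applied to the
#'   template and to subject noise (>= 0).
#' @param subject_noise_sd SD of per-subject white noise before smoothing
#'   (> 0); smoothing reduces the voxel-wise SD substantially.
#' @param effects list of [effect_blob()]s.
#' @param covariate_model per-group list of `c(mean, sd)` for
#'   `age_years`, `iq`, `cprs_t`, `sdq_hi`.
#' @param covariate_coupling optional coefficient linking a subject's
#'   standardized clinical score (`cprs_t`) to the magnitude of that
#'   subject's group effect; 0 (default) leaves covariates independent of
#'   the images.
#' @param seed integer seed making the cohort fully deterministic.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(ADHD = 29L, control = 29L, ASD = 19L),
                        image_shape = c(32L, 32L, 32L),
                        voxel_size_mm = 4,
                        smoothing_fwhm_mm = 8,
                        subject_noise_sd = 0.4,
                        effects = default_effects(),
                        covariate_model = default_covariate_model(),
                        covariate_coupling = 0,
                        seed = 1L) {
  stopifnot(length(group_sizes) >= 1, all(group_sizes >= 1),
            !is.null(names(group_sizes)),
            length(image_shape) == 3,
            voxel_size_mm > 0, smoothing_fwhm_mm >= 0, subject_noise_sd > 0)
  for (g in names(group_sizes)) {
    if (!g %in% names(covariate_model))
      stop("covariate_model has no entry for group '", g, "'")
    if (any(vapply(covariate_model[[g]], function(p) p[2] < 0, logical(1))))
      stop("covariate SDs must be >= 0")
  }
  for (b in effects) {
    stopifnot(inherits(b, "effect_blob"))
    if (any(b$center < 1L) || any(b$center > image_shape))
      stop("effect blob center outside image bounds")
  }
  structure(list(group_sizes = group_sizes,
                 image_shape = as.integer(image_shape),
                 voxel_size_mm = voxel_size_mm,
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 subject_noise_sd = subject_noise_sd,
                 effects = effects,
                 covariate_model = covariate_model,
                 covariate_coupling = covariate_coupling,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

ellipsoid_mask <- function(shape) {
  ctr <- (shape + 1) / 2
  semi <- 0.42 * shape
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  r2 <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
    ((g$z - ctr[3]) / semi[3])^2
  array(r2 <= 1, shape)
}

#' Generate the grey-matter density template
#'
#' A smooth nonnegative scalar field, zero outside an ellipsoidal brain
#' mask: a radially decreasing base density plus a seeded smoothed random
#' texture, then Gaussian-smoothed at the spec's FWHM.  Deterministic
#' given the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return A [brain_volume()].
#' @export
generate_template <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  shape <- spec$image_shape
  if (any(shape < 8L))
    stop("degenerate image shape: every dimension must be >= 8 voxels")
  brain <- ellipsoid_mask(shape)
  ctr <- (shape + 1) / 2
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  r2 <- ((g$x - ctr[1]) / (0.42 * shape[1]))^2 +
    ((g$y - ctr[2]) / (0.42 * shape[2]))^2 +
    ((g$z - ctr[3]) / (0.42 * shape[3]))^2
  base <- array(0.65 * pmax(0, 1 - 0.55 * r2), shape)
  texture <- with_local_seed(derive_seed(spec$seed, "template"), {
    array(rnorm(prod(shape)), shape)
  })
  raw <- brain_volume((base + 0.12 * texture) * brain,
                      voxel_size_mm = spec$voxel_size_mm)
  sm <- smooth_volume(raw, spec$smoothing_fwhm_mm)
  out <- pmax(sm$data, 0) * brain
  brain_volume(out, spec$voxel_size_mm)
}

# Per-group multiplicative effect field: sum of spherical blobs.  Blobs
# reaching outside the brain mask are clipped (with a warning) so that
# background voxels stay exactly zero.
effect_fields <- function(spec, brain) {
  shape <- spec$image_shape
  fields <- list()
  for (g in names(spec$group_sizes))
    fields[[g]] <- array(0, shape)
  if (length(spec$effects) == 0) return(fields)
  grid <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                      z = seq_len(shape[3]))
  for (b in spec$effects) {
    if (!b$target_group %in% names(spec$group_sizes)) next
    d2 <- (grid$x - b$center[1])^2 + (grid$y - b$center[2])^2 +
      (grid$z - b$center[3])^2
    sphere <- array(d2 * spec$voxel_size_mm^2 <= b$radius_mm^2, shape)
    outside <- sum(sphere & !brain)
    if (outside > 0) {
      warning("effect blob at (", paste(b$center, collapse = ","),
              ") extends ", outside, " voxels outside the brain mask; clipped")
      sphere <- sphere & brain
    }
    fields[[b$target_group]] <- fields[[b$target_group]] + b$amplitude * sphere
  }
  fields
}

#' Generate a synthetic cohort of grey-matter volume maps
#'
#' Each subject's volume is `template * (1 + group effect field) +
#' smoothed noise`, with noise restricted to the brain mask so background
#' stays zero.  Covariates are drawn from the per-group distributions,
#' independently of the images unless `covariate_coupling` is nonzero, in
#' which case a subject's standardized clinical score scales that
#' subject's effect magnitude.
#'
#' @param spec a [cohort_spec()].
#' @return List with `manifest` (data.frame: subject_id, group,
#'   age_years, iq, cprs_t, sdq_hi, volume_path), `volumes` (list of
#'   [brain_volume()], aligned one-to-one with manifest rows),
#'   `template`, and `brain_mask` (logical array).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  template <- generate_template(spec)
  brain <- template$data > 0
  fields <- effect_fields(spec, brain)
  groups <- rep(names(spec$group_sizes), times = spec$group_sizes)
  n <- length(groups)
  with_local_seed(derive_seed(spec$seed, "cohort"), {
    covs <- lapply(c("age_years", "iq", "cprs_t", "sdq_hi"), function(nm) {
      vapply(groups, function(g) {
        p <- spec$covariate_model[[g]][[nm]]
        rnorm(1, p[1], p[2])
      }, numeric(1))
    })
    names(covs) <- c("age_years", "iq", "cprs_t", "sdq_hi")
    covs$age_years <- pmax(covs$age_years, 8)  # ages stay physical
    volumes <- vector("list", n)
    for (i in seq_len(n)) {
      g <- groups[i]
      scale_i <- 1
      if (spec$covariate_coupling != 0) {
        p <- spec$covariate_model[[g]][["cprs_t"]]
        if (p[2] > 0)
          scale_i <- 1 + spec$covariate_coupling * (covs$cprs_t[i] - p[1]) / p[2]
      }
      noise <- brain_volume(array(rnorm(prod(spec$image_shape),
                                        sd = spec$subject_noise_sd),
                                  spec$image_shape),
                            voxel_size_mm = spec$voxel_size_mm)
      noise <- smooth_volume(noise, spec$smoothing_fwhm_mm)
      dat <- template$data * (1 + scale_i * fields[[g]]) + noise$data * brain
      volumes[[i]] <- brain_volume(pmax(dat, 0), spec$voxel_size_mm)
    }
    manifest <- data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      group = groups,
      age_years = covs$age_years,
      iq = covs$iq,
      cprs_t = covs$cprs_t,
      sdq_hi = covs$sdq_hi,
      volume_path = NA_character_,
      stringsAsFactors = FALSE
    )
    list(manifest = manifest, volumes = volumes, template = template,
         brain_mask = brain)
  })
}

#' Write a generated cohort to disk
#'
#' Writes one NIfTI-1 volume per subject plus a CSV manifest whose
#' `volume_path` column holds paths relative to `dir`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  for (i in seq_len(nrow(man))) {
    fn <- paste0(man$subject_id[i], ".nii.gz")
    write_volume(cohort$volumes[[i]], file.path(dir, fn))
    man$volume_path[i] <- fn
  }
  path <- file.path(dir, "manifest.csv")
  write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Load a cohort from a manifest CSV
#'
#' @param manifest_path path to a manifest written by [write_cohort()]
#'   (volume paths resolved relative to its directory).
#' @return List with `manifest` and `volumes`, aligned one-to-one.
#' @export
read_cohort <- function(manifest_path) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  volumes <- vector("list", nrow(man))
  ref <- NULL
  for (i in seq_len(nrow(man))) {
    volumes[[i]] <- load_volume(file.path(base, man$volume_path[i]),
                                reference = ref)
    if (is.null(ref)) ref <- volumes[[i]]
  }
  list(manifest = man, volumes = volumes)
}
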