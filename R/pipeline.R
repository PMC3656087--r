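#' Configuration for an end-to-end classification run
#'
#' Validates and freezes everything a run needs: the cohort (a
#' [cohort_spec()] to simulate, or a manifest CSV to load), the design,
#' classifier settings, permutation count and seed.  A config plus its
#' seed fully determines every output.
#'
#' @param cohort a [cohort_spec()] or path to a manifest CSV written by
#'   [write_cohort()].
#' @param design `"binary-balanced"` (matched-pair CV between two
#'   equal-sized groups), `"binary-unbalanced"` (one group vs the pooled
#'   rest, leave-one-subject-out), or `"multiclass"`.
#' @param positive_group patient group for binary designs.
#' @param negative_group comparison group for `"binary-balanced"`;
#'   ignored for `"binary-unbalanced"` (rest) and `"multiclass"`.
#' @param center mean-center kernels within training folds.
#' @param scale_grid kernel-scale grid selected per training fold by the
#'   approximate log marginal likelihood; `NULL` fixes unit scale.
#' @param normalize scale the kernel to unit mean diagonal.
#' @param mask_threshold,mask_min_fraction analysis-mask rule (intensity
#'   above threshold in at least this fraction of subjects).
#' @param n_perm classifier permutations (0 skips the permutation test).
#' @param weight_threshold_fraction display threshold for weight maps.
#' @param vbm_cluster_p cluster-forming voxel p for the univariate
#'   comparison.
#' @param vbm_n_perm permutations for cluster-level FWE (0 skips VBM).
#' @param seed master seed; all stage streams derive from it.
#' @param out_dir output directory, or `NULL` to keep results in memory
#'   only.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       design = c("binary-balanced", "binary-unbalanced",
                                  "multiclass"),
                       positive_group = "ADHD",
                       negative_group = "control",
                       center = TRUE, normalize = TRUE,
                       scale_grid = 10^(0:4),
                       mask_threshold = 0.05, mask_min_fraction = 0.9,
                       n_perm = 0L,
                       weight_threshold_fraction = 0.4,
                       vbm_cluster_p = 0.001, vbm_n_perm = 0L,
                       seed = 1L, out_dir = NULL) {
  design <- match.arg(design)
  structure(list(cohort = cohort, design = design,
                 positive_group = positive_group,
                 negative_group = negative_group,
                 center = center, normalize = normalize,
                 scale_grid = scale_grid,
                 mask_threshold = mask_threshold,
                 mask_min_fraction = mask_min_fraction,
                 n_perm = as.integer(n_perm),
                 weight_threshold_fraction = weight_threshold_fraction,
                 vbm_cluster_p = vbm_cluster_p,
                 vbm_n_perm = as.integer(vbm_n_perm),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# Refit `fit_fn(scale)` over a scale grid and keep the fit with the best
# approximate log marginal likelihood; NULL grid means unit scale.
fit_best_scale <- function(fit_fn, scale_grid) {
  if (is.null(scale_grid)) return(fit_fn(1))
  fits <- lapply(scale_grid, fit_fn)
  fits[[which.max(vapply(fits, function(f) f$lml, numeric(1)))]]
}

#' Run the full classification pipeline
#'
#' Simulate (or load) the cohort, build the analysis mask and pattern
#' matrix, run the cross-validated classifier for the configured design,
#' compute categorical and probabilistic metrics, optionally the
#' permutation test, the whole-sample weight map(s), and the univariate
#' voxel-wise comparison.  When `out_dir` is set, writes the predictions
#' CSV, metrics JSON, ROC CSV, weight-map NIfTIs, cluster table CSV and
#' a run manifest with content hashes; reruns with the same config and
#' seed are byte-identical.
#'
#' @param config a [run_config()].
#' @return A `pipeline_report` list with all stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  # --- cohort ---------------------------------------------------------
  if (inherits(config$cohort, "cohort_spec")) {
    cohort <- generate_cohort(config$cohort)
  } else {
    cohort <- read_cohort(config$cohort)
  }
  man <- cohort$manifest
  groups <- sort(unique(man$group))
  if (config$design == "binary-balanced") {
    if (!all(c(config$positive_group, config$negative_group) %in% groups))
      stop("positive/negative groups not present in cohort")
    n_pos <- sum(man$group == config$positive_group)
    n_neg <- sum(man$group == config$negative_group)
    if (n_pos != n_neg)
      stop("design 'binary-balanced' requires equal group sizes, got ",
           n_pos, " vs ", n_neg)
  }
  if (config$design == "multiclass" && length(groups) < 3)
    stop("design 'multiclass' requires >= 3 groups in the cohort")

  # --- mask, patterns, kernel ----------------------------------------
  mask <- build_mask(cohort$volumes, config$mask_threshold,
                     config$mask_min_fraction)
  if (config$design == "binary-balanced") {
    keep <- man$group %in% c(config$positive_group, config$negative_group)
  } else {
    keep <- rep(TRUE, nrow(man))
  }
  man_used <- man[keep, , drop = FALSE]
  pats <- pattern_matrix(cohort$volumes[keep], mask,
                         subject_ids = man_used$subject_id)
  K <- linear_kernel(pats, normalize = config$normalize)

  labels <- man_used$group
  if (config$design == "binary-unbalanced")
    labels <- ifelse(labels == config$positive_group,
                     config$positive_group,
                     paste0("non-", config$positive_group))

  # --- cross-validated classification --------------------------------
  if (config$design == "multiclass") {
    results <- loo_cv_multiclass(K, labels, center = config$center,
                                 subject_ids = man_used$subject_id,
                                 seed = derive_seed(config$seed, "mc"),
                                 scale_grid = config$scale_grid)
    metrics <- multiclass_metrics(results)
    metrics$target_information <- target_information(results)
    roc <- NULL
  } else {
    scheme <- if (config$design == "binary-balanced")
      cv_scheme("leave-one-pair") else cv_scheme("leave-one-subject")
    results <- loo_cv_binary(K, labels, config$positive_group,
                             scheme = scheme, age = man_used$age_years,
                             center = config$center,
                             subject_ids = man_used$subject_id,
                             scale_grid = config$scale_grid)
    cm <- confusion_metrics(results, config$positive_group)
    roc <- roc_auc(results, config$positive_group)
    metrics <- list(confusion = cm, auc = roc$auc,
                    target_information =
                      target_information(results, config$positive_group))
  }

  # --- permutation significance --------------------------------------
  perm <- NULL
  if (config$n_perm > 0) {
    if (config$design == "multiclass") {
      perm <- permutation_test(K, labels, design = "multiclass",
                               n_perm = config$n_perm,
                               seed = derive_seed(config$seed, "perm"),
                               center = config$center,
                               scale_grid = config$scale_grid)
    } else {
      scheme <- if (config$design == "binary-balanced")
        cv_scheme("leave-one-pair") else cv_scheme("leave-one-subject")
      perm <- permutation_test(K, labels, config$positive_group,
                               scheme = scheme, design = "binary",
                               n_perm = config$n_perm,
                               seed = derive_seed(config$seed, "perm"),
                               age = man_used$age_years,
                               center = config$center,
                               scale_grid = config$scale_grid)
    }
  }

  # --- whole-sample weight maps --------------------------------------
  if (config$design == "multiclass") {
    Kfull <- if (config$center) center_kernel(K$values) else K$values
    post <- fit_best_scale(function(s)
      fit_gpc_multiclass_laplace(s * Kfull + 1, labels), config$scale_grid)
    wmaps <- multiclass_weight_maps(post, pats, centered = config$center)
  } else {
    Kfull <- if (config$center) center_kernel(K$values) else K$values
    post <- fit_best_scale(function(s)
      fit_gpc_binary_ep(s * Kfull + 1, labels, config$positive_group),
      config$scale_grid)
    wmaps <- list(compute_weight_vector(post, pats,
                                        centered = config$center))
    names(wmaps) <- config$positive_group
  }
  wmaps_thr <- lapply(wmaps, threshold_weight_map,
                      fraction = config$weight_threshold_fraction)

  # --- univariate comparison -----------------------------------------
  vbm <- NULL
  if (config$vbm_n_perm > 0 && config$design != "multiclass") {
    pair <- if (config$design == "binary-balanced")
      c(config$negative_group, config$positive_group)
    else c(paste0("non-", config$positive_group), config$positive_group)
    vbm <- cluster_inference(pats, labels, groups = pair,
                             cluster_forming_p = config$vbm_cluster_p,
                             n_perm = config$vbm_n_perm,
                             seed = derive_seed(config$seed, "vbm"))
  }

  # --- probability-covariate correlations ----------------------------
  cors <- NULL
  if (config$design != "multiclass" &&
      all(c("age_years", "iq", "cprs_t", "sdq_hi") %in% names(man_used))) {
    man_cor <- man_used
    man_cor$group <- labels
    cors <- probability_covariate_correlation(results, man_cor)
  }

  report <- structure(
    list(config = config, manifest = man_used, mask = mask,
         results = results, metrics = metrics, roc = roc,
         permutation = perm, weight_maps = wmaps,
         weight_maps_thresholded = wmaps_thr, vbm = vbm,
         correlations = cors),
    class = "pipeline_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> design:", x$config$design, "| n =",
      nrow(x$manifest), "\n")
  if (x$config$design == "multiclass") {
    cat(sprintf("balanced accuracy %.1f%%\n", x$metrics$balanced_accuracy))
  } else {
    print(x$metrics$confusion)
    cat(sprintf("AUC %.3f | target information %.3f bits\n",
                x$metrics$auc, x$metrics$target_information))
  }
  if (!is.null(x$permutation)) print(x$permutation)
  invisible(x)
}

# Serialize metrics to a stable JSON structure (sorted names, fixed
# digits) so identical runs are byte-identical on disk.
metrics_json <- function(report) {
  m <- report$metrics
  out <- if (report$config$design == "multiclass") {
    list(design = report$config$design,
         balanced_accuracy = m$balanced_accuracy,
         per_class = m$per_class,
         target_information = m$target_information)
  } else {
    cm <- m$confusion
    list(design = report$config$design,
         TP = cm$TP, FP = cm$FP, TN = cm$TN, FN = cm$FN,
         sensitivity = cm$sensitivity, specificity = cm$specificity,
         ppv = cm$ppv, npv = cm$npv,
         balanced_accuracy = cm$balanced_accuracy,
         auc = m$auc, target_information = m$target_information)
  }
  if (!is.null(report$permutation)) {
    out$permutation <- list(p_value = report$permutation$p_value,
                            p_value_smoothed =
                              report$permutation$p_value_smoothed,
                            n_perm = report$permutation$n_perm)
  }
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = 10, pretty = TRUE)
}

#' Write all artifacts of a pipeline run
#'
#' Emits predictions CSV, metrics JSON, ROC points CSV, weight-map
#' NIfTIs (raw and thresholded), the cluster table CSV if the univariate
#' stage ran, the covariate correlation table, and a `run_manifest.csv`
#' listing every file with its MD5 content hash.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory.
#' @return Paths written, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "predictions.csv")
  write.csv(report$results, p, row.names = FALSE); paths <- c(paths, p)
  p <- file.path(dir, "metrics.json")
  writeLines(metrics_json(report), p); paths <- c(paths, p)
  if (!is.null(report$roc)) {
    p <- file.path(dir, "roc.csv")
    write.csv(report$roc$curve, p, row.names = FALSE); paths <- c(paths, p)
  }
  for (nm in names(report$weight_maps)) {
    p <- file.path(dir, paste0("weights_", nm, ".nii.gz"))
    write_weight_map(report$weight_maps[[nm]], p); paths <- c(paths, p)
    p2 <- write_weight_map(report$weight_maps_thresholded[[nm]],
                           file.path(dir, paste0("weights_", nm, ".nii.gz")))
    paths <- c(paths, p2)
  }
  if (!is.null(report$permutation)) {
    p <- file.path(dir, "permutation.csv")
    write.csv(data.frame(permuted_balanced_accuracy =
                           report$permutation$permuted),
              p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(report$vbm)) {
    p <- file.path(dir, "vbm_clusters.csv")
    write.csv(report$vbm$clusters, p, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(dir, "vbm_tmap.nii.gz")
    write_volume(report$vbm$t_map$volume, p); paths <- c(paths, p)
  }
  if (!is.null(report$correlations)) {
    p <- file.path(dir, "probability_covariate_correlations.csv")
    write.csv(report$correlations, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  manif <- data.frame(file = basename(paths),
                      md5 = unname(tools::md5sum(paths)),
                      stringsAsFactors = FALSE)
  write.csv(manif, file.path(dir, "run_manifest.csv"), row.names = FALSE)
  invisible(c(paths, file.path(dir, "run_manifest.csv")))
}
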