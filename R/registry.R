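#' The default radiomic feature registry
#'
#' An ordered manifest of the 143 radiomic features extracted per VOI,
#' spanning morphology, first-order SUV intensity (including the five
#' conventional PET metrics: volume, SUVmax, SUVpeak, SUVmean, TLG),
#' intensity-volume histogram, discretized intensity histogram, and the four
#' texture families computed from single merged 26-connectivity matrices
#' (GLCM, GLRLM, GLSZM, NGTDM). The registry is deliberately an editable
#' manifest: pass a subset (or a registry read from
#' `system.file("extdata", "feature_registry.csv", package = "petromics")`)
#' to [extract_all()] to change what is extracted.
#'
#' @return Data frame with columns `feature` and `family` (143 rows for the
#'   default registry).
#' @export
default_registry <- function() {
  fam <- function(names, family) data.frame(feature = names, family = family,
                                            stringsAsFactors = FALSE)
  morph <- c("volume", "morph_voxel_count", "morph_surface_area",
             "morph_surface_volume_ratio", "morph_sphericity",
             "morph_compactness1", "morph_compactness2",
             "morph_spherical_disproportion", "morph_asphericity",
             "morph_max_diameter", "morph_major_axis", "morph_minor_axis",
             "morph_least_axis", "morph_elongation", "morph_flatness",
             "morph_vol_density_aabb", "morph_area_density_aabb",
             "morph_vol_density_aee", "morph_area_density_aee")
  inten <- c("suv_max", "suv_mean", "suv_peak", "tlg", "loc_peak_global",
             "stat_min", "stat_median", "stat_p5", "stat_p10", "stat_p25",
             "stat_p75", "stat_p90", "stat_p95", "stat_iqr", "stat_range",
             "stat_variance", "stat_skewness", "stat_kurtosis", "stat_mad",
             "stat_rmad", "stat_medad", "stat_cov", "stat_qcod",
             "stat_energy", "stat_rms", "stat_com_shift")
  ivh <- c("ivh_v10", "ivh_v25", "ivh_v75", "ivh_v90", "ivh_i10", "ivh_i25",
           "ivh_i75", "ivh_i90", "ivh_v10_minus_v90", "ivh_i10_minus_i90",
           "ivh_auc")
  ih <- c("ih_mean", "ih_variance", "ih_skewness", "ih_kurtosis", "ih_median",
          "ih_min", "ih_max", "ih_mode", "ih_p10", "ih_p25", "ih_p75",
          "ih_p90", "ih_iqr", "ih_range", "ih_mad", "ih_rmad", "ih_medad",
          "ih_cov", "ih_qcod", "ih_entropy", "ih_uniformity",
          "ih_max_gradient", "ih_max_gradient_level", "ih_min_gradient",
          "ih_min_gradient_level")
  glcm <- paste0("glcm_", c("joint_max", "joint_average", "joint_variance",
    "joint_entropy", "diff_average", "diff_variance", "diff_entropy",
    "sum_average", "sum_variance", "sum_entropy", "energy", "contrast",
    "dissimilarity", "inv_diff", "inv_diff_norm", "inv_diff_mom",
    "inv_diff_mom_norm", "inv_variance", "correlation", "autocorrelation",
    "cluster_tendency", "cluster_shade", "cluster_prominence", "info_corr1",
    "info_corr2"))
  glrlm <- paste0("glrlm_", c("sre", "lre", "lglre", "hglre", "srlgle",
    "srhgle", "lrlgle", "lrhgle", "glnu", "glnu_norm", "rlnu", "rlnu_norm",
    "run_percentage", "gl_variance", "rl_variance", "run_entropy"))
  glszm_ <- paste0("glszm_", c("sze", "lze", "lglze", "hglze", "szlgle",
    "szhgle", "lzlgle", "lzhgle", "glnu", "glnu_norm", "zsnu", "zsnu_norm",
    "zone_percentage", "gl_variance", "zs_variance", "zs_entropy"))
  ngtdm_ <- paste0("ngtdm_", c("coarseness", "contrast", "busyness",
    "complexity", "strength"))
  reg <- rbind(fam(morph, "morphology"), fam(inten, "intensity"),
               fam(ivh, "ivh"), fam(ih, "histogram"), fam(glcm, "glcm"),
               fam(glrlm, "glrlm"), fam(glszm_, "glszm"), fam(ngtdm_, "ngtdm"))
  stopifnot(!anyDuplicated(reg$feature), nrow(reg) == 143L)
  reg
}

#' Names of the conventional PET features
#'
#' Volume, SUVmax, SUVpeak, SUVmean and total lesion glycolysis — the
#' clinically established metrics against which other radiomic features are
#' tested for redundancy.
#' @return Character vector of feature names.
#' @export
conventional_features <- function() c("volume", "suv_max", "suv_peak", "suv_mean", "tlg")

#' Extract the full radiomic feature vector from a VOI
#'
#' Runs every feature family on a (resampled) image/mask pair and assembles
#' one finite value per registry entry, in registry order. Extraction is
#' deterministic for fixed input.
#'
#' @param image An [suv_image] (typically after [resample_to_isotropic()]).
#' @param mask The paired [voi_mask].
#' @param registry Registry data frame (default [default_registry()]).
#' @param bin_width Discretization bin width in SUV (default 0.25).
#' @return Named numeric vector of length `nrow(registry)`.
#' @export
extract_all <- function(image, mask, registry = default_registry(), bin_width = 0.25) {
  stopifnot(is.data.frame(registry), all(c("feature", "family") %in% names(registry)))
  disc <- discretize(image, mask, bin_width = bin_width)
  fams <- unique(registry$family)
  vals <- c(
    if ("morphology" %in% fams) .with_feature_context(morphology_features(mask), "morphology"),
    if (any(c("intensity", "ivh") %in% fams)) .with_feature_context(intensity_features(image, mask), "intensity"),
    if ("histogram" %in% fams) .with_feature_context(histogram_features(disc), "histogram"),
    if ("glcm" %in% fams) .with_feature_context(glcm_features(glcm_merged(disc)), "glcm"),
    if ("glrlm" %in% fams) .with_feature_context(glrlm_features(glrlm_merged(disc)), "glrlm"),
    if ("glszm" %in% fams) .with_feature_context(glszm_features(glszm(disc)), "glszm"),
    if ("ngtdm" %in% fams) .with_feature_context(ngtdm_features(ngtdm(disc)), "ngtdm")
  )
  missing <- setdiff(registry$feature, names(vals))
  if (length(missing) > 0)
    .stopf("registry names not produced by any feature family: %s",
           paste(missing, collapse = ", "))
  out <- vals[registry$feature]
  bad <- !is.finite(out)
  if (any(bad))
    .stopf("non-finite feature value(s): %s", paste(names(out)[bad], collapse = ", "))
  out
}

.with_feature_context <- function(expr, family) {
  tryCatch(expr, error = function(e)
    .stopf("feature family '%s' failed: %s", family, conditionMessage(e)))
}

#' Extract a cohort feature table
#'
#' Resamples each patient to the isotropic analysis grid, extracts the
#' registry features, and binds them with the clinical covariates and label
#' into one patients x features table.
#'
#' @param cohort List of `synthetic_patient` objects (see [generate_cohort()]),
#'   or a list of lists with `image`, `mask`, `histology`, `t_stage`,
#'   `n_stage`, `label`.
#' @param registry Registry data frame.
#' @param target_spacing Isotropic analysis spacing in mm (default 2).
#' @param bin_width Discretization bin width (default 0.25).
#' @return Data frame: `patient_id`, clinical columns, `label`, then one
#'   column per registry feature.
#' @export
extract_cohort <- function(cohort, registry = default_registry(),
                           target_spacing = 2, bin_width = 0.25) {
  tab <- attr(cohort, "cohort_table")
  rows <- lapply(seq_along(cohort), function(i) {
    p <- cohort[[i]]
    rs <- resample_to_isotropic(p$image, p$mask, target_spacing = target_spacing)
    extract_all(rs$image, rs$mask, registry = registry, bin_width = bin_width)
  })
  feats <- as.data.frame(do.call(rbind, rows))
  meta <- if (!is.null(tab)) tab else
    data.frame(patient_id = sprintf("P%03d", seq_along(cohort)),
               histology = vapply(cohort, `[[`, "", "histology"),
               t_stage = vapply(cohort, `[[`, 0L, "t_stage"),
               n_stage = vapply(cohort, `[[`, 0L, "n_stage"),
               label = vapply(cohort, `[[`, 0L, "label"),
               stringsAsFactors = FALSE)
  cbind(meta, feats)
}
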