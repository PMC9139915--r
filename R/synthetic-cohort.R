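#' Configuration for a synthetic PET cohort
#'
#' Defines the study conditions for the synthetic cohort generator: a cohort
#' of esophageal-cancer-like patients with ellipsoidal FDG-avid tumors on SUV
#' volumes, binary non-response labels at a fixed prevalence, and clinical
#' covariates (histology, clinical T- and N-stage). Defaults emulate the
#' modelled cohort: 199 patients with 57 non-responders (prevalence 57/199),
#' PET voxel spacing 3.1819 x 3.1819 x 2 mm.
#'
#' `heterogeneity_effect` controls the planted association between the label
#' and intratumoral texture: non-responder tumors receive a spatially
#' correlated texture field with larger amplitude and longer correlation
#' length (one unit of effect = +0.35 SUV field amplitude and +1.5 mm
#' correlation length). At 0 the label is independent of the images.
#'
#' @param n_patients Cohort size (>= 2).
#' @param prevalence Fraction of non-responders, in (0, 1).
#' @param tumor_radius_range Tumor radius range in mm (low, high).
#' @param base_suv_range Mean tumor SUV range (low, high).
#' @param heterogeneity_effect Dimensionless planted-effect size (>= 0).
#' @param noise_sd Additive voxel noise SD, in SUV.
#' @param voxel_spacing Acquisition voxel spacing in mm (length 3).
#' @param seed Integer master seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 199, prevalence = 57 / 199,
                          tumor_radius_range = c(8, 20),
                          base_suv_range = c(4, 12),
                          heterogeneity_effect = 1,
                          noise_sd = 0.3,
                          voxel_spacing = c(3.1819, 3.1819, 2),
                          seed = 1L) {
  if (!.is_count(n_patients) || n_patients < 2) .stopf("n_patients must be a count >= 2")
  if (!(prevalence > 0 && prevalence < 1)) .stopf("prevalence must lie strictly in (0, 1)")
  for (nm in c("tumor_radius_range", "base_suv_range")) {
    v <- get(nm)
    if (length(v) != 2L || v[1] > v[2]) .stopf("%s must be an increasing (low, high) pair", nm)
  }
  if (heterogeneity_effect < 0) .stopf("heterogeneity_effect must be >= 0")
  if (tumor_radius_range[1] < max(voxel_spacing))
    .stopf(paste0("smallest tumor radius (%.3g mm) is below one voxel at spacing ",
                  "%s mm; enlarge the radius or refine the spacing"),
           tumor_radius_range[1], paste(signif(voxel_spacing, 5), collapse = "x"))
  structure(list(n_patients = as.integer(n_patients), prevalence = prevalence,
                 tumor_radius_range = tumor_radius_range,
                 base_suv_range = base_suv_range,
                 heterogeneity_effect = heterogeneity_effect,
                 noise_sd = noise_sd, voxel_spacing = as.numeric(voxel_spacing),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Per-class clinical covariate marginals of the emulated cohort
# (responders n = 142 / non-responders n = 57).
.clinical_marginals <- function() {
  list(
    histology = list(levels = c("adenocarcinoma", "squamous"),
                     responder = c(124, 18), nonresponder = c(53, 4)),
    t_stage = list(levels = c(1L, 2L, 3L, 4L),  # 4 encodes clinical T4a
                   responder = c(2, 28, 107, 5), nonresponder = c(0, 8, 44, 5)),
    n_stage = list(levels = c(0L, 1L, 2L, 3L),
                   responder = c(30, 75, 33, 4), nonresponder = c(16, 23, 15, 3))
  )
}

# Separable Gaussian smoothing of a 3-D array (zero-padded, edge-renormalized).
.smooth_gaussian <- function(arr, sigma_mm, spacing) {
  out <- arr
  norm <- array(1, dim(arr))
  for (a in 1:3) {
    s <- sigma_mm / spacing[a]
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    out <- .conv_axis(out, k, a)
    norm <- .conv_axis(norm, k, a)
  }
  out / pmax(norm, 1e-12)
}

.conv_axis <- function(arr, k, axis) {
  r <- (length(k) - 1L) / 2L
  dims <- dim(arr)
  acc <- array(0, dims)
  for (j in seq_along(k)) {
    d <- integer(3); d[axis] <- j - r - 1L
    if (d[axis] == 0L) { acc <- acc + k[j] * arr; next }
    rng <- .shift_ranges(dims, d)
    if (any(vapply(rng, length, 1L) == 0L)) next
    sub <- array(0, dims)
    sub[rng[[1]], rng[[2]], rng[[3]]] <-
      arr[rng[[1]] + d[1], rng[[2]] + d[2], rng[[3]] + d[3]]
    acc <- acc + k[j] * sub
  }
  acc
}

#' Generate one synthetic PET patient
#'
#' Builds an ellipsoidal tumor filled with a base SUV plus a spatially
#' correlated Gaussian texture field (smoothed white noise; kernel width =
#' correlation length) whose amplitude and correlation length depend on the
#' non-response label through `heterogeneity_effect`, over a near-zero SUV
#' background with additive noise.
#'
#' @param config A [cohort_config].
#' @param label Optional fixed label (0/1); if `NULL`, drawn from
#'   `config$prevalence`.
#' @param seed Optional integer seed for this patient; default uses the
#'   current RNG state.
#' @return A `synthetic_patient`: list with `image` ([suv_image]), `mask`
#'   ([voi_mask]), `histology`, `t_stage`, `n_stage`, `label`.
#' @export
generate_tumor <- function(config, label = NULL, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(label)) label <- as.integer(stats::runif(1) < config$prevalence)
  sp <- config$voxel_spacing
  r <- stats::runif(1, config$tumor_radius_range[1], config$tumor_radius_range[2])
  semi <- r * stats::runif(3, 0.8, 1.2)
  margin <- 8
  half <- max(semi) + margin
  dims <- 2L * ceiling(half / sp) + 1L
  ctr <- (dims + 1) / 2
  coords <- lapply(1:3, function(a) ((seq_len(dims[a]) - ctr[a]) * sp[a]))
  X <- outer(outer((coords[[1]] / semi[1])^2, (coords[[2]] / semi[2])^2, "+"),
             (coords[[3]] / semi[3])^2, "+")
  dim(X) <- dims
  mask <- array(as.numeric(X <= 1), dims)
  if (sum(mask) < 1) .stopf("tumor of radius %.3g mm contains no voxel at spacing %s mm",
                            r, paste(signif(sp, 5), collapse = "x"))
  h <- config$heterogeneity_effect
  amp <- 0.4 + 0.35 * h * label
  clen <- 3 + 1.5 * h * label
  base_suv <- stats::runif(1, config$base_suv_range[1], config$base_suv_range[2])
  field <- .smooth_gaussian(array(stats::rnorm(prod(dims)), dims), clen, sp)
  fs <- stats::sd(field[mask == 1])
  if (is.na(fs) || fs < 1e-12) fs <- 1
  field <- field / fs * amp
  img <- array(0.3, dims) + stats::rnorm(prod(dims), 0, config$noise_sd)
  img[mask == 1] <- base_suv + field[mask == 1] +
    stats::rnorm(sum(mask), 0, config$noise_sd)
  img <- pmax(img, 0)
  dim(img) <- dims
  structure(list(image = suv_image(img, spacing = sp),
                 mask = voi_mask(mask, spacing = sp),
                 histology = NA_character_, t_stage = NA_integer_,
                 n_stage = NA_integer_, label = label),
            class = "synthetic_patient")
}

#' Generate a full synthetic cohort
#'
#' Labels are allocated deterministically as `round(n_patients * prevalence)`
#' positives and then shuffled under the seed, so the prevalence is exact for
#' every seed. Clinical covariates (histology, T-stage, N-stage) are allocated
#' per class by largest-remainder counts from the emulated cohort's per-class
#' marginal tables, then shuffled within class.
#'
#' @param config A [cohort_config].
#' @return List of `synthetic_patient` objects, with a `cohort_table`
#'   attribute (data frame: patient_id, histology, t_stage, n_stage, label).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  n_pos <- as.integer(round(n * config$prevalence))
  if (n_pos < 1 || n_pos > n - 1) .stopf("prevalence yields a one-class cohort")
  set.seed(config$seed)
  labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  marg <- .clinical_marginals()
  clin <- data.frame(histology = character(n), t_stage = integer(n),
                     n_stage = integer(n), stringsAsFactors = FALSE)
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    key <- if (cls == 1L) "nonresponder" else "responder"
    for (v in names(marg)) {
      cnt <- .largest_remainder(length(idx), marg[[v]][[key]])
      vals <- rep(marg[[v]]$levels, cnt)
      clin[[v]][idx] <- sample(vals)
    }
  }
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    p <- generate_tumor(config, label = labels[i], seed = .sub_seed(config$seed, i))
    p$histology <- clin$histology[i]
    p$t_stage <- clin$t_stage[i]
    p$n_stage <- clin$n_stage[i]
    patients[[i]] <- p
  }
  tab <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                    histology = clin$histology, t_stage = clin$t_stage,
                    n_stage = clin$n_stage, label = labels,
                    stringsAsFactors = FALSE)
  attr(patients, "cohort_table") <- tab
  patients
}

#' Write a synthetic cohort to disk
#'
#' Writes per-patient NIfTI image/mask pairs and a cohort CSV
#' (patient_id, histology, t_stage, n_stage, label).
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The cohort table, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- attr(cohort, "cohort_table")
  if (is.null(tab) || nrow(tab) != length(cohort))
    tab <- data.frame(patient_id = sprintf("P%03d", seq_along(cohort)),
                      histology = vapply(cohort, `[[`, "", "histology"),
                      t_stage = vapply(cohort, `[[`, 0L, "t_stage"),
                      n_stage = vapply(cohort, `[[`, 0L, "n_stage"),
                      label = vapply(cohort, `[[`, 0L, "label"),
                      stringsAsFactors = FALSE)
  for (i in seq_along(cohort)) {
    write_volume(cohort[[i]]$image, file.path(dir, sprintf("%s_suv.nii.gz", tab$patient_id[i])))
    write_volume(cohort[[i]]$mask, file.path(dir, sprintf("%s_mask.nii.gz", tab$patient_id[i])))
  }
  utils::write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(tab)
}

#' Generate a tabular synthetic feature set with planted effects
#'
#' Draws standardized features from correlated blocks (within-block Pearson
#' correlation `block_correlation` via a shared latent factor) and plants a
#' mean shift of `effect_sd` standard deviations in the positive class on the
#' first `planted_features` features. Labels are allocated count-then-shuffle
#' at the stated prevalence. This emulates the redundancy structure of a
#' radiomic feature matrix without going through image synthesis.
#'
#' @param n Number of rows (patients).
#' @param n_features Number of features.
#' @param planted_features Number of label-associated features (<= n_features).
#' @param effect_sd Planted class mean shift, in feature SD units.
#' @param block_correlation Within-block correlation, in `[0, 1)`.
#' @param prevalence Positive-class fraction in (0, 1).
#' @param seed Integer seed.
#' @param block_size Features per correlated block (default 5).
#' @return Data frame with a `label` column and `n_features` feature columns;
#'   planted feature names in attribute `"planted"`.
#' @export
generate_feature_table <- function(n, n_features = 30, planted_features = 5,
                                   effect_sd = 0, block_correlation = 0.5,
                                   prevalence = 57 / 199, seed = 1L,
                                   block_size = 5L) {
  if (planted_features > n_features) .stopf("planted_features must be <= n_features")
  if (block_correlation < 0 || block_correlation >= 1)
    .stopf("block_correlation must lie in [0, 1)")
  if (!(prevalence > 0 && prevalence < 1)) .stopf("prevalence must lie in (0, 1)")
  set.seed(seed)
  n_pos <- as.integer(round(n * prevalence))
  labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  n_blocks <- ceiling(n_features / block_size)
  Z <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
  X <- matrix(0, n, n_features)
  for (j in seq_len(n_features)) {
    b <- (j - 1L) %/% block_size + 1L
    X[, j] <- sqrt(block_correlation) * Z[, b] +
      sqrt(1 - block_correlation) * stats::rnorm(n)
  }
  if (planted_features > 0 && effect_sd != 0)
    X[labels == 1L, seq_len(planted_features)] <-
      X[labels == 1L, seq_len(planted_features), drop = FALSE] + effect_sd
  colnames(X) <- sprintf("feature_%03d", seq_len(n_features))
  out <- data.frame(label = labels, X, check.names = FALSE)
  attr(out, "planted") <- colnames(X)[seq_len(planted_features)]
  out
}
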