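#' Morphological features of a VOI
#'
#' Geometry of the binary tumor region: volume (voxel count x voxel volume),
#' surface area by voxel-face counting (a face is counted when an in-mask
#' voxel abuts an out-of-mask voxel or the image border), sphericity and
#' related shape indices, maximum 3-D diameter over surface-voxel centres,
#' principal-axis lengths from the eigenvalues of the voxel-centre covariance
#' (axis length = 4 sqrt(lambda)), and bounding-box / enclosing-ellipsoid
#' density measures.
#'
#' @param mask A [voi_mask].
#' @param spacing Optional spacing override in mm (defaults to the mask's).
#' @return Named numeric vector of morphology features (prefix `morph_`,
#'   plus `volume` in mm^3).
#' @export
morphology_features <- function(mask, spacing = NULL) {
  stopifnot(inherits(mask, "voi_mask"))
  if (is.null(spacing)) spacing <- mask$spacing
  m <- mask$values
  nvox <- sum(m)
  if (nvox < 1) .stopf("morphology features need a non-empty mask")
  voxvol <- prod(spacing)
  V <- nvox * voxvol

  # surface area via exposed voxel faces
  dims <- dim(m)
  A <- 0
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3], spacing[1] * spacing[2])
  for (a in 1:3) for (s in c(-1L, 1L)) {
    d <- integer(3); d[a] <- s
    nb <- array(0, dims)
    rng <- .shift_ranges(dims, d)
    if (!any(vapply(rng, length, 1L) == 0L))
      nb[rng[[1]], rng[[2]], rng[[3]]] <- m[rng[[1]] + d[1], rng[[2]] + d[2], rng[[3]] + d[3]]
    A <- A + sum(m == 1 & nb == 0) * face_area[a]
  }

  sphericity <- (pi^(1 / 3)) * (6 * V)^(2 / 3) / A
  compactness1 <- V / (sqrt(pi) * A^(3 / 2))
  compactness2 <- 36 * pi * V^2 / A^3
  R_eq <- (3 * V / (4 * pi))^(1 / 3)
  spherical_disproportion <- A / (4 * pi * R_eq^2)
  asphericity <- (A^3 / (36 * pi * V^2))^(1 / 3) - 1

  # voxel-centre world coordinates
  idx <- which(m == 1, arr.ind = TRUE)
  W <- sweep(idx - 1, 2, spacing, "*")

  # max 3-D diameter over surface voxels (all voxels if few)
  surf <- .surface_voxels(m)
  S <- sweep(which(surf, arr.ind = TRUE) - 1, 2, spacing, "*")
  if (nrow(S) < 2) {
    max_diam <- 0
  } else {
    dd <- stats::dist(S)
    max_diam <- max(dd)
  }

  if (nrow(W) > 1) {
    ev <- eigen(stats::cov(W), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)  # major >= minor >= least
  elongation <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
  flatness <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0

  # axis-aligned bounding box of voxel extents
  ext <- vapply(1:3, function(a) (diff(range(idx[, a])) + 1) * spacing[a], 1.0)
  v_aabb <- prod(ext)
  a_aabb <- 2 * (ext[1] * ext[2] + ext[1] * ext[3] + ext[2] * ext[3])

  # approximate enclosing ellipsoid from principal semi-axes 2 sqrt(lambda)
  semi <- pmax(2 * sqrt(ev), 1e-9)
  v_aee <- 4 / 3 * pi * prod(semi)
  p <- 1.6075  # Thomsen surface approximation
  a_aee <- 4 * pi * ((semi[1]^p * semi[2]^p + semi[1]^p * semi[3]^p +
                        semi[2]^p * semi[3]^p) / 3)^(1 / p)

  c(volume = V,
    morph_voxel_count = nvox,
    morph_surface_area = A,
    morph_surface_volume_ratio = A / V,
    morph_sphericity = sphericity,
    morph_compactness1 = compactness1,
    morph_compactness2 = compactness2,
    morph_spherical_disproportion = spherical_disproportion,
    morph_asphericity = asphericity,
    morph_max_diameter = max_diam,
    morph_major_axis = axes[1],
    morph_minor_axis = axes[2],
    morph_least_axis = axes[3],
    morph_elongation = elongation,
    morph_flatness = flatness,
    morph_vol_density_aabb = V / v_aabb,
    morph_area_density_aabb = A / a_aabb,
    morph_vol_density_aee = V / v_aee,
    morph_area_density_aee = A / a_aee)
}

.surface_voxels <- function(m) {
  dims <- dim(m)
  exposed <- array(FALSE, dims)
  for (a in 1:3) for (s in c(-1L, 1L)) {
    d <- integer(3); d[a] <- s
    nb <- array(0, dims)
    rng <- .shift_ranges(dims, d)
    if (!any(vapply(rng, length, 1L) == 0L))
      nb[rng[[1]], rng[[2]], rng[[3]]] <- m[rng[[1]] + d[1], rng[[2]] + d[2], rng[[3]] + d[3]]
    exposed <- exposed | (m == 1 & nb == 0)
  }
  exposed
}

# Integer voxel offsets whose centre lies within a 1 cm^3 sphere.
.sphere_offsets <- function(spacing) {
  r <- (3 * 1000 / (4 * pi))^(1 / 3)  # 6.2035 mm
  rr <- floor(r / spacing)
  g <- as.matrix(expand.grid(dx = -rr[1]:rr[1], dy = -rr[2]:rr[2], dz = -rr[3]:rr[3]))
  keep <- sqrt((g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 +
                 (g[, 3] * spacing[3])^2) <= r
  g[keep, , drop = FALSE]
}

# Mean SUV in the 1 cm^3 sphere centred at each given voxel (clipped at the
# image border; sphere voxels need not lie inside the VOI).
.sphere_means <- function(values, centres, spacing) {
  dims <- dim(values)
  offs <- .sphere_offsets(spacing)
  sums <- numeric(nrow(centres))
  cnts <- numeric(nrow(centres))
  for (r in seq_len(nrow(offs))) {
    pos <- sweep(centres, 2, offs[r, ], "+")
    ok <- pos[, 1] >= 1 & pos[, 1] <= dims[1] & pos[, 2] >= 1 & pos[, 2] <= dims[2] &
      pos[, 3] >= 1 & pos[, 3] <= dims[3]
    if (!any(ok)) next
    lin <- pos[ok, 1] + (pos[ok, 2] - 1) * dims[1] + (pos[ok, 3] - 1) * dims[1] * dims[2]
    sums[ok] <- sums[ok] + values[lin]
    cnts[ok] <- cnts[ok] + 1
  }
  sums / pmax(cnts, 1)
}

#' Intensity features of a VOI
#'
#' First-order SUV statistics inside the VOI, the conventional PET metrics
#' (SUVmax, SUVmean, SUVpeak, TLG = SUVmean x volume), intensity-volume
#' histogram measures, and the centre-of-mass shift between the binary and
#' the intensity-weighted centroid. SUVpeak is the maximum over VOI voxels of
#' the mean SUV in a 1 cm^3 sphere; when the VOI itself is smaller than that
#' sphere the value falls back to SUVmean with a warning.
#'
#' @param image An [suv_image].
#' @param mask The paired [voi_mask].
#' @return Named numeric vector (conventional names plus prefixes `stat_`,
#'   `ivh_`, `loc_`).
#' @export
intensity_features <- function(image, mask) {
  stopifnot(inherits(image, "suv_image"), inherits(mask, "voi_mask"))
  .check_paired(image, mask)
  inside <- mask$values == 1
  if (!any(inside)) .stopf("intensity features need a non-empty VOI")
  x <- image$values[inside]
  n <- length(x)
  voxvol <- prod(image$spacing)
  V <- n * voxvol
  mu <- mean(x)

  centres <- which(inside, arr.ind = TRUE)
  if (V < 1000) {
    .warnf("VOI volume %.0f mm^3 is smaller than the 1 cm^3 peak sphere; SUVpeak falls back to SUVmean", V)
    suv_peak <- mu
    loc_peak_global <- mu
  } else {
    sm <- .sphere_means(image$values, centres, image$spacing)
    suv_peak <- max(sm)
    gmax <- which.max(image$values[inside])
    loc_peak_global <- sm[gmax]
  }

  q <- stats::quantile(x, c(0.05, 0.10, 0.25, 0.75, 0.90, 0.95), names = FALSE, type = 7)
  m2 <- mean((x - mu)^2)
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^(3 / 2) else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 - 3 else 0
  sel_r <- x >= q[2] & x <= q[5]
  rmad <- if (any(sel_r)) mean(abs(x[sel_r] - mean(x[sel_r]))) else 0
  covv <- if (mu != 0) sqrt(m2) / mu else 0
  qcod <- if ((q[4] + q[3]) != 0) (q[4] - q[3]) / (q[4] + q[3]) else 0

  # centre-of-mass shift (mm) between binary and SUV-weighted centroids
  Wc <- sweep(centres - 1, 2, image$spacing, "*")
  com_bin <- colMeans(Wc)
  com_int <- colSums(Wc * x) / sum(x)
  com_shift <- sqrt(sum((com_bin - com_int)^2))

  # intensity-volume histogram on the VOI SUV range
  rng <- max(x) - min(x)
  vfrac <- function(theta) mean(x >= theta)
  if (rng > 0) {
    thr <- function(g) min(x) + g * rng
    v10 <- vfrac(thr(0.10)); v25 <- vfrac(thr(0.25))
    v75 <- vfrac(thr(0.75)); v90 <- vfrac(thr(0.90))
    xd <- sort(x, decreasing = TRUE)
    iat <- function(g) xd[max(1L, ceiling(g * n))]
    i10 <- iat(0.10); i25 <- iat(0.25); i75 <- iat(0.75); i90 <- iat(0.90)
    ivh_auc <- (mu - min(x)) / rng
  } else {
    .warnf("constant VOI intensity: intensity-volume histogram degenerates")
    v10 <- v25 <- v75 <- v90 <- 1
    i10 <- i25 <- i75 <- i90 <- mu
    ivh_auc <- 0
  }

  c(suv_max = max(x), suv_mean = mu, suv_peak = suv_peak,
    tlg = mu * V,
    loc_peak_global = loc_peak_global,
    stat_min = min(x), stat_median = stats::median(x),
    stat_p5 = q[1], stat_p10 = q[2], stat_p25 = q[3],
    stat_p75 = q[4], stat_p90 = q[5], stat_p95 = q[6],
    stat_iqr = q[4] - q[3], stat_range = rng,
    stat_variance = m2, stat_skewness = skew, stat_kurtosis = kurt,
    stat_mad = mean(abs(x - mu)), stat_rmad = rmad,
    stat_medad = mean(abs(x - stats::median(x))),
    stat_cov = covv, stat_qcod = qcod,
    stat_energy = sum(x^2), stat_rms = sqrt(mean(x^2)),
    stat_com_shift = com_shift,
    ivh_v10 = v10, ivh_v25 = v25, ivh_v75 = v75, ivh_v90 = v90,
    ivh_i10 = i10, ivh_i25 = i25, ivh_i75 = i75, ivh_i90 = i90,
    ivh_v10_minus_v90 = v10 - v90, ivh_i10_minus_i90 = i10 - i90,
    ivh_auc = ivh_auc)
}

#' Intensity-histogram features of a discretized VOI
#'
#' First-order statistics of the discretized gray levels inside the VOI,
#' including entropy, uniformity and histogram-gradient measures.
#'
#' @param disc A `discretized_image` from [discretize()].
#' @return Named numeric vector with prefix `ih_`.
#' @export
histogram_features <- function(disc) {
  .check_disc(disc)
  g <- disc$bins[disc$mask == 1]
  L <- disc$n_levels
  n <- length(g)
  h <- tabulate(g, nbins = L)
  p <- h / n
  mu <- sum(seq_len(L) * p)
  m2 <- sum((seq_len(L) - mu)^2 * p)
  skew <- if (m2 > 0) sum((seq_len(L) - mu)^3 * p) / m2^(3 / 2) else 0
  kurt <- if (m2 > 0) sum((seq_len(L) - mu)^4 * p) / m2^2 - 3 else 0
  q <- stats::quantile(g, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 1)
  med <- stats::median(g)
  mode_lev <- which.max(h)
  sel_r <- g >= q[1] & g <= q[4]
  rmad <- if (any(sel_r)) mean(abs(g[sel_r] - mean(g[sel_r]))) else 0
  entropy <- -sum(p[p > 0] * log2(p[p > 0]))
  uniformity <- sum(p^2)
  if (L >= 2) {
    grad <- c(h[2] - h[1],
              if (L > 2) (h[3:L] - h[1:(L - 2)]) / 2 else NULL,
              h[L] - h[L - 1])
    max_g <- max(grad); min_g <- min(grad)
    max_gl <- which.max(grad); min_gl <- which.min(grad)
  } else {
    max_g <- min_g <- 0; max_gl <- min_gl <- 1
  }
  c(ih_mean = mu, ih_variance = m2, ih_skewness = skew, ih_kurtosis = kurt,
    ih_median = med, ih_min = min(g), ih_max = max(g), ih_mode = mode_lev,
    ih_p10 = q[1], ih_p25 = q[2], ih_p75 = q[3], ih_p90 = q[4],
    ih_iqr = q[3] - q[2], ih_range = max(g) - min(g),
    ih_mad = mean(abs(g - mean(g))), ih_rmad = rmad,
    ih_medad = mean(abs(g - med)),
    ih_cov = if (mu != 0) sqrt(m2) / mu else 0,
    ih_qcod = if ((q[3] + q[2]) != 0) (q[3] - q[2]) / (q[3] + q[2]) else 0,
    ih_entropy = entropy, ih_uniformity = uniformity,
    ih_max_gradient = max_g, ih_max_gradient_level = max_gl,
    ih_min_gradient = min_g, ih_min_gradient_level = min_gl)
}

#' Texture features from merged texture matrices
#'
#' Scalar features computed from each merged texture matrix. Quantities whose
#' denominator vanishes on degenerate inputs (e.g. a constant VOI) return 0
#' with a warning rather than failing.
#'
#' @param tm A `texture_matrix` of the matching kind.
#' @return Named numeric vector with prefix `glcm_`, `glrlm_`, `glszm_`
#'   or `ngtdm_`.
#' @name texture_features
NULL

#' @rdname texture_features
#' @export
glcm_features <- function(tm) {
  stopifnot(inherits(tm, "texture_matrix"), tm$kind == "GLCM")
  P <- tm$matrix
  L <- nrow(P)
  lev <- seq_len(L)
  pi_ <- rowSums(P)
  mu <- sum(lev * pi_)
  sig2 <- sum((lev - mu)^2 * pi_)
  I <- matrix(lev, L, L)
  J <- t(I)
  # difference and sum marginals
  pd <- vapply(0:(L - 1), function(k) sum(P[abs(I - J) == k]), 1.0)
  ps <- vapply(2:(2 * L), function(k) sum(P[(I + J) == k]), 1.0)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  da <- sum((0:(L - 1)) * pd)
  sa <- sum((2:(2 * L)) * ps)
  hxy <- ent(P)
  pij <- outer(pi_, pi_)
  hxy1 <- -sum(P[pij > 0] * log2(pij[pij > 0]))
  hxy2 <- ent(pij)
  hx <- ent(pi_)
  corr <- if (sig2 > 0) (sum(I * J * P) - mu^2) / sig2 else { .warnf("constant VOI: GLCM correlation undefined, returning 0"); 0 }
  ic1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  ic2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  off <- I != J
  c(glcm_joint_max = max(P),
    glcm_joint_average = mu,
    glcm_joint_variance = sum((I - mu)^2 * P),
    glcm_joint_entropy = hxy,
    glcm_diff_average = da,
    glcm_diff_variance = sum(((0:(L - 1)) - da)^2 * pd),
    glcm_diff_entropy = ent(pd),
    glcm_sum_average = sa,
    glcm_sum_variance = sum(((2:(2 * L)) - sa)^2 * ps),
    glcm_sum_entropy = ent(ps),
    glcm_energy = sum(P^2),
    glcm_contrast = sum((I - J)^2 * P),
    glcm_dissimilarity = sum(abs(I - J) * P),
    glcm_inv_diff = sum(P / (1 + abs(I - J))),
    glcm_inv_diff_norm = sum(P / (1 + abs(I - J) / L)),
    glcm_inv_diff_mom = sum(P / (1 + (I - J)^2)),
    glcm_inv_diff_mom_norm = sum(P / (1 + (I - J)^2 / L^2)),
    glcm_inv_variance = sum(P[off] / (I[off] - J[off])^2),
    glcm_correlation = corr,
    glcm_autocorrelation = sum(I * J * P),
    glcm_cluster_tendency = sum((I + J - 2 * mu)^2 * P),
    glcm_cluster_shade = sum((I + J - 2 * mu)^3 * P),
    glcm_cluster_prominence = sum((I + J - 2 * mu)^4 * P),
    glcm_info_corr1 = ic1,
    glcm_info_corr2 = ic2)
}

# Shared by GLRLM (runs) and GLSZM (zones): 16 analogous statistics.
.rl_zone_features <- function(M, n_voxels, prefix, unit_names) {
  Ns <- sum(M)
  L <- nrow(M); Mx <- ncol(M)
  g <- seq_len(L); j <- seq_len(Mx)
  rg <- rowSums(M); rl <- colSums(M)
  p <- M / Ns
  mug <- sum(g * rowSums(p))
  muj <- sum(j * colSums(p))
  pe <- p[p > 0]
  out <- c(
    sum(rl / j^2) / Ns,                 # short emphasis
    sum(rl * j^2) / Ns,                 # long emphasis
    sum(rg / g^2) / Ns,                 # low gray level
    sum(rg * g^2) / Ns,                 # high gray level
    sum(sweep(sweep(M, 1, g^2, "/"), 2, j^2, "/")) / Ns,
    sum(sweep(sweep(M, 1, g^2, "*"), 2, j^2, "/")) / Ns,
    sum(sweep(sweep(M, 1, g^2, "/"), 2, j^2, "*")) / Ns,
    sum(sweep(sweep(M, 1, g^2, "*"), 2, j^2, "*")) / Ns,
    sum(rg^2) / Ns,
    sum(rg^2) / Ns^2,
    sum(rl^2) / Ns,
    sum(rl^2) / Ns^2,
    Ns / n_voxels,
    sum((matrix(g, L, Mx) - mug)^2 * p),
    sum((matrix(j, L, Mx, byrow = TRUE) - muj)^2 * p),
    -sum(pe * log2(pe))
  )
  names(out) <- paste0(prefix, unit_names)
  out
}

#' @rdname texture_features
#' @export
glrlm_features <- function(tm) {
  stopifnot(inherits(tm, "texture_matrix"), tm$kind == "GLRLM")
  .rl_zone_features(tm$matrix, tm$n_voxels, "glrlm_",
    c("sre", "lre", "lglre", "hglre", "srlgle", "srhgle", "lrlgle", "lrhgle",
      "glnu", "glnu_norm", "rlnu", "rlnu_norm", "run_percentage",
      "gl_variance", "rl_variance", "run_entropy"))
}

#' @rdname texture_features
#' @export
glszm_features <- function(tm) {
  stopifnot(inherits(tm, "texture_matrix"), tm$kind == "GLSZM")
  .rl_zone_features(tm$matrix, tm$n_voxels, "glszm_",
    c("sze", "lze", "lglze", "hglze", "szlgle", "szhgle", "lzlgle", "lzhgle",
      "glnu", "glnu_norm", "zsnu", "zsnu_norm", "zone_percentage",
      "gl_variance", "zs_variance", "zs_entropy"))
}

#' @rdname texture_features
#' @export
ngtdm_features <- function(tm) {
  stopifnot(inherits(tm, "texture_matrix"), tm$kind == "NGTDM")
  p <- tm$p; s <- tm$s; lev <- tm$levels
  present <- p > 0
  Ngp <- sum(present)
  N <- tm$n_valid
  ps_sum <- sum(p * s)
  if (ps_sum > 0) {
    coarseness <- 1 / ps_sum
  } else {
    .warnf("zero-contrast VOI: NGTDM coarseness denominator is 0, returning 0")
    coarseness <- 0
  }
  if (Ngp > 1) {
    pp <- outer(p[present], p[present])
    dd <- outer(lev[present], lev[present], "-")^2
    contrast <- sum(pp * dd) / (Ngp * (Ngp - 1)) * sum(s) / N
    bden <- sum(abs(outer(lev[present] * p[present], lev[present] * p[present], "-")))
    busyness <- if (bden > 0) ps_sum / bden else 0
    num_c <- outer(p[present] * s[present], p[present] * s[present], "+")
    den_c <- outer(p[present], p[present], "+")
    adiff <- abs(outer(lev[present], lev[present], "-"))
    complexity <- sum(adiff * num_c / den_c) / N
    sden <- sum(s)
    strength <- if (sden > 0) sum(den_c * dd) / sden else 0
  } else {
    contrast <- busyness <- complexity <- strength <- 0
  }
  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}
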