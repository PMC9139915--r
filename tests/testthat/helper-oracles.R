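# Brute-force oracles and phantom builders shared across the suite.
# Every oracle is written as a plain double loop, independent of the
# vectorized implementations it checks.

all_offsets26 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

in_bounds <- function(v, dims) all(v >= 1) && all(v <= dims)

# Ordered co-occurrence counts over all 26 neighbour offsets (equivalent to
# symmetric counting over 13 direction pairs), normalized.
bf_glcm <- function(bins, mask) {
  dims <- dim(bins)
  L <- max(bins[mask == 1])
  P <- matrix(0, L, L)
  offs <- all_offsets26()
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    if (mask[i, j, k] != 1) next
    for (r in seq_len(nrow(offs))) {
      v <- c(i, j, k) + offs[r, ]
      if (!in_bounds(v, dims)) next
      if (mask[v[1], v[2], v[3]] != 1) next
      P[bins[i, j, k], bins[v[1], v[2], v[3]]] <-
        P[bins[i, j, k], bins[v[1], v[2], v[3]]] + 1
    }
  }
  if (sum(P) == 0) stop("no pairs")
  P / sum(P)
}

# Run-length counts per direction by explicit scalar walking.
bf_glrlm <- function(bins, mask) {
  dims <- dim(bins)
  L <- max(bins[mask == 1])
  maxlen <- max(dims)
  R <- matrix(0, L, maxlen)
  offs13 <- all_offsets26()
  keep <- apply(offs13, 1, function(v) v[which(v != 0)[1]] > 0)
  offs13 <- offs13[keep, , drop = FALSE]
  for (r in seq_len(nrow(offs13))) {
    d <- offs13[r, ]
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
      v <- c(i, j, k)
      if (mask[i, j, k] != 1) next
      g <- bins[i, j, k]
      prev <- v - d
      if (in_bounds(prev, dims) && mask[prev[1], prev[2], prev[3]] == 1 &&
          bins[prev[1], prev[2], prev[3]] == g) next  # not a run start
      len <- 1
      nxt <- v + d
      while (in_bounds(nxt, dims) && mask[nxt[1], nxt[2], nxt[3]] == 1 &&
             bins[nxt[1], nxt[2], nxt[3]] == g) {
        len <- len + 1
        nxt <- nxt + d
      }
      R[g, len] <- R[g, len] + 1
    }
  }
  R[, seq_len(max(which(colSums(R) > 0))), drop = FALSE]
}

# Zone sizes by stack-based flood fill over 26-connected equal-level voxels.
bf_glszm <- function(bins, mask) {
  dims <- dim(bins)
  L <- max(bins[mask == 1])
  seen <- array(FALSE, dims)
  offs <- all_offsets26()
  zones <- list()
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    if (mask[i, j, k] != 1 || seen[i, j, k]) next
    g <- bins[i, j, k]
    stack <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0
    while (length(stack) > 0) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(offs))) {
        w <- v + offs[r, ]
        if (!in_bounds(w, dims)) next
        if (mask[w[1], w[2], w[3]] == 1 && !seen[w[1], w[2], w[3]] &&
            bins[w[1], w[2], w[3]] == g) {
          seen[w[1], w[2], w[3]] <- TRUE
          stack[[length(stack) + 1]] <- w
        }
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  zm <- do.call(rbind, zones)
  Z <- matrix(0, L, max(zm[, 2]))
  for (r in seq_len(nrow(zm))) Z[zm[r, 1], zm[r, 2]] <- Z[zm[r, 1], zm[r, 2]] + 1
  Z
}

# NGTDM s and n vectors by per-voxel neighbour loops.
bf_ngtdm <- function(bins, mask) {
  dims <- dim(bins)
  L <- max(bins[mask == 1])
  s <- numeric(L); n <- numeric(L)
  offs <- all_offsets26()
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    if (mask[i, j, k] != 1) next
    nb <- c()
    for (r in seq_len(nrow(offs))) {
      v <- c(i, j, k) + offs[r, ]
      if (in_bounds(v, dims) && mask[v[1], v[2], v[3]] == 1)
        nb <- c(nb, bins[v[1], v[2], v[3]])
    }
    if (length(nb) == 0) next
    g <- bins[i, j, k]
    s[g] <- s[g] + abs(g - mean(nb))
    n[g] <- n[g] + 1
  }
  list(s = s, n = n)
}

# AP for distinct scores: mean precision at each positive's rank.
oracle_ap_distinct <- function(labels, scores) {
  stopifnot(!anyDuplicated(scores))
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  prec_at <- cumsum(y) / seq_along(y)
  sum(prec_at[y == 1]) / sum(y)
}

# AUC by exhaustive pairwise comparison (ties count one half).
oracle_auc_pairs <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Random discretized phantom: VOI is the full small grid.
random_disc_phantom <- function(dims, n_levels, seed) {
  set.seed(seed)
  img <- array(sample(seq_len(n_levels), prod(dims), replace = TRUE) * 0.25 - 0.2,
               dims)
  mask <- array(1, dims)
  # randomly carve out some voxels so the VOI is irregular
  drop <- sample(prod(dims), size = floor(prod(dims) / 5))
  mask[drop] <- 0
  if (sum(mask) < 2) mask[seq_len(2)] <- 1
  disc <- discretize(suv_image(img, spacing = c(2, 2, 2)),
                     voi_mask(mask, spacing = c(2, 2, 2)))
  disc
}

# Digital ball mask of given radius (voxels) on an isotropic grid.
ball_mask <- function(radius_mm, spacing) {
  half <- radius_mm + 2 * max(spacing)
  dims <- 2L * as.integer(ceiling(half / spacing)) + 1L
  ctr <- (dims + 1) / 2
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - ctr[a]) * spacing[a])
  D2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  dim(D2) <- dims
  voi_mask(array(as.numeric(D2 <= radius_mm^2), dims), spacing = spacing)
}

# Small image cohort configuration used across image-based tests.
tiny_cohort_config <- function(n = 12, seed = 1, effect = 1)
  cohort_config(n_patients = n, prevalence = 1 / 3,
                tumor_radius_range = c(8, 12), base_suv_range = c(5, 9),
                heterogeneity_effect = effect, noise_sd = 0.3,
                voxel_spacing = c(3.1819, 3.1819, 2), seed = seed)

# Tabular preselection config used by pipeline tests (no manifests).
tabular_preselect <- function() preselect_config(icc_manifest = NULL, redundancy = FALSE)
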