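#' Merged 3-D texture matrices
#'
#' All four texture-matrix builders score the spatial distribution of
#' gray levels in three dimensions with 26-voxel connectivity and accumulate
#' the counts into a single merged matrix (not per-direction matrices that
#' are later averaged):
#'
#' * `glcm_merged()` — gray-level co-occurrences over all 13 unique direction
#'   pairs at distance 1, counted symmetrically (both orderings), summed into
#'   one matrix and normalized to sum 1.
#' * `glrlm_merged()` — run lengths of consecutive equal gray levels along
#'   each of the 13 directions, merged into one gray-level x run-length
#'   count matrix.
#' * `glszm()` — sizes of 26-connected zones of equal gray level
#'   (gray-level x zone-size counts; direction-free by construction).
#' * `ngtdm()` — neighborhood gray-tone differences: for each in-VOI voxel
#'   with at least one in-VOI 26-neighbor, the absolute difference between
#'   its level and the mean level of those neighbors, accumulated per level.
#'
#' @param disc A `discretized_image` from [discretize()].
#' @return A `texture_matrix`: list with `kind`, `matrix` (or vectors for
#'   NGTDM), `normalized` flag, and counts needed by the feature formulas.
#' @name texture_matrices
NULL

.check_disc <- function(disc) {
  if (!inherits(disc, "discretized_image"))
    .stopf("expected a discretized_image (see discretize())")
  if (sum(disc$mask) < 1) .stopf("VOI is empty")
  invisible(TRUE)
}

# Crop arrays to the mask bounding box (1-voxel padding) to keep the shifted
# accumulations cheap on large fields of view.
.crop_to_mask <- function(disc) {
  idx <- which(disc$mask == 1, arr.ind = TRUE)
  dims <- dim(disc$mask)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, dims)
  list(bins = disc$bins[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
       mask = disc$mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
       n_levels = disc$n_levels)
}

#' @rdname texture_matrices
#' @export
glcm_merged <- function(disc) {
  .check_disc(disc)
  if (sum(disc$mask) < 2) .stopf("GLCM needs at least two in-VOI voxels")
  d <- .crop_to_mask(disc)
  L <- d$n_levels
  counts <- numeric(L * L)
  offs <- .offsets13()
  for (r in seq_len(nrow(offs))) {
    p <- .shift_pair(d$bins, offs[r, ])
    m <- .shift_pair(d$mask, offs[r, ])
    sel <- m$base == 1 & m$shifted == 1
    if (!any(sel)) next
    i <- p$base[sel]; j <- p$shifted[sel]
    counts <- counts + tabulate((i - 1L) * L + j, nbins = L * L) +
      tabulate((j - 1L) * L + i, nbins = L * L)
  }
  if (sum(counts) == 0) .stopf("VOI has no neighboring voxel pairs; GLCM undefined")
  P <- matrix(counts / sum(counts), L, L, byrow = TRUE)
  structure(list(kind = "GLCM", matrix = P, normalized = TRUE,
                 n_pairs = sum(counts)), class = "texture_matrix")
}

#' @rdname texture_matrices
#' @export
glrlm_merged <- function(disc) {
  .check_disc(disc)
  d <- .crop_to_mask(disc)
  dims <- dim(d$bins)
  L <- d$n_levels
  max_run <- max(dims)
  R <- matrix(0, L, max_run)
  offs <- .offsets13()
  vox <- which(d$mask == 1, arr.ind = TRUE)
  lin <- function(xyz) xyz[, 1] + (xyz[, 2] - 1L) * dims[1] + (xyz[, 3] - 1L) * dims[1] * dims[2]
  inb <- function(xyz) xyz[, 1] >= 1 & xyz[, 1] <= dims[1] &
    xyz[, 2] >= 1 & xyz[, 2] <= dims[2] & xyz[, 3] >= 1 & xyz[, 3] <= dims[3]
  bin_at <- d$bins
  msk_at <- d$mask
  for (r in seq_len(nrow(offs))) {
    dvec <- offs[r, ]
    prev <- sweep(vox, 2, dvec)
    ok <- inb(prev)
    same_prev <- rep(FALSE, nrow(vox))
    if (any(ok)) {
      pl <- lin(prev[ok, , drop = FALSE])
      same_prev[ok] <- msk_at[pl] == 1 & bin_at[pl] == bin_at[lin(vox[ok, , drop = FALSE])]
    }
    starts <- vox[!same_prev, , drop = FALSE]
    if (nrow(starts) == 0) next
    g <- bin_at[lin(starts)]
    len <- rep(1L, nrow(starts))
    cur <- starts
    active <- rep(TRUE, nrow(starts))
    while (any(active)) {
      nxt <- sweep(cur, 2, dvec, "+")
      ok <- active & inb(nxt)
      cont <- rep(FALSE, length(active))
      if (any(ok)) {
        nl <- lin(nxt[ok, , drop = FALSE])
        cont[ok] <- msk_at[nl] == 1 & bin_at[nl] == g[ok]
      }
      len[cont] <- len[cont] + 1L
      cur[cont, ] <- nxt[cont, , drop = FALSE]
      active <- cont
    }
    for (k in seq_along(g)) R[g[k], len[k]] <- R[g[k], len[k]] + 1
  }
  # trim trailing all-zero run-length columns
  last <- max(which(colSums(R) > 0))
  structure(list(kind = "GLRLM", matrix = R[, seq_len(last), drop = FALSE],
                 normalized = FALSE, n_voxels = sum(disc$mask)),
            class = "texture_matrix")
}

#' @rdname texture_matrices
#' @export
glszm <- function(disc) {
  .check_disc(disc)
  d <- .crop_to_mask(disc)
  L <- d$n_levels
  # label 26-connected components of equal gray level within the VOI
  idx <- which(d$mask == 1)
  node <- array(0L, dim(d$mask))
  node[idx] <- seq_along(idx)
  edges <- list()
  offs <- .offsets13()
  for (r in seq_len(nrow(offs))) {
    p <- .shift_pair(node, offs[r, ])
    b <- .shift_pair(d$bins, offs[r, ])
    sel <- p$base > 0L & p$shifted > 0L & b$base == b$shifted
    if (any(sel)) edges[[length(edges) + 1L]] <- cbind(p$base[sel], p$shifted[sel])
  }
  if (length(edges) > 0) {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership[seq_along(idx)]
  } else {
    memb <- seq_along(idx)
  }
  zones <- data.frame(level = d$bins[idx], zone = memb)
  agg <- stats::aggregate(rep(1L, nrow(zones)),
                          by = list(zone = zones$zone, level = zones$level), FUN = sum)
  max_size <- max(agg$x)
  Z <- matrix(0, L, max_size)
  for (k in seq_len(nrow(agg))) Z[agg$level[k], agg$x[k]] <- Z[agg$level[k], agg$x[k]] + 1
  structure(list(kind = "GLSZM", matrix = Z, normalized = FALSE,
                 n_voxels = sum(disc$mask)), class = "texture_matrix")
}

#' @rdname texture_matrices
#' @export
ngtdm <- function(disc) {
  .check_disc(disc)
  d <- .crop_to_mask(disc)
  L <- d$n_levels
  dims <- dim(d$bins)
  nb_sum <- array(0, dims)
  nb_cnt <- array(0, dims)
  for (r in seq_len(nrow(.offsets26()))) {
    dvec <- .offsets26()[r, ]
    rng <- .shift_ranges(dims, dvec)
    if (any(vapply(rng, length, 1L) == 0L)) next
    sub_b <- array(0, dims); sub_m <- array(0, dims)
    sub_b[rng[[1]], rng[[2]], rng[[3]]] <-
      d$bins[rng[[1]] + dvec[1], rng[[2]] + dvec[2], rng[[3]] + dvec[3]]
    sub_m[rng[[1]], rng[[2]], rng[[3]]] <-
      d$mask[rng[[1]] + dvec[1], rng[[2]] + dvec[2], rng[[3]] + dvec[3]]
    nb_sum <- nb_sum + sub_b * sub_m
    nb_cnt <- nb_cnt + sub_m
  }
  valid <- d$mask == 1 & nb_cnt > 0
  A <- nb_sum[valid] / nb_cnt[valid]
  g <- d$bins[valid]
  s <- numeric(L); n <- numeric(L)
  for (lev in unique(g)) {
    sel <- g == lev
    s[lev] <- sum(abs(lev - A[sel]))
    n[lev] <- sum(sel)
  }
  structure(list(kind = "NGTDM", levels = seq_len(L), s = s, n = n,
                 p = n / sum(n), normalized = FALSE, n_valid = sum(n)),
            class = "texture_matrix")
}

#' @export
print.texture_matrix <- function(x, ...) {
  cat(sprintf("<texture_matrix> %s%s\n", x$kind,
              if (!is.null(x$matrix)) sprintf(" %dx%d", nrow(x$matrix), ncol(x$matrix)) else ""))
  invisible(x)
}
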