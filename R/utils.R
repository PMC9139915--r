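# Internal helpers shared across modules.

# The 13 unique displacement vectors of the 26-neighbourhood (one per
# direction pair): first non-zero component positive.
.offsets13 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- apply(g, 1L, function(v) v[which(v != 0)[1L]] > 0)
  unname(g[keep, , drop = FALSE])
}

# All 26 neighbourhood displacements.
.offsets26 <- function() {
  o <- .offsets13()
  rbind(o, -o)
}

# Index ranges so that voxel (i,j,k) and (i+d) are both in bounds.
.shift_ranges <- function(dims, d) {
  lapply(1:3, function(a) {
    lo <- max(1L, 1L - d[a])
    hi <- min(dims[a], dims[a] - d[a])
    if (lo > hi) integer(0) else lo:hi
  })
}

# Extract the sub-array of `arr` shifted by `d` relative to the base region.
# Returns list(base = A[r], shifted = A[r + d]) as plain arrays.
.shift_pair <- function(arr, d) {
  dims <- dim(arr)
  r <- .shift_ranges(dims, d)
  if (any(vapply(r, length, 1L) == 0L)) {
    return(list(base = array(arr[0], c(0, 0, 0)), shifted = array(arr[0], c(0, 0, 0))))
  }
  list(
    base = arr[r[[1]], r[[2]], r[[3]], drop = FALSE],
    shifted = arr[r[[1]] + d[1], r[[2]] + d[2], r[[3]] + d[3], drop = FALSE]
  )
}

# Largest-remainder allocation of n into counts proportional to p.
.largest_remainder <- function(n, p) {
  stopifnot(all(p >= 0), sum(p) > 0)
  p <- p / sum(p)
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    # break remainder ties by index order for determinism
    ord <- order(raw - base, seq_along(p), decreasing = c(TRUE, FALSE), method = "radix")
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

# Deterministic sub-seed derived from a master seed (kept < 2^31).
.sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 7919) %% 2147483647)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
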