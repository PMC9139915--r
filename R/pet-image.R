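#' SUV image and VOI mask containers
#'
#' `suv_image()` wraps a 3-D array of standardized uptake values (SUV,
#' dimensionless, body-weight normalized) together with its voxel spacing and
#' world origin in millimetres. `voi_mask()` wraps a binary tumor mask on the
#' same grid. Masks must share the grid of their paired image exactly; no
#' implicit resampling is ever performed.
#'
#' @param values 3-D numeric array. For masks, values must be 0/1 (or logical).
#' @param spacing Numeric length-3, voxel spacing in mm (strictly positive).
#' @param origin Numeric length-3, world coordinate of voxel (1,1,1) in mm.
#' @return An object of class `suv_image` or `voi_mask`: a list with elements
#'   `values`, `spacing`, `origin`.
#' @examples
#' img <- suv_image(array(1, c(4, 4, 4)), spacing = c(2, 2, 2))
#' msk <- voi_mask(array(1, c(4, 4, 4)), spacing = c(2, 2, 2))
#' @export
suv_image <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    .stopf("SUV volume must be a 3-D array, got %d dimension(s)",
           if (is.array(values)) length(dim(values)) else 1L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    .stopf("voxel spacing must be three strictly positive mm values")
  if (any(!is.finite(values)))
    .stopf("SUV values must all be finite")
  if (any(values < 0))
    .stopf("SUV values must be non-negative")
  structure(list(values = values, spacing = spacing, origin = as.numeric(origin)),
            class = "suv_image")
}

#' @rdname suv_image
#' @export
voi_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    .stopf("VOI mask must be a 3-D array")
  v <- values
  storage.mode(v) <- "double"
  if (!all(v %in% c(0, 1)))
    .stopf("VOI mask must be binary (0/1)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    .stopf("voxel spacing must be three strictly positive mm values")
  structure(list(values = v, spacing = spacing, origin = as.numeric(origin)),
            class = "voi_mask")
}

#' @export
print.suv_image <- function(x, ...) {
  cat(sprintf("<suv_image> %s voxels, spacing %s mm, SUV range [%.3g, %.3g]\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 5), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %s voxels, spacing %s mm, %d foreground\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 5), collapse = "x"),
              sum(x$values)))
  invisible(x)
}

.check_paired <- function(image, mask) {
  if (!identical(dim(image$values), dim(mask$values)))
    .stopf("image and mask grids differ: %s vs %s",
           paste(dim(image$values), collapse = "x"),
           paste(dim(mask$values), collapse = "x"))
  if (max(abs(image$spacing - mask$spacing)) > 1e-9)
    .stopf("image and mask voxel spacing differ")
  invisible(TRUE)
}

#' Read and write SUV volumes as NIfTI
#'
#' Volumes are stored as NIfTI-1 with voxel spacing carried in the header
#' (`pixdim`). A write/read round trip preserves values and spacing to
#' floating-point precision.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param mask Logical; read/interpret the volume as a binary mask.
#' @return `read_volume()` returns an [suv_image] (or [voi_mask] when
#'   `mask = TRUE`); `write_volume()` returns `path` invisibly.
#' @export
read_volume <- function(path, mask = FALSE) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) != 3L)
    .stopf("expected a 3-D volume, '%s' has %d dimension(s)", path, length(dim(arr)))
  sp <- RNifti::pixdim(nii)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    .stopf("'%s' has missing or non-positive voxel spacing in its header", path)
  if (mask) voi_mask(round(arr), spacing = sp)
  else suv_image(arr, spacing = sp)
}

#' @param image An [suv_image] or [voi_mask].
#' @rdname read_volume
#' @export
write_volume <- function(image, path) {
  stopifnot(inherits(image, "suv_image") || inherits(image, "voi_mask"))
  nii <- RNifti::asNifti(image$values)
  RNifti::pixdim(nii) <- image$spacing
  RNifti::writeNifti(nii, path, datatype = "double")
  invisible(path)
}

#' Delineate a tumor VOI by SUV thresholding
#'
#' Voxels above an SUV threshold (absolute, or a percentage of the maximum
#' inside the search region) are retained, and the largest 26-connected
#' component within the search region becomes the VOI. This mirrors
#' threshold-based PET delineation; manually corrected masks from an external
#' tool can be supplied downstream instead.
#'
#' @param image An [suv_image].
#' @param mode `"percent_of_max"` (default) or `"absolute_suv"`.
#' @param value Threshold: a percentage in (0, 100] for `percent_of_max`
#'   (default 40), or an SUV for `absolute_suv`.
#' @param seed_region Optional list with integer ranges `x`, `y`, `z`
#'   (voxel indices) bounding the search; default is the whole image.
#' @return A [voi_mask] on the image grid.
#' @export
delineate_suv_threshold <- function(image, mode = c("percent_of_max", "absolute_suv"),
                                    value = 40, seed_region = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(image, "suv_image"))
  dims <- dim(image$values)
  if (is.null(seed_region))
    seed_region <- list(x = 1:dims[1], y = 1:dims[2], z = 1:dims[3])
  reg <- array(FALSE, dims)
  reg[seed_region$x, seed_region$y, seed_region$z] <- TRUE
  vals <- image$values
  thr <- switch(mode,
    absolute_suv = value,
    percent_of_max = {
      if (value <= 0 || value > 100) .stopf("percent_of_max threshold must be in (0, 100]")
      value / 100 * max(vals[reg])
    })
  above <- (vals > thr) & reg
  if (!any(above))
    .stopf("no voxel exceeds SUV threshold %.4g inside the seed region; lower the threshold", thr)
  comp <- .label_components(above)
  sizes <- tabulate(comp[above])
  keep <- which.max(sizes)
  m <- array(0, dims)
  m[which(above)[comp[above] == keep]] <- 1
  voi_mask(m, spacing = image$spacing, origin = image$origin)
}

# Label 26-connected components of a logical 3-D array; returns an integer
# array (0 outside), using an igraph connected-components backend.
.label_components <- function(fg) {
  dims <- dim(fg)
  idx <- which(fg)
  lab <- array(0L, dims)
  if (length(idx) == 0L) return(lab)
  node <- array(0L, dims)
  node[idx] <- seq_along(idx)
  edges <- list()
  for (r in seq_len(nrow(.offsets13()))) {
    d <- .offsets13()[r, ]
    p <- .shift_pair(node, d)
    sel <- p$base > 0L & p$shifted > 0L
    if (any(sel)) edges[[length(edges) + 1L]] <- cbind(p$base[sel], p$shifted[sel])
  }
  if (length(edges) == 0L) {
    lab[idx] <- seq_along(idx)
    return(lab)
  }
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  lab[idx] <- igraph::components(g)$membership[seq_along(idx)]
  lab
}

#' Resample an SUV image and its VOI to an isotropic grid
#'
#' Both image and mask are trilinearly interpolated onto an isotropic grid
#' (default 2 mm), after which the interpolated mask is rounded to binary with
#' values of exactly 0.5 rounding up (inclusive boundary, so thin structures
#' are not dropped).
#'
#' @param image An [suv_image].
#' @param mask The paired [voi_mask] (same grid).
#' @param target_spacing Target isotropic spacing in mm (default 2).
#' @return A list with elements `image` and `mask` on the new grid.
#' @export
resample_to_isotropic <- function(image, mask, target_spacing = 2) {
  stopifnot(inherits(image, "suv_image"), inherits(mask, "voi_mask"))
  .check_paired(image, mask)
  if (any(dim(image$values) < 2L))
    .stopf("cannot trilinearly resample a degenerate (single-slice) volume; dims are %s",
           paste(dim(image$values), collapse = "x"))
  if (target_spacing <= 0) .stopf("target spacing must be positive")
  out_img <- .trilinear_resample(image$values, image$spacing, target_spacing)
  out_msk <- .trilinear_resample(mask$values, mask$spacing, target_spacing)
  msk_bin <- ifelse(out_msk$values >= 0.5, 1, 0)  # 0.5 rounds up
  list(
    image = suv_image(pmax(out_img$values, 0), spacing = rep(target_spacing, 3),
                      origin = image$origin),
    mask = voi_mask(array(msk_bin, dim(out_msk$values)),
                    spacing = rep(target_spacing, 3), origin = mask$origin)
  )
}

# Vectorized trilinear interpolation onto an isotropic grid covering the same
# voxel-centre extent as the input.
.trilinear_resample <- function(arr, spacing, target) {
  dims <- dim(arr)
  axes <- lapply(1:3, function(a) {
    extent <- (dims[a] - 1) * spacing[a]
    n_out <- floor(extent / target) + 1L
    t <- (seq_len(n_out) - 1) * target / spacing[a] + 1  # continuous input index
    i0 <- pmin(pmax(floor(t), 1), dims[a] - 1L)
    w <- t - i0
    list(i0 = as.integer(i0), w = w, n = n_out)
  })
  nx <- axes[[1]]$n; ny <- axes[[2]]$n; nz <- axes[[3]]$n
  out <- array(0, c(nx, ny, nz))
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    wx <- if (a == 0) 1 - axes[[1]]$w else axes[[1]]$w
    wy <- if (b == 0) 1 - axes[[2]]$w else axes[[2]]$w
    wz <- if (cc == 0) 1 - axes[[3]]$w else axes[[3]]$w
    W <- outer(outer(wx, wy), wz)
    dim(W) <- c(nx, ny, nz)
    out <- out + W * arr[axes[[1]]$i0 + a, axes[[2]]$i0 + b, axes[[3]]$i0 + cc, drop = FALSE]
  }
  list(values = out, spacing = rep(target, 3))
}
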