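test_that("morphology volume and voxel counting are exact", {
  m <- array(0, c(5, 5, 5)); m[2:3, 2, 2] <- 1; m[2:5, 3, 3] <- 1; m[2:5, 4, 4] <- 1
  msk <- voi_mask(m, spacing = c(2, 2, 2))
  f <- morphology_features(msk)
  expect_equal(unname(f["volume"]), 10 * 8)   # 10 voxels x 8 mm^3
  expect_equal(unname(f["morph_voxel_count"]), 10)

  single <- array(0, c(3, 3, 3)); single[2, 2, 2] <- 1
  f1 <- morphology_features(voi_mask(single, spacing = c(2, 2, 2)))
  expect_equal(unname(f1["volume"]), 8)
  expect_equal(unname(f1["morph_surface_area"]), 6 * 4)  # 6 exposed 2x2 faces
})

test_that("face-count sphericity of a digital ball approaches the estimator limit", {
  # voxel-face surface area converges to 1.5x the true sphere area, so the
  # face-count sphericity limit for a ball is 2/3
  sph <- sapply(c(2, 1, 0.5), function(s) {
    f <- morphology_features(ball_mask(10, spacing = c(s, s, s)))
    unname(f["morph_sphericity"])
  })
  expect_lt(abs(sph[3] - 2 / 3), 0.02)
  expect_lt(abs(sph[3] - 2 / 3), abs(sph[1] - 2 / 3) + 0.01)
  # volume itself converges to the analytic ball volume
  v <- morphology_features(ball_mask(10, spacing = c(0.5, 0.5, 0.5)))["volume"]
  expect_lt(abs(v - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
})

test_that("intensity features are exact on constant phantoms", {
  msk <- ball_mask(8, spacing = c(2, 2, 2))
  img <- suv_image(array(4, dim(msk$values)), spacing = c(2, 2, 2))
  f <- intensity_features(img, msk)
  expect_equal(unname(f["suv_max"]), 4)
  expect_equal(unname(f["suv_mean"]), 4)
  expect_equal(unname(f["stat_variance"]), 0)
  nvox <- sum(msk$values)
  expect_equal(unname(f["tlg"]), 4 * nvox * 8)
})

test_that("TLG multiplies SUVmean by volume on a tiny VOI", {
  m <- array(0, c(8, 8, 8)); m[2:3, 2:3, 2:3] <- 1; m[4, 2, 2] <- 1; m[4, 3, 2] <- 1
  msk <- voi_mask(m, spacing = c(2, 2, 2))   # 10 voxels = 80 mm^3
  img <- suv_image(array(4, c(8, 8, 8)), spacing = c(2, 2, 2))
  expect_warning(f <- intensity_features(img, msk), "peak sphere")
  expect_equal(unname(f["tlg"]), 320)
  expect_equal(unname(f["suv_peak"]), 4)  # fallback to SUVmean
})

test_that("a single hot voxel raises SUVmax above SUVmean", {
  msk <- ball_mask(8, spacing = c(2, 2, 2))
  a <- array(0, dim(msk$values)); a[msk$values == 1] <- 1
  ctr <- (dim(a) + 1) / 2
  a[ctr[1], ctr[2], ctr[3]] <- 10
  f <- intensity_features(suv_image(a, spacing = c(2, 2, 2)), msk)
  expect_equal(unname(f["suv_max"]), 10)
  expect_lt(unname(f["suv_mean"]), 10)
  expect_lt(unname(f["suv_peak"]), 10)  # sphere mean dilutes the hot voxel
  expect_gt(unname(f["suv_peak"]), unname(f["suv_mean"]))
})

test_that("full extraction yields 143 finite features, deterministically", {
  p <- generate_tumor(tiny_cohort_config(seed = 2), label = 1, seed = 31)
  rs <- resample_to_isotropic(p$image, p$mask)
  v1 <- extract_all(rs$image, rs$mask)
  v2 <- extract_all(rs$image, rs$mask)
  expect_length(v1, 143)
  expect_true(all(is.finite(v1)))
  expect_identical(v1, v2)
  expect_named(v1, default_registry()$feature)
})

test_that("features are invariant to whole-voxel translation", {
  p <- generate_tumor(tiny_cohort_config(seed = 4), label = 0, seed = 17)
  rs <- resample_to_isotropic(p$image, p$mask)
  v0 <- extract_all(rs$image, rs$mask)
  pad <- function(a, n = 3) {
    d <- dim(a); out <- array(0, d + c(2 * n, 2 * n, 2 * n))
    out[n + seq_len(d[1]), n + seq_len(d[2]), n + seq_len(d[3])] <- a
    out
  }
  shift <- function(a, s) {
    d <- dim(a); out <- array(0, d)
    out[(1 + s):d[1], (1 + s):d[2], (1 + s):d[3]] <-
      a[1:(d[1] - s), 1:(d[2] - s), 1:(d[3] - s)]
    out
  }
  ip <- pad(rs$image$values); mp <- pad(rs$mask$values)
  v1 <- extract_all(suv_image(ip, spacing = rs$image$spacing),
                    voi_mask(mp, spacing = rs$mask$spacing))
  v2 <- extract_all(suv_image(shift(ip, 2), spacing = rs$image$spacing),
                    voi_mask(shift(mp, 2), spacing = rs$mask$spacing))
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("merged-direction features are invariant to axis permutation", {
  p <- generate_tumor(tiny_cohort_config(seed = 6), label = 1, seed = 23)
  rs <- resample_to_isotropic(p$image, p$mask)  # isotropic grid
  v1 <- extract_all(rs$image, rs$mask)
  perm <- function(a) aperm(a, c(3, 1, 2))
  v2 <- extract_all(suv_image(perm(rs$image$values), spacing = rs$image$spacing),
                    voi_mask(perm(rs$mask$values), spacing = rs$mask$spacing))
  texture <- default_registry()$feature[default_registry()$family %in%
                                          c("glcm", "glrlm", "glszm", "ngtdm",
                                            "histogram", "intensity", "ivh")]
  expect_equal(v1[texture], v2[texture], tolerance = 1e-9)
})
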