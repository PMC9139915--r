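test_that("NIfTI round trip preserves values and anisotropic spacing", {
  set.seed(1)
  img <- suv_image(array(runif(5 * 6 * 7, 0, 10), c(5, 6, 7)),
                   spacing = c(3.1819, 3.1819, 2))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(img, path)
  back <- read_volume(path)
  expect_equal(back$values, img$values, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$spacing, c(3.1819, 3.1819, 2), tolerance = 1e-6)
})

test_that("non-3-D input and invalid grids are rejected", {
  expect_error(suv_image(matrix(1, 3, 3), spacing = c(2, 2, 2)), "3-D")
  expect_error(suv_image(array(-1, c(2, 2, 2)), spacing = c(2, 2, 2)), "non-negative")
  expect_error(suv_image(array(1, c(2, 2, 2)), spacing = c(2, 0, 2)), "positive")
  expect_error(voi_mask(array(0.5, c(2, 2, 2)), spacing = c(2, 2, 2)), "binary")
  path <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(1, 4, 4)), path)
  expect_error(read_volume(path), "3-D")
})

test_that("SUV threshold delineation keeps the largest component above threshold", {
  a <- array(1, c(9, 9, 9))
  a[2:3, 2:3, 2:3] <- 8          # small hot blob (8 voxels)
  a[5:8, 5:8, 5:8] <- 6          # larger hot blob (64 voxels)
  img <- suv_image(a, spacing = c(2, 2, 2))
  m <- delineate_suv_threshold(img, mode = "absolute_suv", value = 2.5)
  expect_equal(sum(m$values), 64)
  expect_equal(sum(m$values[5:8, 5:8, 5:8]), 64)

  # percent of max: threshold 40% of 10 keeps strictly > 4
  b <- array(1, c(6, 6, 6)); b[3:4, 3:4, 3:4] <- 10; b[1, 1, 1] <- 4
  m2 <- delineate_suv_threshold(suv_image(b, spacing = c(2, 2, 2)),
                                mode = "percent_of_max", value = 40)
  expect_equal(sum(m2$values), 8)

  expect_error(delineate_suv_threshold(img, mode = "absolute_suv", value = 99),
               "threshold")
})

test_that("constant-image delineation keeps the whole seed region", {
  img <- suv_image(array(5, c(6, 6, 6)), spacing = c(2, 2, 2))
  reg <- list(x = 2:4, y = 2:4, z = 2:4)
  m <- delineate_suv_threshold(img, mode = "absolute_suv", value = 2.5,
                               seed_region = reg)
  expect_equal(sum(m$values), 27)
  expect_equal(sum(m$values[2:4, 2:4, 2:4]), 27)
})

test_that("trilinear resampling preserves constants and exactly interpolates ramps", {
  const <- suv_image(array(4, c(7, 7, 7)), spacing = c(3.1819, 3.1819, 2))
  msk <- voi_mask(array(1, c(7, 7, 7)), spacing = c(3.1819, 3.1819, 2))
  rs <- resample_to_isotropic(const, msk, target_spacing = 2)
  expect_true(all(abs(rs$image$values - 4) < 1e-9))
  expect_true(all(rs$mask$values == 1))
  expect_equal(rs$image$spacing, c(2, 2, 2))

  # linear ramp along x reproduced exactly at interior points
  ramp <- array(rep(seq(0, 12, length.out = 13), times = 25), c(13, 5, 5))
  rimg <- suv_image(ramp, spacing = c(4, 4, 4))
  rmsk <- voi_mask(array(1, c(13, 5, 5)), spacing = c(4, 4, 4))
  rs2 <- resample_to_isotropic(rimg, rmsk, target_spacing = 2)
  expected <- (seq_len(dim(rs2$image$values)[1]) - 1) * 2 / 4  # world mm / 4mm per unit
  expect_equal(rs2$image$values[, 2, 2], expected, tolerance = 1e-12)
})

test_that("mask interpolation rounds 0.5 up and stays binary", {
  # two-voxel mask along x at 4mm: midpoint voxel interpolates to exactly 0.5
  m <- array(0, c(4, 3, 3)); m[2, , ] <- 1
  msk <- voi_mask(m, spacing = c(4, 4, 4))
  img <- suv_image(array(1, c(4, 3, 3)), spacing = c(4, 4, 4))
  rs <- resample_to_isotropic(img, msk, target_spacing = 2)
  vals <- rs$mask$values
  expect_true(all(vals %in% c(0, 1)))
  # input centre x=4mm is mask; neighbours at 2 and 6mm interpolate to 0.5 -> 1
  expect_equal(vals[2:4, 2, 2], c(1, 1, 1))
  expect_equal(vals[1, 2, 2], 0)
})

test_that("degenerate single-slice volumes cannot be resampled", {
  img <- suv_image(array(1, c(5, 5, 1)), spacing = c(2, 2, 2))
  msk <- voi_mask(array(1, c(5, 5, 1)), spacing = c(2, 2, 2))
  expect_error(resample_to_isotropic(img, msk), "single-slice")
})

test_that("digital-ball volume error vanishes with finer rasterization", {
  true_v <- 4 / 3 * pi * 10^3
  err <- sapply(c(2, 1, 0.5), function(s)
    abs(sum(ball_mask(10, spacing = c(s, s, s))$values) * s^3 - true_v) / true_v)
  expect_lt(err[3], 0.01)
  expect_lt(err[3], err[1])

  # rounding-resampled masks stay near the source mask's own volume
  msk <- ball_mask(10, spacing = c(3.1819, 3.1819, 2))
  img <- suv_image(array(1, dim(msk$values)), spacing = msk$spacing)
  src_v <- sum(msk$values) * prod(msk$spacing)
  rs <- resample_to_isotropic(img, msk, target_spacing = 2)
  expect_lt(abs(sum(rs$mask$values) * 8 - src_v) / src_v, 0.05)
})
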