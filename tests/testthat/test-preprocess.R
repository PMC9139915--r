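test_that("sample skewness matches the direct moment formula", {
  expect_equal(sample_skewness(c(-1, 0, 1)), 0)
  expect_gt(sample_skewness(c(0, 0, 0, 10)), 0)
  set.seed(8)
  x <- rlnorm(200)
  m <- mean(x); m2 <- mean((x - m)^2); m3 <- mean((x - m)^3)
  expect_equal(sample_skewness(x), m3 / m2^(3 / 2), tolerance = 1e-12)
  expect_error(sample_skewness(c(1, 2)), "at least 3")
  expect_warning(s0 <- sample_skewness(c(2, 2, 2)), "zero-variance")
  expect_equal(s0, 0)
})

test_that("Yeo-Johnson follows the two-branch formula and is monotone", {
  x <- c(-3, -0.5, 0, 0.5, 3)
  expect_equal(yeo_johnson(x[x >= 0], 1), x[x >= 0])          # identity at lambda 1
  expect_equal(yeo_johnson(0, runif(1, -4, 4)), 0)            # zero maps to zero
  expect_equal(yeo_johnson(2, 0), log(3))
  expect_equal(yeo_johnson(-2, 2), -log(3))
  expect_equal(yeo_johnson(2, 0.5), ((3)^0.5 - 1) / 0.5)
  expect_equal(yeo_johnson(-2, 0.5), -((3)^1.5 - 1) / 1.5)
  set.seed(11)
  for (lam in runif(5, -3, 3)) {
    z <- sort(rnorm(50, 0, 2))
    expect_true(all(diff(yeo_johnson(z, lam)) > 0))
  }
})

test_that("fitted lambda agrees with the independent power-transform oracle", {
  skip_if_not_installed("car")
  set.seed(21)
  x <- rlnorm(300, 0, 0.7)
  lam_pkg <- petromics:::.fit_yj_lambda(x)
  lam_car <- car::powerTransform(x, family = "yjPower")$lambda
  expect_equal(unname(lam_pkg), unname(lam_car), tolerance = 0.02)
})

test_that("the skewness rule assigns branches with an inclusive boundary", {
  # construct features with controlled skewness
  set.seed(5)
  sym <- rnorm(300)                     # |skew| < 0.5 -> robust
  skw <- rlnorm(300)                    # skew > 0.5 -> Yeo-Johnson
  tab <- data.frame(sym = sym, skw = skw)
  plan <- fit_normalization_plan(tab)
  expect_equal(plan$sym$branch, "robust")
  expect_equal(plan$skw$branch, "yeo_johnson")
})

test_that("a feature at |skewness| exactly 0.5 takes the robust branch", {
  tab <- data.frame(f = rnorm(50))
  local_mocked_bindings(sample_skewness = function(values) 0.5,
                        .package = "petromics")
  plan <- fit_normalization_plan(tab)
  expect_equal(plan$f$branch, "robust")
  local_mocked_bindings(sample_skewness = function(values) -0.5,
                        .package = "petromics")
  expect_equal(fit_normalization_plan(tab)$f$branch, "robust")
  local_mocked_bindings(sample_skewness = function(values) 0.5001,
                        .package = "petromics")
  expect_equal(fit_normalization_plan(tab)$f$branch, "yeo_johnson")
})

test_that("robust branch maps training median to 0 and IQR to 1", {
  set.seed(6)
  x <- rnorm(101, 10, 3)
  tab <- data.frame(f = x)
  plan <- fit_normalization_plan(tab)
  out <- apply_normalization_plan(plan, tab)
  expect_equal(median(out$f), 0, tolerance = 1e-12)
  expect_equal(IQR(out$f), 1, tolerance = 1e-12)
})

test_that("test rows are transformed with training constants only", {
  set.seed(7)
  train <- data.frame(f = rlnorm(150))
  test <- data.frame(f = rlnorm(50, 1))
  plan <- fit_normalization_plan(train)
  out1 <- apply_normalization_plan(plan, test)
  # applying the same plan twice to different tables uses identical constants
  out2 <- apply_normalization_plan(plan, test)
  expect_identical(out1, out2)
  expect_error(apply_normalization_plan(plan, data.frame(g = 1:3)), "lacks")
})

test_that("degenerate features fall back with a warning", {
  tab <- data.frame(const = rep(2, 20), ok = rnorm(20))
  expect_warning(plan <- fit_normalization_plan(tab), "constant")
  expect_equal(plan$const$branch, "identity")
  tab2 <- data.frame(f = c(rep(0, 20), -5, 5))  # symmetric but zero IQR
  expect_warning(plan2 <- fit_normalization_plan(tab2), "IQR")
  expect_equal(plan2$f$branch, "robust")
})

test_that("Yeo-Johnson reduces skewness of log-normal features", {
  reduced <- 0
  for (seed in 1:8) {
    set.seed(seed)
    x <- rlnorm(200, 0, 1)
    tab <- data.frame(f = x)
    plan <- fit_normalization_plan(tab)
    y <- apply_normalization_plan(plan, tab)$f
    if (abs(sample_skewness(y)) <= abs(sample_skewness(x))) reduced <- reduced + 1
  }
  expect_gte(reduced, 7)
})

test_that("normalization plans survive a JSON round trip", {
  set.seed(9)
  tab <- data.frame(a = rnorm(60), b = rlnorm(60))
  plan <- fit_normalization_plan(tab)
  path <- withr::local_tempfile(fileext = ".json")
  write_normalization_plan(plan, path)
  back <- read_normalization_plan(path)
  out1 <- apply_normalization_plan(plan, tab)
  out2 <- apply_normalization_plan(back, tab)
  expect_equal(out1, out2, tolerance = 1e-12)
})
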