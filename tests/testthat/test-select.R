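make_named_table <- function(n = 60, p = 8, seed = 1) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(X) <- sprintf("f%02d", seq_len(p))
  X
}

test_that("ICC preselection drops exactly the sub-cutoff features, boundary retained", {
  tab <- make_named_table(p = 5)
  man <- data.frame(feature = names(tab), icc = c(0.59, 0.6, 0.61, 0.2, 1.0))
  out <- drop_low_icc(tab, man)
  expect_setequal(attr(out, "dropped"), c("f01", "f04"))
  expect_true(all(c("f02", "f03", "f05") %in% names(out)))  # 0.6 retained (strict <)
  man2 <- man[-1, ]
  expect_error(drop_low_icc(tab, man2, features = names(tab)), "f01")
})

test_that("the packaged manifest replays the printed preselection arithmetic", {
  man <- read_icc_manifest()
  reg <- default_registry()
  expect_equal(nrow(man), 143)
  expect_equal(sum(man$icc < 0.6), 22)
  expect_setequal(man$feature, reg$feature)
  # 143 - 22 = 121 features survive the ICC step on a full feature table
  tab <- as.data.frame(matrix(rnorm(10 * 143), 10, 143))
  names(tab) <- reg$feature
  out <- drop_low_icc(tab, man)
  expect_equal(ncol(out), 121)
})

test_that("redundancy pruning matches a brute-force all-pairs correlation scan", {
  set.seed(3)
  n <- 120
  conv <- data.frame(volume = rnorm(n), suv_max = rnorm(n), suv_peak = rnorm(n),
                     suv_mean = rnorm(n), tlg = rnorm(n))
  # features: some duplicates of conventional features plus noise
  feat <- data.frame(
    dup_vol = conv$volume + rnorm(n, 0, 0.05),
    dup_tlg = -conv$tlg + rnorm(n, 0, 0.05),
    mild = 0.5 * conv$suv_max + rnorm(n),
    noise1 = rnorm(n), noise2 = rnorm(n))
  tab <- cbind(conv, feat)
  out <- drop_conventional_redundant(tab)
  # oracle: all-pairs Pearson scan
  oracle_drop <- names(feat)[sapply(names(feat), function(f)
    any(abs(sapply(names(conv), function(cv) cor(tab[[f]], tab[[cv]]))) > 0.8))]
  expect_setequal(attr(out, "dropped"), oracle_drop)
  expect_true(all(names(conv) %in% names(out)))
  expect_true(all(c("noise1", "noise2") %in% names(out)))

  tab$flat <- rep(1, n)
  expect_warning(out2 <- drop_conventional_redundant(tab), "zero-variance")
  expect_true("flat" %in% names(out2))
})

test_that("PCA retains the minimal component set above 95% variance", {
  set.seed(4)
  n <- 200
  strong <- rnorm(n, 0, 10)
  tab <- data.frame(a = strong, b = strong + rnorm(n, 0, 0.1),
                    c = rnorm(n, 0, 0.1), d = rnorm(n, 0, 0.1))
  basis <- fit_pca(tab)
  expect_equal(basis$n_retained, 1)   # one direction carries ~99% variance
  expect_gt(cumsum(basis$explained)[basis$n_retained], 0.95)

  iso <- as.data.frame(matrix(rnorm(4000 * 10), 4000, 10))
  basis2 <- fit_pca(iso)
  expect_true(basis2$n_retained %in% c(9, 10))  # equal eigenvalues need ~ceil(.95 d)
  G <- t(basis2$rotation) %*% basis2$rotation
  expect_equal(G, diag(basis2$n_retained), tolerance = 1e-9, ignore_attr = TRUE)

  sc <- project_pca(basis, tab)
  expect_equal(ncol(sc), 1)
  expect_equal(var(sc$PC01) / sum(apply(tab, 2, var)),
               basis$explained[1], tolerance = 1e-9)
  expect_error(fit_pca(tab[1, , drop = FALSE]), "2 samples")
})

test_that("every filter ranks a perfectly separating feature first", {
  set.seed(5)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  tab <- make_named_table(n = n, p = 6, seed = 5)
  tab$signal <- y * 4 + rnorm(n, 0, 0.1)
  for (m in c("logistic", "anova", "fisher", "relief", "t_score", "gini")) {
    r <- rank_features(tab, y, method = m)
    expect_equal(r$feature[1], "signal", info = m)
  }
})

test_that("filter scores equal their direct formula oracles", {
  set.seed(6)
  n <- 40
  y <- rbinom(n, 1, 0.4)
  if (sum(y) < 2) y[1:2] <- 1
  x <- rnorm(n) + y
  tab <- data.frame(x = x)

  r_t <- rank_features(tab, y, method = "t_score")$score[1]
  expect_equal(r_t, abs(unname(t.test(x[y == 1], x[y == 0])$statistic)),
               tolerance = 1e-9)

  r_a <- rank_features(tab, y, method = "anova")$score[1]
  expect_equal(r_a, unname(summary(aov(x ~ factor(y)))[[1]]$`F value`[1]),
               tolerance = 1e-9)

  r_f <- rank_features(tab, y, method = "fisher")$score[1]
  mu <- mean(x); num <- 0; den <- 0
  for (cl in 0:1) {
    xi <- x[y == cl]
    num <- num + length(xi) * (mean(xi) - mu)^2
    den <- den + length(xi) * mean((xi - mean(xi))^2)
  }
  expect_equal(r_f, num / den, tolerance = 1e-12)

  r_l <- rank_features(tab, y, method = "logistic")$score[1]
  sm <- summary(glm(y ~ x, family = binomial()))$coefficients
  expect_equal(r_l, abs(sm[2, 3]), tolerance = 1e-9)

  # gini: oracle by scanning all midpoints
  gini <- function(p) 2 * p * (1 - p)
  xs <- sort(unique(x))
  gains <- sapply(head(xs, -1) + diff(xs) / 2, function(thr) {
    l <- y[x <= thr]; r <- y[x > thr]
    gini(mean(y)) - length(l) / n * gini(mean(l)) - length(r) / n * gini(mean(r))
  })
  r_g <- rank_features(tab, y, method = "gini")$score[1]
  expect_equal(r_g, max(gains), tolerance = 1e-12)
})

test_that("label-independent features score near the null for every filter", {
  set.seed(7)
  n <- 100
  y <- rep(c(0, 1), each = n / 2)
  tab <- make_named_table(n = n, p = 5, seed = 77)
  for (m in c("t_score", "anova", "fisher")) {
    r <- rank_features(tab, y, method = m)
    expect_lt(max(r$score), 12, label = m)  # no spuriously extreme score
  }
  # zero-variance features score 0 and sort by name among ties
  tab$zzz_flat <- 1
  tab$aaa_flat <- 1
  r <- rank_features(tab, y, method = "fisher")
  expect_equal(r$score[r$feature %in% c("zzz_flat", "aaa_flat")], c(0, 0))
  ties <- r$feature[r$score == 0]
  expect_identical(ties, sort(ties))
})

test_that("LASSO support shrinks with the penalty and hits the stated limits", {
  set.seed(8)
  n <- 100
  y <- rep(c(0, 1), each = n / 2)
  tab <- data.frame(s1 = y + rnorm(n, 0, 0.4), s2 = y + rnorm(n, 0, 0.4),
                    n1 = rnorm(n), n2 = rnorm(n))
  expect_length(lasso_select(tab, y, lambda = 10), 0)          # full shrinkage
  low <- lasso_select(tab, y, lambda = 1e-4)
  expect_true(all(c("s1", "s2") %in% low))                     # unpenalized limit
  sizes <- sapply(c(1e-4, 0.01, 0.05, 0.2, 1), function(l)
    length(lasso_select(tab, y, lambda = l)))
  expect_true(all(diff(sizes) <= 0))                           # monotone path
  expect_error(lasso_select(tab, y, lambda = 0), "positive")
  sel <- lasso_select_cv(tab, y, seed = 3)
  expect_gte(length(sel), 1)
})

test_that("the strategy grid enumerates 24 distinct strategies (144 pipelines)", {
  s <- enumerate_strategies()
  expect_equal(nrow(s), 24)
  expect_equal(nrow(unique(s)), 24)
  expect_equal(anyDuplicated(s$strategy_id), 0)
  expect_equal(sort(unique(s$filter)),
               sort(c("logistic", "anova", "fisher", "relief", "t_score", "gini")))
  expect_equal(nrow(s) * length(petromics:::.classifier_names()), 144)
})
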