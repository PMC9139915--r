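test_that("stratified 70/30 split reproduces the cohort arithmetic", {
  labels <- c(rep(1, 57), rep(0, 142))
  sp <- split_cohort(labels, test_fraction = 0.3, seed = 4)
  expect_length(sp$train, 139)
  expect_length(sp$test, 60)
  expect_equal(sum(labels[sp$train]), 40)   # round(57 * 0.7)
  expect_equal(sum(labels[sp$test]), 17)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  sp2 <- split_cohort(labels, test_fraction = 0.3, seed = 4)
  expect_identical(sp, sp2)
  expect_error(split_cohort(c(1, 0, 0, 0)), "at least 2")
})

test_that("repeated stratified CV yields 10 folds with balanced prevalence", {
  labels <- rbinom(80, 1, 0.3)
  labels[1:10] <- 1
  cfg <- cv_config(n_folds = 2, n_repeats = 5, seed = 3)
  folds <- petromics:::.make_cv_folds(labels, cfg)
  expect_length(folds, 10)
  global_rate <- mean(labels)
  for (f in folds) {
    expect_setequal(c(f$train, f$val), seq_along(labels))
    n_val_pos <- sum(labels[f$val])
    expected <- global_rate * length(f$val)
    expect_lte(abs(n_val_pos - expected), 1)  # within one sample of global rate
  }
})

test_that("cross_validate returns 10 scores and reacts to planted signal", {
  tab_null <- generate_feature_table(120, n_features = 8, planted_features = 0,
                                     prevalence = 0.3, seed = 5)
  pl <- list(use_pca = FALSE, filter = "anova", use_lasso = FALSE,
             classifier = "logistic", k = 5)
  r <- cross_validate(pl, tab_null, cv = cv_config(seed = 2),
                      preselect = tabular_preselect(), seed = 1)
  expect_length(r$fold_ap, 10)
  expect_lt(r$mean_ap, 0.55)

  tab_sig <- generate_feature_table(120, n_features = 8, planted_features = 3,
                                    effect_sd = 2, prevalence = 0.3, seed = 5)
  r2 <- cross_validate(pl, tab_sig, cv = cv_config(seed = 2),
                       preselect = tabular_preselect(), seed = 1)
  expect_gt(r2$mean_ap, r$mean_ap + 0.2)
})

test_that("the tuned leaderboard covers all 144 pipelines deterministically", {
  tab <- generate_feature_table(90, n_features = 12, planted_features = 3,
                                effect_sd = 1.5, prevalence = 0.3, seed = 9)
  lb1 <- tune_and_rank(tab, cv = cv_config(n_repeats = 2, seed = 4),
                       grids = pipeline_grids("reduced"),
                       preselect = tabular_preselect(), seed = 6)
  expect_equal(nrow(lb1), 144)
  expect_setequal(unique(lb1$classifier), petromics:::.classifier_names())
  expect_equal(length(unique(lb1$strategy_id)), 24)
  expect_true(all(diff(lb1$mean_ap) <= 1e-12))
  lb2 <- tune_and_rank(tab, cv = cv_config(n_repeats = 2, seed = 4),
                       grids = pipeline_grids("reduced"),
                       preselect = tabular_preselect(), seed = 6)
  expect_identical(as.data.frame(lb1), as.data.frame(lb2))
})

test_that("soft voting averages member probabilities", {
  tab <- generate_feature_table(80, n_features = 6, planted_features = 2,
                                effect_sd = 2, prevalence = 0.3, seed = 3)
  presel <- tabular_preselect()
  pl1 <- list(use_pca = FALSE, filter = "anova", use_lasso = FALSE,
              classifier = "logistic", k = 3)
  pl2 <- list(use_pca = FALSE, filter = "t_score", use_lasso = FALSE,
              classifier = "naive_bayes", k = 3)
  m1 <- fit_final(pl1, tab, preselect = presel, seed = 1)
  m2 <- fit_final(pl2, tab, preselect = presel, seed = 1)
  p1 <- predict(m1, tab); p2 <- predict(m2, tab)
  pv <- soft_vote(list(m1, m2), tab)
  expect_equal(pv, (p1 + p2) / 2, tolerance = 1e-12)
  expect_true(all(pv >= 0 & pv <= 1))
  # identical members reproduce the single member
  expect_equal(soft_vote(list(m1, m1), tab), p1, tolerance = 1e-12)
})

test_that("every classifier backend emits valid probabilities", {
  tab <- generate_feature_table(60, n_features = 5, planted_features = 2,
                                effect_sd = 1.5, prevalence = 0.4, seed = 2)
  X <- tab[, -1]; y <- tab$label
  for (clf in petromics:::.classifier_names()) {
    fit <- fit_classifier(clf, X, y, hyper = classifier_grids("reduced")[[clf]][1, , drop = FALSE],
                          seed = 3)
    p <- predict_prob(fit, X)
    expect_length(p, nrow(X))
    expect_true(all(p >= 0 & p <= 1), info = clf)
    expect_gt(roc_auc(y, p), 0.5)  # separable data: better than chance in-sample
  }
})

test_that("resubstitution optimism: training AP exceeds cross-validated AP", {
  tab <- generate_feature_table(120, n_features = 10, planted_features = 2,
                                effect_sd = 1, prevalence = 0.3, seed = 12)
  pl <- list(use_pca = FALSE, filter = "t_score", use_lasso = FALSE,
             classifier = "random_forest", k = 5,
             hyper = data.frame(num_trees = 100, max_depth = 0))
  presel <- tabular_preselect()
  cvres <- cross_validate(pl, tab, cv = cv_config(seed = 1), preselect = presel, seed = 2)
  m <- fit_final(pl, tab, preselect = presel, seed = 2)
  ap_train <- ap_score(tab$label, predict(m, tab))
  expect_gte(ap_train, cvres$mean_ap)
})

test_that("no fitting call ever touches test rows (leakage audit)", {
  tab <- generate_feature_table(100, n_features = 10, planted_features = 2,
                                effect_sd = 1.5, prevalence = 0.3, seed = 8)
  rownames(tab) <- sprintf("row%03d", seq_len(nrow(tab)))
  sp <- split_cohort(tab$label, seed = 2)
  train_tab <- tab[sp$train, ]
  test_tab <- tab[sp$test, ]
  presel <- tabular_preselect()
  audit_start()
  lb <- tune_and_rank(train_tab, cv = cv_config(n_repeats = 1, seed = 1),
                      grids = pipeline_grids("reduced"), preselect = presel,
                      strategies = enumerate_strategies()[c(1, 8, 20), ], seed = 3)
  m <- fit_final(as.list(lb[1, ]), train_tab, preselect = presel,
                 grids = pipeline_grids("reduced"), seed = 3)
  scores <- predict(m, test_tab)
  audit_stop()
  seen <- audit_rows_seen()
  expect_gt(length(seen), 0)
  expect_true(all(seen %in% rownames(train_tab)))
  expect_false(any(rownames(test_tab) %in% seen))
  expect_equal(length(scores), nrow(test_tab))
})

test_that("learning-curve validation AP grows with n and matches full-size CV", {
  tab <- generate_feature_table(160, n_features = 8, planted_features = 3,
                                effect_sd = 2, prevalence = 0.3, seed = 4)
  pl <- list(use_pca = FALSE, filter = "anova", use_lasso = FALSE,
             classifier = "logistic", k = 3)
  presel <- tabular_preselect()
  lc <- learning_curve(pl, tab, sizes = c(40, 160), cv = cv_config(seed = 9),
                       preselect = presel, seed = 5)
  expect_equal(nrow(lc), 2)
  expect_gte(lc$val_ap[2], lc$val_ap[1] - 0.05)   # grows (statistical direction)
  expect_true(all(lc$train_ap >= lc$val_ap - 0.05))  # optimism at every size
  full <- cross_validate(pl, tab, cv = cv_config(seed = 9), preselect = presel, seed = 5)
  expect_equal(lc$val_ap[2], full$mean_ap, tolerance = 1e-12)
})
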