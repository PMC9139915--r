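#' Load the packaged ICC reproducibility manifest
#'
#' Multivendor reproducibility (intraclass correlation coefficient) per
#' registry feature. The packaged default is a synthetic stand-in — the
#' clinical multivendor ICC study underlying the original preselection is not
#' publicly deposited — constructed so that exactly 22 of the 143 registry
#' features fall below the 0.6 cutoff. Users with real ICC estimates should
#' supply their own CSV (columns `feature`, `icc`).
#'
#' @param path CSV path; default is the packaged synthetic manifest.
#' @return Data frame with columns `feature` and `icc`.
#' @export
read_icc_manifest <- function(path = system.file("extdata", "icc_manifest_synthetic.csv",
                                                 package = "petromics")) {
  if (!nzchar(path) || !file.exists(path)) .stopf("ICC manifest not found: '%s'", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("feature", "icc") %in% names(man)))
    .stopf("ICC manifest needs columns 'feature' and 'icc'")
  man
}

#' Drop radiomic features with low multivendor reproducibility
#'
#' Removes every feature whose manifest ICC is strictly below the cutoff
#' (a feature at exactly the cutoff is retained). The removal is recorded in
#' the `"dropped"` attribute of the returned table.
#'
#' @param table Feature table (patients x features).
#' @param icc_manifest Data frame mapping `feature` to `icc`.
#' @param features Columns to screen (default: all manifest-covered columns
#'   present); every screened column must appear in the manifest.
#' @param cutoff ICC cutoff (default 0.6).
#' @return The table without the low-ICC columns.
#' @export
drop_low_icc <- function(table, icc_manifest, features = NULL, cutoff = 0.6) {
  if (is.null(features)) features <- intersect(names(table), icc_manifest$feature)
  missing <- setdiff(features, icc_manifest$feature)
  if (length(missing) > 0)
    .stopf("ICC manifest lacks entries for: %s", paste(missing, collapse = ", "))
  icc <- icc_manifest$icc[match(features, icc_manifest$feature)]
  drop <- features[icc < cutoff]
  out <- table[, setdiff(names(table), drop), drop = FALSE]
  attr(out, "dropped") <- drop
  out
}

#' Drop features redundant with the conventional PET metrics
#'
#' Any non-conventional radiomic feature whose absolute Pearson correlation
#' with at least one conventional feature (volume, SUVmax, SUVpeak, SUVmean,
#' TLG) exceeds `rho` is removed; the conventional features themselves are
#' always retained. Intended to run on the normalized training table. A
#' zero-variance feature has undefined correlation and is retained with a
#' warning.
#'
#' @param table Normalized feature table (training rows).
#' @param conventional_names Conventional feature columns (default
#'   [conventional_features()] intersected with the table).
#' @param features Radiomic columns to screen (default: all numeric columns
#'   except label/clinical/conventional).
#' @param rho Correlation cutoff (default 0.8, strict `>`).
#' @return The table without the redundant columns (`"dropped"` attribute
#'   lists them).
#' @export
drop_conventional_redundant <- function(table, conventional_names = NULL,
                                        features = NULL, rho = 0.8) {
  if (is.null(conventional_names))
    conventional_names <- intersect(conventional_features(), names(table))
  if (length(conventional_names) == 0) .stopf("no conventional feature columns present")
  if (is.null(features))
    features <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                        c("label", "t_stage", "n_stage", conventional_names))
  X <- as.matrix(table[, features, drop = FALSE])
  C <- as.matrix(table[, conventional_names, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  zv <- sds == 0 | !is.finite(sds)
  if (any(zv))
    .warnf("zero-variance feature(s) have undefined correlation and are retained: %s",
           paste(features[zv], collapse = ", "))
  drop <- character(0)
  if (any(!zv)) {
    cc <- suppressWarnings(stats::cor(X[, !zv, drop = FALSE], C))
    cc[!is.finite(cc)] <- 0
    redundant <- apply(abs(cc) > rho, 1, any)
    drop <- rownames(cc)[redundant]
  }
  out <- table[, setdiff(names(table), drop), drop = FALSE]
  attr(out, "dropped") <- drop
  out
}

#' Principal component basis retaining > 95% variance
#'
#' Fits PCA on the training rows (centred, not re-scaled: inputs are assumed
#' normalized) and retains the minimal number of leading components whose
#' cumulative explained variance exceeds the threshold.
#'
#' @param train_table Data frame (numeric feature columns only).
#' @param features Columns to use (default: all numeric).
#' @param var_threshold Cumulative explained-variance threshold (default 0.95).
#' @return A `pca_basis`: rotation, centring, explained-variance fractions,
#'   `n_retained`.
#' @export
fit_pca <- function(train_table, features = NULL, var_threshold = 0.95) {
  if (is.null(features)) features <- names(train_table)[vapply(train_table, is.numeric, TRUE)]
  X <- as.matrix(train_table[, features, drop = FALSE])
  if (nrow(X) < 2) .stopf("PCA needs at least 2 samples")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  evf <- pr$sdev^2 / sum(pr$sdev^2)
  n_ret <- which(cumsum(evf) > var_threshold)[1]
  structure(list(rotation = pr$rotation[, seq_len(n_ret), drop = FALSE],
                 center = pr$center, explained = evf, n_retained = n_ret,
                 features = features, var_threshold = var_threshold),
            class = "pca_basis")
}

#' @param basis A `pca_basis` from [fit_pca()].
#' @param table Data frame containing the basis features.
#' @rdname fit_pca
#' @return `project_pca()` returns a data frame of component scores
#'   (`PC01`, `PC02`, ...).
#' @export
project_pca <- function(basis, table) {
  stopifnot(inherits(basis, "pca_basis"))
  X <- as.matrix(table[, basis$features, drop = FALSE])
  S <- sweep(X, 2, basis$center) %*% basis$rotation
  out <- as.data.frame(S)
  names(out) <- sprintf("PC%02d", seq_len(ncol(S)))
  out
}

#' Univariable filter rankings
#'
#' Ranks features by one of six univariable filter statistics:
#' * `logistic` — absolute Wald z of a single-feature logistic regression;
#' * `anova` — one-way ANOVA F statistic;
#' * `fisher` — Fisher score
#'   `sum(n_c (mu_c - mu)^2) / sum(n_c sigma_c^2)` over the two classes;
#' * `relief` — ReliefF weight with `k` nearest hits/misses (Manhattan
#'   distance on range-scaled features, all instances used);
#' * `t_score` — absolute Welch t statistic;
#' * `gini` — best single-threshold Gini impurity decrease.
#'
#' Scores are sorted descending; ties (including the all-zero scores of
#' label-independent degenerate features) are broken lexicographically by
#' feature name, making the ranking deterministic. A zero-variance feature
#' scores 0 for every method.
#'
#' @param table Data frame of numeric features.
#' @param labels Binary labels (0/1), one per row.
#' @param method One of `"logistic"`, `"anova"`, `"fisher"`, `"relief"`,
#'   `"t_score"`, `"gini"`.
#' @param k Neighbours for ReliefF (default 10).
#' @return Data frame `feature`, `score`, ordered by decreasing score.
#' @export
rank_features <- function(table, labels,
                          method = c("logistic", "anova", "fisher", "relief",
                                     "t_score", "gini"),
                          k = 10L) {
  method <- match.arg(method)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) .stopf("both classes must be present")
  feats <- names(table)[vapply(table, is.numeric, TRUE)]
  X <- as.matrix(table[, feats, drop = FALSE])
  zv <- apply(X, 2, function(v) stats::sd(v) == 0)
  score <- numeric(length(feats))
  idx_ok <- which(!zv)
  if (method == "relief") {
    if (length(idx_ok) > 0)
      score[idx_ok] <- .relieff(X[, idx_ok, drop = FALSE], labels, k = k)
  } else {
    scorer <- switch(method,
      logistic = function(x) {
        fit <- suppressWarnings(stats::glm(labels ~ x, family = stats::binomial()))
        if (fit$deviance < 1e-6) return(Inf)  # perfect separation: Wald z collapses
        s <- summary(fit)$coefficients
        if (nrow(s) < 2 || !is.finite(s[2, 3])) 0 else abs(s[2, 3])
      },
      anova = function(x) {
        f <- stats::anova(stats::lm(x ~ factor(labels)))[["F value"]][1]
        if (is.finite(f)) f else 0
      },
      fisher = function(x) {
        num <- 0; den <- 0; mu <- mean(x)
        for (cl in c(0L, 1L)) {
          xi <- x[labels == cl]; nc <- length(xi)
          num <- num + nc * (mean(xi) - mu)^2
          den <- den + nc * mean((xi - mean(xi))^2)
        }
        if (den > 0) num / den else if (num > 0) Inf else 0
      },
      t_score = function(x) {
        tt <- tryCatch(stats::t.test(x[labels == 1], x[labels == 0])$statistic,
                       error = function(e) NA_real_)
        if (is.finite(tt)) abs(unname(tt)) else 0
      },
      gini = function(x) .gini_gain(x, labels))
    for (j in idx_ok) score[j] <- scorer(X[, j])
  }
  ord <- order(-score, feats, method = "radix")
  data.frame(feature = feats[ord], score = score[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

# Best single-threshold Gini impurity decrease for one feature.
.gini_gain <- function(x, y) {
  n <- length(y)
  ord <- order(x, method = "radix")
  xs <- x[ord]; ys <- y[ord]
  cum_pos <- cumsum(ys)
  pos <- sum(ys)
  gini <- function(p) 2 * p * (1 - p)
  parent <- gini(pos / n)
  cut_ok <- which(diff(xs) > 0)  # split between distinct values only
  if (length(cut_ok) == 0) return(0)
  nl <- cut_ok
  pl <- cum_pos[cut_ok] / nl
  nr <- n - nl
  pr <- (pos - cum_pos[cut_ok]) / nr
  child <- (nl / n) * gini(pl) + (nr / n) * gini(pr)
  max(parent - child)
}

# ReliefF weights: every instance is used; k nearest hits and misses by
# Manhattan distance; feature differences scaled by feature range.
.relieff <- function(X, y, k = 10L) {
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  Xs <- sweep(X, 2, rng, "/")
  D <- as.matrix(stats::dist(Xs, method = "manhattan"))
  diag(D) <- Inf
  W <- numeric(p)
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    diff_ <- which(y != y[i])
    kh <- min(k, length(same)); km <- min(k, length(diff_))
    if (kh == 0 || km == 0) next
    hits <- same[order(D[i, same], same, method = "radix")][seq_len(kh)]
    miss <- diff_[order(D[i, diff_], diff_, method = "radix")][seq_len(km)]
    dh <- abs(sweep(Xs[hits, , drop = FALSE], 2, Xs[i, ]))
    dm <- abs(sweep(Xs[miss, , drop = FALSE], 2, Xs[i, ]))
    W <- W - colMeans(dh) / n + colMeans(dm) / n
  }
  W
}

#' LASSO feature selection
#'
#' Support (non-zero coefficients) of an L1-penalized logistic regression.
#' `lasso_select()` evaluates a given penalty; `lasso_select_cv()` tunes the
#' penalty by internal cross-validation on the supplied (training) rows and
#' returns the selected support. An empty support falls back to the single
#' feature with the largest maximal absolute coefficient along the path, so a
#' downstream classifier always has at least one input.
#'
#' @param table Data frame of normalized numeric features.
#' @param labels Binary labels (0/1).
#' @param lambda Penalty (> 0) for `lasso_select()`.
#' @param nfolds Internal CV folds for `lasso_select_cv()` (default 3).
#' @param seed Seed controlling the internal fold assignment.
#' @return Character vector of selected feature names.
#' @export
lasso_select <- function(table, labels, lambda) {
  if (lambda <= 0) .stopf("lasso penalty must be positive")
  X <- as.matrix(table[, vapply(table, is.numeric, TRUE), drop = FALSE])
  fit <- glmnet::glmnet(X, factor(labels, levels = c(0, 1)), family = "binomial",
                        lambda = lambda, standardize = FALSE)
  beta <- as.matrix(fit$beta)
  colnames(X)[beta[, 1] != 0]
}

#' @rdname lasso_select
#' @export
lasso_select_cv <- function(table, labels, nfolds = 3L, seed = 1L) {
  X <- as.matrix(table[, vapply(table, is.numeric, TRUE), drop = FALSE])
  if (ncol(X) < 2) return(colnames(X))
  y <- factor(labels, levels = c(0, 1))
  set.seed(seed)
  foldid <- .stratified_fold_ids(as.integer(labels), nfolds)
  cv <- tryCatch(
    glmnet::cv.glmnet(X, y, family = "binomial", foldid = foldid,
                      standardize = FALSE, type.measure = "deviance"),
    error = function(e) NULL)
  if (is.null(cv)) return(colnames(X))
  beta <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
  sel <- names(beta)[beta != 0]
  if (length(sel) == 0) {
    path <- glmnet::glmnet(X, y, family = "binomial", standardize = FALSE)
    strongest <- rownames(path$beta)[which.max(apply(abs(path$beta), 1, max))]
    sel <- strongest
  }
  sel
}

# Stratified fold ids (round-robin within shuffled class blocks).
.stratified_fold_ids <- function(labels, nfolds) {
  ids <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    ids[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  ids
}

#' Enumerate the 24 feature-selection strategies
#'
#' The full `{PCA on/off} x {6 univariable filters} x {LASSO on/off}` grid in
#' a deterministic order. Combined with the six classifiers this yields the
#' 144-pipeline model grid.
#'
#' @return Data frame with columns `strategy_id`, `use_pca`, `filter`,
#'   `use_lasso` (24 rows).
#' @export
enumerate_strategies <- function() {
  filters <- c("logistic", "anova", "fisher", "relief", "t_score", "gini")
  g <- expand.grid(use_lasso = c(FALSE, TRUE), filter = filters,
                   use_pca = c(FALSE, TRUE), stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("use_pca", "filter", "use_lasso")]
  g$strategy_id <- sprintf("%s_%s_%s", ifelse(g$use_pca, "pca", "raw"),
                           g$filter, ifelse(g$use_lasso, "lasso", "nolasso"))
  g[, c("strategy_id", "use_pca", "filter", "use_lasso")]
}
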