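# Model training: stratified splitting, the 144-pipeline cross-validated
# sweep ranked by mean average precision, final fits and soft voting.

## ---- leakage audit -------------------------------------------------------

.audit_env <- new.env(parent = emptyenv())
.audit_env$enabled <- FALSE
.audit_env$rows <- character(0)

#' Leakage audit of fitting calls
#'
#' When enabled, every fitting routine (normalization-plan fit, PCA fit,
#' filter ranking, LASSO selection, classifier fit) records the row names of
#' the table it was fitted on. Comparing the recorded set against the
#' training indices proves that no test-row statistic was touched before
#' final evaluation.
#'
#' @return `audit_rows_seen()` returns the sorted unique row names recorded
#'   since `audit_start()`.
#' @export
audit_start <- function() {
  .audit_env$enabled <- TRUE
  .audit_env$rows <- character(0)
  invisible(TRUE)
}

#' @rdname audit_start
#' @export
audit_stop <- function() {
  .audit_env$enabled <- FALSE
  invisible(TRUE)
}

#' @rdname audit_start
#' @export
audit_rows_seen <- function() sort(unique(.audit_env$rows))

.audit_record <- function(rows) {
  if (isTRUE(.audit_env$enabled) && !is.null(rows))
    .audit_env$rows <- c(.audit_env$rows, as.character(rows))
  invisible(NULL)
}

## ---- splitting and folds -------------------------------------------------

#' Stratified train/test split
#'
#' Randomly partitions the cohort with preservation of the class
#' distribution: per class, `round(n_class * test_fraction)` samples go to
#' the test subset (proportional rounding), the rest to training.
#'
#' @param labels Binary labels (0/1); each class needs >= 2 members.
#' @param test_fraction Test fraction (default 0.3).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_cohort <- function(labels, test_fraction = 0.3, seed = 1L) {
  labels <- as.integer(labels)
  if (any(table(labels) < 2)) .stopf("each class needs at least 2 members to split")
  set.seed(seed)
  test_idx <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    n_test <- round(length(idx) * test_fraction)
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  list(train = sort(setdiff(seq_along(labels), test_idx)), test = sort(test_idx))
}

#' Cross-validation configuration
#'
#' Stratified `n_folds`-fold cross-validation repeated `n_repeats` times
#' (default 2 x 5 = 10 validation scores per pipeline).
#' @param n_folds Folds per repeat (default 2).
#' @param n_repeats Repeats (default 5).
#' @param seed Integer seed for fold shuffling.
#' @return A `cv_config` list.
#' @export
cv_config <- function(n_folds = 2L, n_repeats = 5L, seed = 1L) {
  structure(list(n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)), class = "cv_config")
}

# Stratified repeated folds: list of list(train, val) index pairs.
.make_cv_folds <- function(labels, cfg) {
  labels <- as.integer(labels)
  folds <- list()
  for (r in seq_len(cfg$n_repeats)) {
    set.seed(.sub_seed(cfg$seed, r))
    fid <- .stratified_fold_ids(labels, cfg$n_folds)
    for (f in seq_len(cfg$n_folds)) {
      val <- which(fid == f)
      folds[[length(folds) + 1L]] <- list(train = which(fid != f), val = val,
                                          repeat_id = r, fold_id = f)
    }
  }
  folds
}

## ---- preprocessing within a training subset ------------------------------

#' Encode clinical covariates for modelling
#'
#' Histology becomes a binary adenocarcinoma indicator; clinical T- and
#' N-stage are kept as integer ordinals (T4a encoded as 4), preserving their
#' order.
#'
#' @param table Cohort feature table with `histology`, `t_stage`, `n_stage`.
#' @return The table with `histology` replaced by `histology_adeno`.
#' @export
encode_clinical <- function(table) {
  if ("histology" %in% names(table)) {
    table$histology_adeno <- as.integer(table$histology == "adenocarcinoma")
    table$histology <- NULL
  }
  table
}

.clinical_cols <- function(table)
  intersect(c("histology_adeno", "t_stage", "n_stage"), names(table))

#' Preselection configuration
#'
#' Controls the strategy-independent cascade head: manifest-based ICC
#' preselection and redundancy pruning against the conventional features.
#' Both default on when the relevant columns/manifest are available; tabular
#' synthetic studies can switch them off.
#'
#' @param icc_manifest Data frame (`feature`, `icc`) or `NULL` to skip.
#' @param icc_cutoff ICC cutoff (default 0.6).
#' @param redundancy Logical: prune features correlated with the
#'   conventional set (default `TRUE` when conventional columns exist).
#' @param redundancy_rho Correlation cutoff (default 0.8).
#' @return A `preselect_config` list.
#' @export
preselect_config <- function(icc_manifest = NULL, icc_cutoff = 0.6,
                             redundancy = TRUE, redundancy_rho = 0.8) {
  structure(list(icc_manifest = icc_manifest, icc_cutoff = icc_cutoff,
                 redundancy = redundancy, redundancy_rho = redundancy_rho),
            class = "preselect_config")
}

# Fit the strategy-independent head of the cascade on training rows:
# ICC drop -> normalization plan -> redundancy drop. Returns the fitted
# constants plus the transformed training design.
.fit_preproc <- function(train_table, cfg) {
  tab <- train_table
  counts <- list()
  feat_all <- setdiff(names(tab)[vapply(tab, is.numeric, TRUE)],
                      c("label", .clinical_cols(tab)))
  counts$n_input <- length(feat_all)
  if (!is.null(cfg$icc_manifest)) {
    screened <- intersect(feat_all, cfg$icc_manifest$feature)
    tab2 <- drop_low_icc(tab, cfg$icc_manifest, features = screened,
                         cutoff = cfg$icc_cutoff)
    icc_dropped <- attr(tab2, "dropped")
    tab <- tab2
  } else icc_dropped <- character(0)
  feat <- setdiff(feat_all, icc_dropped)
  counts$n_after_icc <- length(feat)
  plan <- fit_normalization_plan(tab, features = feat)
  .audit_record(rownames(train_table))
  tab <- apply_normalization_plan(plan, tab)
  conv <- intersect(conventional_features(), feat)
  if (isTRUE(cfg$redundancy) && length(conv) > 0) {
    tab2 <- drop_conventional_redundant(tab, conventional_names = conv,
                                        features = setdiff(feat, conv),
                                        rho = cfg$redundancy_rho)
    red_dropped <- attr(tab2, "dropped")
    tab <- tab2
  } else red_dropped <- character(0)
  feat <- setdiff(feat, red_dropped)
  counts$n_after_redundancy <- length(feat)
  model_cols <- c(feat, .clinical_cols(train_table))
  structure(list(plan = plan, icc_dropped = icc_dropped,
                 red_dropped = red_dropped, model_cols = model_cols,
                 counts = counts,
                 train_X = tab[, model_cols, drop = FALSE]),
            class = "petromics_preproc")
}

.apply_preproc <- function(pp, table) {
  tab <- apply_normalization_plan(pp$plan, table)
  tab[, pp$model_cols, drop = FALSE]
}

## ---- the pipeline sweep --------------------------------------------------

# Evaluate every (strategy, classifier, hyper, k) cell on one fold.
# Returns a data frame of AP scores (validation and resubstitution).
.sweep_fold <- function(tr, va, ytr, yva, cfg, grids, seed, strategies,
                        with_train_ap = FALSE) {
  pp <- .fit_preproc(tr, cfg)
  Xtr <- pp$train_X
  Xva <- .apply_preproc(pp, va)
  need_pca <- any(strategies$use_pca)
  if (need_pca) {
    basis <- fit_pca(Xtr)
    .audit_record(rownames(tr))
    Xtr_p <- project_pca(basis, Xtr)
    Xva_p <- project_pca(basis, Xva)
  }
  out <- list()
  for (variant in unique(strategies$use_pca)) {
    Xt <- if (variant) Xtr_p else Xtr
    Xv <- if (variant) Xva_p else Xva
    strat_v <- strategies[strategies$use_pca == variant, , drop = FALSE]
    for (flt in unique(strat_v$filter)) {
      ranking <- rank_features(Xt, ytr, method = flt)
      .audit_record(rownames(tr))
      for (k in grids$k_grid) {
        sel_k <- ranking$feature[seq_len(min(k, nrow(ranking)))]
        for (lasso in unique(strat_v$use_lasso[strat_v$filter == flt])) {
          sel <- if (lasso) {
            lasso_select_cv(Xt[, sel_k, drop = FALSE], ytr, seed = seed)
          } else sel_k
          if (lasso) .audit_record(rownames(tr))
          sid <- sprintf("%s_%s_%s", if (variant) "pca" else "raw", flt,
                         if (lasso) "lasso" else "nolasso")
          for (clf in names(grids$classifiers)) {
            hgrid <- grids$classifiers[[clf]]
            for (h in seq_len(nrow(hgrid))) {
              fit <- tryCatch(
                fit_classifier(clf, Xt[, sel, drop = FALSE], ytr,
                               hyper = hgrid[h, , drop = FALSE], seed = seed),
                error = function(e) NULL)
              if (is.null(fit)) { ap_va <- NA_real_; ap_tr <- NA_real_ }
              else {
                p_va <- predict_prob(fit, Xv[, sel, drop = FALSE])
                ap_va <- ap_score(yva, p_va)
                ap_tr <- if (with_train_ap)
                  ap_score(ytr, predict_prob(fit, Xt[, sel, drop = FALSE]))
                else NA_real_
              }
              out[[length(out) + 1L]] <- data.frame(
                strategy_id = sid, classifier = clf, hyper_id = h,
                k = k, ap = ap_va, ap_train = ap_tr,
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Cross-validate and rank the full pipeline grid
#'
#' Runs stratified repeated cross-validation over every combination of the
#' 24 feature-selection strategies and the 6 classifiers (144 pipelines).
#' Inside each fold the entire cascade — normalization, redundancy pruning,
#' PCA, filter ranking, LASSO, classifier — is refit on that fold's training
#' half. Per pipeline, the hyperparameter cell (filter cut `k` plus
#' classifier hyperparameters) with the best mean validation AP is kept; the
#' leaderboard is sorted by decreasing mean AP with deterministic
#' lexicographic tie-breaks.
#'
#' @param table Model table: numeric feature columns plus `label` (see
#'   [encode_clinical()]).
#' @param cv CV configuration from [cv_config()].
#' @param grids Grids from [pipeline_grids()].
#' @param preselect A [preselect_config()].
#' @param strategies Strategy subset (default [enumerate_strategies()]).
#' @param seed Seed for stochastic learners and internal LASSO folds.
#' @return A `model_leaderboard` data frame: `strategy_id`, `classifier`,
#'   `k`, `hyper_id`, `mean_ap`, `sd_ap`, `rank`.
#' @export
tune_and_rank <- function(table, cv = cv_config(),
                          grids = pipeline_grids("default"),
                          preselect = preselect_config(),
                          strategies = enumerate_strategies(), seed = 1L) {
  y <- as.integer(table$label)
  folds <- .make_cv_folds(y, cv)
  res <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    r <- .sweep_fold(table[f$train, , drop = FALSE], table[f$val, , drop = FALSE],
                     y[f$train], y[f$val], preselect, grids,
                     seed = .sub_seed(seed, i), strategies = strategies)
    r$fold <- i
    res[[i]] <- r
  }
  all <- do.call(rbind, res)
  key <- interaction(all$strategy_id, all$classifier, all$hyper_id, all$k, drop = TRUE)
  agg <- do.call(rbind, lapply(split(all, key), function(d) {
    data.frame(strategy_id = d$strategy_id[1], classifier = d$classifier[1],
               hyper_id = d$hyper_id[1], k = d$k[1],
               mean_ap = mean(d$ap, na.rm = TRUE),
               sd_ap = stats::sd(d$ap, na.rm = TRUE),
               n_failed = sum(is.na(d$ap)),
               stringsAsFactors = FALSE)
  }))
  # best hyper cell per pipeline: max mean AP, ties -> smaller k, hyper order
  best <- do.call(rbind, lapply(
    split(agg, interaction(agg$strategy_id, agg$classifier, drop = TRUE)),
    function(d) d[order(-d$mean_ap, d$k, d$hyper_id, method = "radix")[1], , drop = FALSE]))
  best <- best[order(-best$mean_ap, best$strategy_id, best$classifier,
                     method = "radix"), , drop = FALSE]
  best$rank <- seq_len(nrow(best))
  rownames(best) <- NULL
  class(best) <- c("model_leaderboard", "data.frame")
  best
}

#' Cross-validate a single pipeline
#'
#' Same protocol as [tune_and_rank()] restricted to one strategy, one
#' classifier and one hyperparameter cell.
#'
#' @param pipeline List with `strategy_id` (or `use_pca`/`filter`/`use_lasso`),
#'   `classifier`, `k`, and optionally `hyper` (one-row data frame).
#' @inheritParams tune_and_rank
#' @param with_train_ap Also record resubstitution AP per fold.
#' @return List: `mean_ap`, `sd_ap`, `fold_ap` (length
#'   `n_folds * n_repeats`), and `fold_ap_train` when requested.
#' @export
cross_validate <- function(pipeline, table, cv = cv_config(),
                           preselect = preselect_config(), seed = 1L,
                           with_train_ap = FALSE) {
  strat <- .pipeline_strategy(pipeline)
  grids <- list(k_grid = if (is.null(pipeline$k)) Inf else pipeline$k,
                classifiers = stats::setNames(
                  list(if (is.null(pipeline$hyper)) data.frame(dummy = NA)
                       else as.data.frame(pipeline$hyper)),
                  pipeline$classifier))
  y <- as.integer(table$label)
  folds <- .make_cv_folds(y, cv)
  ap <- numeric(length(folds)); ap_tr <- numeric(length(folds))
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    stopifnot(sum(y[f$val]) > 0)  # stratification guarantees positives per fold
    r <- .sweep_fold(table[f$train, , drop = FALSE], table[f$val, , drop = FALSE],
                     y[f$train], y[f$val], preselect, grids,
                     seed = .sub_seed(seed, i), strategies = strat,
                     with_train_ap = with_train_ap)
    ap[i] <- r$ap[1]
    ap_tr[i] <- r$ap_train[1]
  }
  out <- list(mean_ap = mean(ap), sd_ap = stats::sd(ap), fold_ap = ap)
  if (with_train_ap) out$fold_ap_train <- ap_tr
  out
}

.pipeline_strategy <- function(pipeline) {
  if (!is.null(pipeline$strategy_id)) {
    s <- enumerate_strategies()
    s[s$strategy_id == pipeline$strategy_id, , drop = FALSE]
  } else {
    data.frame(strategy_id = sprintf("%s_%s_%s",
                                     ifelse(pipeline$use_pca, "pca", "raw"),
                                     pipeline$filter,
                                     ifelse(pipeline$use_lasso, "lasso", "nolasso")),
               use_pca = pipeline$use_pca, filter = pipeline$filter,
               use_lasso = pipeline$use_lasso, stringsAsFactors = FALSE)
  }
}

## ---- final fits, ensembles -----------------------------------------------

#' Fit a pipeline on the full training subset
#'
#' Refits the entire cascade (normalization, redundancy pruning, optional
#' PCA, filter ranking with the tuned cut, optional LASSO, classifier with
#' the tuned hyperparameters) on all supplied training rows. The returned
#' model carries every fitted constant, so prediction on new rows touches no
#' statistic of those rows.
#'
#' @inheritParams cross_validate
#' @param grids Grids used during tuning (to resolve `hyper_id`).
#' @return A `petromics_model` with a [predict()][predict.petromics_model]
#'   method returning positive-class probabilities.
#' @export
fit_final <- function(pipeline, table, preselect = preselect_config(),
                      grids = pipeline_grids("default"), seed = 1L) {
  strat <- .pipeline_strategy(pipeline)
  stopifnot(nrow(strat) == 1L)
  y <- as.integer(table$label)
  pp <- .fit_preproc(table, preselect)
  Xtr <- pp$train_X
  basis <- NULL
  if (strat$use_pca) {
    basis <- fit_pca(Xtr)
    .audit_record(rownames(table))
    Xtr <- project_pca(basis, Xtr)
  }
  ranking <- rank_features(Xtr, y, method = strat$filter)
  .audit_record(rownames(table))
  k <- if (is.null(pipeline$k)) Inf else pipeline$k
  sel <- ranking$feature[seq_len(min(k, nrow(ranking)))]
  if (strat$use_lasso) {
    sel <- lasso_select_cv(Xtr[, sel, drop = FALSE], y, seed = seed)
    .audit_record(rownames(table))
  }
  hyper <- pipeline$hyper
  if (is.null(hyper) && !is.null(pipeline$hyper_id))
    hyper <- grids$classifiers[[pipeline$classifier]][pipeline$hyper_id, , drop = FALSE]
  clf <- fit_classifier(pipeline$classifier, Xtr[, sel, drop = FALSE], y,
                        hyper = if (is.null(hyper)) list() else hyper, seed = seed)
  structure(list(preproc = pp, basis = basis, selected = sel,
                 strategy = strat, classifier = clf,
                 pipeline = pipeline, seed = seed),
            class = "petromics_model")
}

#' @param object A `petromics_model`.
#' @param newdata Feature table with the training columns (clinical already
#'   encoded).
#' @param ... Unused.
#' @rdname fit_final
#' @export
predict.petromics_model <- function(object, newdata, ...) {
  X <- .apply_preproc(object$preproc, newdata)
  if (!is.null(object$basis)) X <- project_pca(object$basis, X)
  predict_prob(object$classifier, X[, object$selected, drop = FALSE])
}

#' Soft-voting ensemble of fitted pipelines
#'
#' Aggregates member models by the arithmetic mean of their positive-class
#' probabilities. `fit_ensemble()` refits the top `n_members` leaderboard
#' pipelines on the training subset and bundles them.
#'
#' @param members List of fitted `petromics_model`s.
#' @param table Feature table to score.
#' @return `soft_vote()`: numeric probability vector (mean over members).
#' @export
soft_vote <- function(members, table) {
  stopifnot(length(members) >= 1)
  P <- vapply(members, function(m) predict.petromics_model(m, table),
              numeric(nrow(table)))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  rowMeans(P)
}

#' @param leaderboard A `model_leaderboard` from [tune_and_rank()].
#' @param n_members Number of top pipelines to aggregate (default 10).
#' @inheritParams fit_final
#' @rdname soft_vote
#' @return `fit_ensemble()`: a `soft_vote_ensemble` (list of fitted members)
#'   with a `predict()` method.
#' @export
fit_ensemble <- function(leaderboard, table, n_members = 10,
                         preselect = preselect_config(),
                         grids = pipeline_grids("default"), seed = 1L) {
  top <- utils::head(leaderboard, n_members)
  members <- lapply(seq_len(nrow(top)), function(i) {
    fit_final(as.list(top[i, , drop = FALSE]), table, preselect = preselect,
              grids = grids, seed = seed)
  })
  structure(list(members = members, leaderboard = top), class = "soft_vote_ensemble")
}

#' @export
predict.soft_vote_ensemble <- function(object, newdata, ...)
  soft_vote(object$members, newdata)

## ---- learning curve ------------------------------------------------------

#' Learning curve of a pipeline
#'
#' For each training-set size, draws a stratified subsample, runs the
#' repeated cross-validation protocol on it, and records the mean
#' resubstitution (train) and validation AP. At the full size this
#' reproduces [cross_validate()]'s mean AP.
#'
#' @inheritParams cross_validate
#' @param sizes Training sizes to evaluate (each <= `nrow(table)`).
#' @return Data frame: `n`, `train_ap`, `train_ap_sd`, `val_ap`, `val_ap_sd`.
#' @export
learning_curve <- function(pipeline, table, sizes, cv = cv_config(),
                           preselect = preselect_config(), seed = 1L) {
  y <- as.integer(table$label)
  out <- list()
  for (n in sizes) {
    if (n > nrow(table)) { .warnf("size %d exceeds the table; skipped", n); next }
    frac <- n / nrow(table)
    set.seed(.sub_seed(seed, n))
    idx <- integer(0)
    for (cl in c(0L, 1L)) {
      icl <- which(y == cl)
      idx <- c(idx, sample(icl, max(2L, round(length(icl) * frac))))
    }
    idx <- sort(idx)
    min_class <- min(table(y[idx]))
    if (min_class < cv$n_folds) { .warnf("size %d too small for stratified folds; skipped", n); next }
    r <- cross_validate(pipeline, table[idx, , drop = FALSE], cv = cv,
                        preselect = preselect, seed = seed, with_train_ap = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      n = length(idx),
      train_ap = mean(r$fold_ap_train), train_ap_sd = stats::sd(r$fold_ap_train),
      val_ap = r$mean_ap, val_ap_sd = r$sd_ap)
  }
  do.call(rbind, out)
}
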