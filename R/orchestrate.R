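#' Configuration for an end-to-end pipeline run
#'
#' Bundles every stage's settings: the synthetic cohort (or a directory of
#' NIfTI/CSV inputs), the feature registry, the ICC manifest, the strategy
#' and hyperparameter grids, the cross-validation protocol, the seeds, and an
#' optional cohort subgroup filter (`"all"`, `"t3plus"` = clinical T3-T4a
#' only, `"adeno"` = adenocarcinoma only; subgroup filters apply before the
#' train/test split).
#'
#' @param cohort A [cohort_config()] (simulation) or a directory path holding
#'   `cohort.csv` plus `P*_suv.nii.gz` / `P*_mask.nii.gz` pairs.
#' @param registry Feature registry data frame.
#' @param icc_manifest ICC manifest data frame, or `NULL` to skip ICC
#'   preselection.
#' @param grids `"default"`, `"reduced"`, or a [pipeline_grids()] list.
#' @param cv A [cv_config()].
#' @param split_seed Seed of the stratified 70/30 split.
#' @param test_fraction Held-out fraction (default 0.3).
#' @param subgroup `"all"`, `"t3plus"` or `"adeno"`.
#' @param n_ensemble Members of the soft-voting ensemble (default 10).
#' @param strategies Strategy grid subset (default all 24).
#' @param model_seed Seed for stochastic learners.
#' @param outdir Output directory for artifacts, or `NULL` to keep results
#'   in memory only.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            registry = default_registry(),
                            icc_manifest = read_icc_manifest(),
                            grids = "default",
                            cv = cv_config(),
                            split_seed = 1L, test_fraction = 0.3,
                            subgroup = c("all", "t3plus", "adeno"),
                            n_ensemble = 10L,
                            strategies = enumerate_strategies(),
                            model_seed = 1L,
                            outdir = NULL) {
  subgroup <- match.arg(subgroup)
  if (is.character(grids)) grids <- pipeline_grids(grids)
  stopifnot(is.data.frame(registry), all(c("feature", "family") %in% names(registry)))
  if (!is.null(icc_manifest))
    stopifnot(all(c("feature", "icc") %in% names(icc_manifest)))
  structure(list(cohort = cohort, registry = registry,
                 icc_manifest = icc_manifest, grids = grids, cv = cv,
                 split_seed = as.integer(split_seed),
                 test_fraction = test_fraction, subgroup = subgroup,
                 n_ensemble = as.integer(n_ensemble), strategies = strategies,
                 model_seed = as.integer(model_seed), outdir = outdir),
            class = "pipeline_config")
}

.read_cohort_dir <- function(dir) {
  csv <- file.path(dir, "cohort.csv")
  if (!file.exists(csv)) .stopf("cohort directory '%s' lacks cohort.csv", dir)
  tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
  patients <- lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$patient_id[i]
    list(image = read_volume(file.path(dir, sprintf("%s_suv.nii.gz", id))),
         mask = read_volume(file.path(dir, sprintf("%s_mask.nii.gz", id)), mask = TRUE),
         histology = tab$histology[i], t_stage = tab$t_stage[i],
         n_stage = tab$n_stage[i], label = tab$label[i])
  })
  attr(patients, "cohort_table") <- tab
  patients
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) the cohort, resample to the isotropic analysis grid
#' and extract the registry features, apply the subgroup filter, split 70/30
#' stratified, sweep and rank the pipeline grid by cross-validated average
#' precision, fit the best pipeline and the top-`n_ensemble` soft-voting
#' ensemble on the training subset, and evaluate both on the held-out test
#' subset. Deterministic for fixed configuration and seeds. When `outdir`
#' is set, writes `features.csv`, `leaderboard.csv`, `report_best.json`,
#' `report_ensemble.json`, and `run_record.json` (stage-by-stage feature
#' counts, seeds, artifact checksums).
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_run` list: `cohort_table`, `features`, `split`,
#'   `leaderboard`, `best_model`, `ensemble`, `report_best`,
#'   `report_ensemble`, `counts`, `run_record`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  cohort <- stage("simulate", {
    if (inherits(config$cohort, "cohort_config")) generate_cohort(config$cohort)
    else .read_cohort_dir(config$cohort)
  })
  features <- stage("extract", extract_cohort(cohort, registry = config$registry))

  n_before <- nrow(features)
  features <- stage("subgroup", switch(config$subgroup,
    all = features,
    t3plus = features[features$t_stage >= 3, , drop = FALSE],
    adeno = features[features$histology == "adenocarcinoma", , drop = FALSE]))
  if (min(table(features$label)) < 4)
    .stopf("subgroup '%s' leaves too few samples per class", config$subgroup)

  model_tab <- encode_clinical(features)
  feature_cols <- setdiff(names(model_tab),
                          c("patient_id", "label"))
  split <- stage("split", split_cohort(model_tab$label,
                                       test_fraction = config$test_fraction,
                                       seed = config$split_seed))
  train_tab <- model_tab[split$train, c("label", feature_cols), drop = FALSE]
  test_tab <- model_tab[split$test, c("label", feature_cols), drop = FALSE]
  presel <- preselect_config(icc_manifest = config$icc_manifest)

  leaderboard <- stage("tune", tune_and_rank(
    train_tab, cv = config$cv, grids = config$grids, preselect = presel,
    strategies = config$strategies, seed = config$model_seed))

  best <- stage("fit_final", fit_final(as.list(leaderboard[1, , drop = FALSE]),
                                       train_tab, preselect = presel,
                                       grids = config$grids, seed = config$model_seed))
  ensemble <- stage("ensemble", fit_ensemble(
    leaderboard, train_tab, n_members = min(config$n_ensemble, nrow(leaderboard)),
    preselect = presel, grids = config$grids, seed = config$model_seed))

  report_best <- stage("evaluate", evaluate_scores(
    test_tab$label, predict(best, test_tab)))
  report_ensemble <- stage("evaluate", evaluate_scores(
    test_tab$label, predict(ensemble, test_tab)))

  counts <- c(n_patients = n_before, n_analyzed = nrow(features),
              n_train = length(split$train), n_test = length(split$test),
              best$preproc$counts)
  run_record <- list(
    subgroup = config$subgroup,
    seeds = list(cohort = if (inherits(config$cohort, "cohort_config"))
      config$cohort$seed else NA,
      split = config$split_seed, cv = config$cv$seed, model = config$model_seed),
    cv = unclass(config$cv),
    n_strategies = nrow(config$strategies),
    n_pipelines = nrow(leaderboard),
    feature_counts = counts,
    best = as.list(leaderboard[1, , drop = FALSE]))

  out <- structure(list(cohort_table = attr(cohort, "cohort_table"),
                        features = features, split = split,
                        leaderboard = leaderboard, best_model = best,
                        ensemble = ensemble, report_best = report_best,
                        report_ensemble = report_ensemble, counts = counts,
                        run_record = run_record),
                   class = "pipeline_run")
  if (!is.null(config$outdir)) .write_run_artifacts(out, config$outdir)
  out
}

.write_run_artifacts <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$features, file.path(outdir, "features.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(run$leaderboard),
                   file.path(outdir, "leaderboard.csv"), row.names = FALSE)
  write_evaluation_report(run$report_best, file.path(outdir, "report_best.json"))
  write_evaluation_report(run$report_ensemble, file.path(outdir, "report_ensemble.json"))
  rec <- run$run_record
  files <- file.path(outdir, c("features.csv", "leaderboard.csv",
                               "report_best.json", "report_ensemble.json"))
  rec$artifact_md5 <- as.list(tools::md5sum(files))
  jsonlite::write_json(rec, file.path(outdir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outdir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d patients (%d analyzed), best %s + %s: test AP %.3f (chance %.3f), AUC %.3f\n",
              x$counts[["n_patients"]], x$counts[["n_analyzed"]],
              x$leaderboard$strategy_id[1], x$leaderboard$classifier[1],
              x$report_best$ap, x$report_best$baseline_ap, x$report_best$auc))
  invisible(x)
}

#' Descriptive cohort summary by response class
#'
#' Per-class counts and percentages for categorical characteristics and
#' median (IQR) for continuous ones, mirroring a clinical baseline table.
#' No inferential statistics are computed.
#'
#' @param cohort_table Data frame with a binary `label` column
#'   (1 = non-responder).
#' @return Data frame: `characteristic`, `level`, `responder`,
#'   `nonresponder` (formatted strings).
#' @export
summarize_cohort <- function(cohort_table) {
  stopifnot("label" %in% names(cohort_table))
  lab <- as.integer(cohort_table$label)
  cols <- setdiff(names(cohort_table), c("label", "patient_id"))
  fmt_cat <- function(x, sel) {
    n <- sum(sel)
    vapply(sort(unique(x)), function(v)
      sprintf("%d (%.1f%%)", sum(x[sel] == v), 100 * sum(x[sel] == v) / n), "")
  }
  rows <- list()
  for (cl in cols) {
    x <- cohort_table[[cl]]
    categorical <- is.character(x) || is.factor(x) || length(unique(x)) <= 6
    if (categorical) {
      levs <- sort(unique(x))
      rows[[cl]] <- data.frame(
        characteristic = cl, level = as.character(levs),
        responder = fmt_cat(x, lab == 0), nonresponder = fmt_cat(x, lab == 1),
        stringsAsFactors = FALSE)
    } else {
      fmt_num <- function(sel) {
        q <- stats::quantile(x[sel], c(0.25, 0.5, 0.75), names = FALSE)
        sprintf("%.3g (%.3g-%.3g)", q[2], q[1], q[3])
      }
      rows[[cl]] <- data.frame(
        characteristic = cl, level = "median (IQR)",
        responder = fmt_num(lab == 0), nonresponder = fmt_num(lab == 1),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
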