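mini_config <- function(seed = 1, outdir = NULL, subgroup = "all") {
  pipeline_config(
    cohort = cohort_config(n_patients = 16, prevalence = 0.3125,
                           tumor_radius_range = c(8, 12),
                           base_suv_range = c(5, 9), heterogeneity_effect = 2,
                           voxel_spacing = c(3.1819, 3.1819, 2), seed = seed),
    grids = "reduced",
    cv = cv_config(n_folds = 2, n_repeats = 2, seed = seed),
    split_seed = seed, model_seed = seed, n_ensemble = 3,
    strategies = enumerate_strategies()[c(2, 13), ],
    subgroup = subgroup, outdir = outdir)
}

test_that("the end-to-end run is deterministic under fixed seeds", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- suppressWarnings(run_pipeline(mini_config(seed = 5, outdir = d1)))
  r2 <- suppressWarnings(run_pipeline(mini_config(seed = 5, outdir = d2)))
  expect_identical(as.data.frame(r1$leaderboard), as.data.frame(r2$leaderboard))
  expect_identical(r1$report_best$ap, r2$report_best$ap)
  expect_identical(r1$report_ensemble$ap, r2$report_ensemble$ap)
  # artifact files are byte-identical across the two runs
  for (f in c("features.csv", "leaderboard.csv", "report_best.json"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  expect_true(file.exists(file.path(d1, "run_record.json")))
  rec <- jsonlite::read_json(file.path(d1, "run_record.json"))
  expect_equal(rec$feature_counts$n_input, 143)
  expect_equal(rec$feature_counts$n_after_icc, 121)
})

test_that("subgroup filters restrict the analyzed cohort before the split", {
  cfg <- mini_config(seed = 7, subgroup = "t3plus")
  r <- suppressWarnings(run_pipeline(cfg))
  expect_true(all(r$features$t_stage >= 3))
  expect_lte(r$counts[["n_analyzed"]], r$counts[["n_patients"]])
  expect_equal(r$counts[["n_train"]] + r$counts[["n_test"]],
               r$counts[["n_analyzed"]])
})

test_that("an invalid configuration fails before any computation", {
  expect_error(pipeline_config(registry = data.frame(x = 1)), "feature")
  expect_error(pipeline_config(icc_manifest = data.frame(a = 1)), "icc|feature")
  expect_error(read_icc_manifest("/nonexistent/manifest.csv"), "not found")
  expect_error(pipeline_config(subgroup = "everyone"), "arg")
})

test_that("cohorts written to disk can be re-run from the directory", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(cohort_config(n_patients = 4, prevalence = 0.5,
                                          tumor_radius_range = c(8, 10),
                                          base_suv_range = c(5, 8), seed = 3))
  tab <- write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  back <- petromics:::.read_cohort_dir(dir)
  expect_length(back, 4)
  expect_equal(attr(back, "cohort_table")$label, tab$label)
  expect_equal(back[[1]]$image$values, cohort[[1]]$image$values,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("cohort summaries report per-class counts and medians correctly", {
  tab <- data.frame(label = c(0, 0, 0, 1, 1),
                    histology = c("a", "a", "b", "a", "a"),
                    size = c(1, 2, 3, 10, 20))
  s <- summarize_cohort(tab)
  hrow <- s[s$characteristic == "histology" & s$level == "a", ]
  expect_match(hrow$responder, "^2 \\(66.7%\\)")
  expect_match(hrow$nonresponder, "^2 \\(100.0%\\)")
  # median/IQR of a known sample equals sort-based order statistics
  tab2 <- data.frame(label = rep(c(0, 1), each = 11),
                     u = c(sort(runif(11)), 1:11))
  s2 <- summarize_cohort(tab2)
  urow <- s2[s2$characteristic == "u", ]
  expect_match(urow$nonresponder, "^6 \\(3.5-8.5\\)")
})
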