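#!/usr/bin/env Rscript
# Step 4 — the 144-pipeline sweep.
#
# Cross-validates every combination of the 24 feature-selection strategies
# ({PCA} x {6 univariable filters} x {LASSO}) with the 6 classifiers on the
# training subset (stratified 2-fold CV repeated 5 times), ranks pipelines
# by mean average precision, refits the best pipeline and the top-10
# soft-voting ensemble on the full training subset. Reduced hyperparameter
# grids keep the sweep at desk scale; pass "default" below for the full
# grids. The whole cascade is refit inside every fold.

suppressMessages(library(petromics))
features <- read.csv("results/features.csv", check.names = FALSE)
model_tab <- encode_clinical(features)
sp <- jsonlite::read_json("results/split.json", simplifyVector = TRUE)
feature_cols <- setdiff(names(model_tab), c("patient_id", "label"))
train <- model_tab[sp$train, c("label", feature_cols)]

presel <- preselect_config(icc_manifest = read_icc_manifest())
grids <- pipeline_grids("reduced")

t0 <- Sys.time()
lb <- suppressWarnings(tune_and_rank(train, cv = cv_config(n_folds = 2, n_repeats = 5,
                                                           seed = 20260922),
                                     grids = grids, preselect = presel,
                                     seed = 20260922))
cat(sprintf("Swept %d pipelines in %.1f min\n", nrow(lb),
            as.numeric(difftime(Sys.time(), t0, units = "mins"))))
write.csv(as.data.frame(lb), "results/leaderboard.csv", row.names = FALSE)
cat("Top 10 by cross-validated average precision:\n")
print(head(as.data.frame(lb)[, c("rank", "strategy_id", "classifier", "k",
                                 "mean_ap", "sd_ap")], 10), row.names = FALSE)

best <- suppressWarnings(fit_final(as.list(lb[1, ]), train, preselect = presel,
                                   grids = grids, seed = 20260922))
ens <- suppressWarnings(fit_ensemble(lb, train, n_members = 10,
                                     preselect = presel, grids = grids,
                                     seed = 20260922))
saveRDS(list(best = best, ensemble = ens), "results/models.rds")
cat(sprintf("Best pipeline: %s + %s (CV AP %.3f +/- %.3f); top-10 ensemble refitted\n",
            lb$strategy_id[1], lb$classifier[1], lb$mean_ap[1], lb$sd_ap[1]))
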