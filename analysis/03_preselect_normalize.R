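#!/usr/bin/env Rscript
# Step 3 — preselection and normalization (training subset only).
#
# Splits the cohort 70/30 stratified, then walks the cascade head on the
# training rows: manifest-based ICC preselection (ICC < 0.6 removed),
# skewness-branched normalization (|skew| <= 0.5 robust median/IQR scaling,
# otherwise Yeo-Johnson + standardization), and redundancy pruning of
# radiomic features with |Pearson rho| > 0.8 against a conventional metric
# (volume, SUVmax, SUVpeak, SUVmean, TLG). Reports the feature count after
# every step and the branch composition; writes the normalization plan.

suppressMessages(library(petromics))
features <- read.csv("results/features.csv", check.names = FALSE)
model_tab <- encode_clinical(features)

sp <- split_cohort(model_tab$label, test_fraction = 0.3, seed = 20260922)
train <- model_tab[sp$train, ]
cat(sprintf("Split: %d train / %d test (%d / %d non-responders)\n",
            length(sp$train), length(sp$test),
            sum(train$label), sum(model_tab$label[sp$test])))
writeLines(jsonlite::toJSON(sp), "results/split.json")

man <- read_icc_manifest()
radiomic <- intersect(names(train), man$feature)
after_icc <- drop_low_icc(train, man, features = radiomic)
cat(sprintf("ICC preselection: %d -> %d radiomic features (%d removed at ICC < 0.6)\n",
            length(radiomic), length(radiomic) - length(attr(after_icc, "dropped")),
            length(attr(after_icc, "dropped"))))

kept <- setdiff(radiomic, attr(after_icc, "dropped"))
plan <- suppressWarnings(fit_normalization_plan(after_icc, features = kept))
branches <- table(vapply(plan, `[[`, "", "branch"))
cat(sprintf("Normalization branches: %s\n",
            paste(names(branches), branches, sep = " = ", collapse = ", ")))
write_normalization_plan(plan, "results/normalization_plan.json")

norm_train <- apply_normalization_plan(plan, after_icc)
pruned <- suppressWarnings(drop_conventional_redundant(norm_train,
  conventional_names = intersect(conventional_features(), kept),
  features = setdiff(kept, conventional_features())))
cat(sprintf("Redundancy pruning: %d removed (|rho| > 0.8 vs conventional), %d radiomic features remain\n",
            length(attr(pruned, "dropped")),
            length(kept) - length(attr(pruned, "dropped"))))

remaining <- setdiff(kept, attr(pruned, "dropped"))
cc <- abs(cor(as.matrix(pruned[, remaining])))
diag(cc) <- 0
cat(sprintf("Residual redundancy: %.0f%% of remaining features have >= 1 |rho| > 0.8 partner\n",
            100 * mean(apply(cc, 1, max) > 0.8)))
write.csv(data.frame(step = c("input", "after_icc", "after_redundancy"),
                     n_radiomic = c(length(radiomic), length(kept), length(remaining))),
          "results/feature_counts.csv", row.names = FALSE)
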