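#!/usr/bin/env Rscript
# Step 5 — held-out evaluation and learning curve.
#
# Scores the best pipeline and the soft-voting ensemble on the untouched
# 30% test subset: average precision against the chance baseline (test
# prevalence), ROC AUC, and the PR/ROC curves. Also traces the best
# pipeline's learning curve over increasing training sizes.

suppressMessages(library(petromics))
features <- read.csv("results/features.csv", check.names = FALSE)
model_tab <- encode_clinical(features)
sp <- jsonlite::read_json("results/split.json", simplifyVector = TRUE)
feature_cols <- setdiff(names(model_tab), c("patient_id", "label"))
train <- model_tab[sp$train, c("label", feature_cols)]
test <- model_tab[sp$test, c("label", feature_cols)]
models <- readRDS("results/models.rds")

rep_best <- evaluate_scores(test$label, predict(models$best, test))
rep_ens <- evaluate_scores(test$label, predict(models$ensemble, test))
write_evaluation_report(rep_best, "results/report_best.json")
write_evaluation_report(rep_ens, "results/report_ensemble.json")
write.csv(rep_best$pr_curve, "results/pr_curve_best.csv", row.names = FALSE)
write.csv(rep_best$roc_curve, "results/roc_curve_best.csv", row.names = FALSE)

cat(sprintf("Best model:  test AP %.3f (chance %.3f), AUC %.3f\n",
            rep_best$ap, rep_best$baseline_ap, rep_best$auc))
cat(sprintf("Soft vote:   test AP %.3f, AUC %.3f (top-10 members)\n",
            rep_ens$ap, rep_ens$auc))

suppressMessages(library(ggplot2))
p1 <- ggplot(rep_best$pr_curve, aes(recall, precision)) +
  geom_step(direction = "hv", colour = "steelblue") +
  geom_hline(yintercept = rep_best$baseline_ap, linetype = "dashed") +
  coord_cartesian(ylim = c(0, 1)) +
  labs(title = sprintf("Precision-recall, best model (test AP %.2f, chance %.2f)",
                       rep_best$ap, rep_best$baseline_ap)) +
  theme_minimal()
ggsave("results/pr_curve_best.png", p1, width = 5, height = 4, dpi = 120)
p2 <- ggplot(rep_best$roc_curve, aes(fpr, tpr)) +
  geom_step(direction = "vh", colour = "firebrick") +
  geom_abline(linetype = "dashed") +
  labs(title = sprintf("ROC, best model (test AUC %.2f)", rep_best$auc)) +
  theme_minimal()
ggsave("results/roc_curve_best.png", p2, width = 5, height = 4, dpi = 120)

lb <- read.csv("results/leaderboard.csv")
pl <- c(as.list(lb[1, c("strategy_id", "classifier", "k", "hyper_id")]))
presel <- preselect_config(icc_manifest = read_icc_manifest())
lc <- suppressWarnings(learning_curve(pl, train,
                                      sizes = round(nrow(train) * c(0.4, 0.6, 0.8, 1)),
                                      cv = cv_config(seed = 20260922),
                                      preselect = presel, seed = 20260922))
write.csv(lc, "results/learning_curve.csv", row.names = FALSE)
cat("Learning curve (mean AP by training size):\n")
print(lc, row.names = FALSE)
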