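#!/usr/bin/env Rscript
# Step 6 -- evaluation artifacts.
#
# Confusion matrices and threshold metrics at the Youden-optimal training
# threshold, AUROC with DeLong intervals, AUPR, pairwise DeLong
# comparisons, calibration coordinates, the boosted-tree importance
# ranking, and the case-vs-control cohort characteristics table.

suppressPackageStartupMessages(library(altsynergy))

test <- read.delim("results/test_predictions.tsv")
train <- read.delim("results/train_predictions.tsv")
models <- c("mlr", "lasso", "gbt")

metrics <- list()
for (m in models) {
  thr <- youden_threshold(train[[m]], train$outcome)
  cm <- confusion_at_threshold(test[[m]], test$outcome, thr)
  tm <- threshold_metrics(cm)
  ra <- roc_auc(test[[m]], test$outcome)
  metrics[[m]] <- data.frame(
    model = m, threshold = thr, tp = cm$tp, fp = cm$fp, fn = cm$fn,
    tn = cm$tn, sensitivity = tm$sensitivity, ppv = tm$ppv,
    specificity = tm$specificity, npv = tm$npv, f1 = tm$f1,
    auroc = ra$auroc, auroc_low = ra$ci_low, auroc_high = ra$ci_high,
    aupr = pr_auc(test[[m]], test$outcome))
}
metrics <- do.call(rbind, metrics)
write.table(metrics, "results/test_metrics.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(metrics[, c("model", "sensitivity", "ppv", "specificity", "npv",
                  "f1", "auroc", "aupr")], digits = 3)

cat("\nDeLong comparisons (test set):\n")
for (pair in list(c("mlr", "lasso"), c("mlr", "gbt"), c("lasso", "gbt"))) {
  dl <- delong_test(test[[pair[1]]], test[[pair[2]]], test$outcome)
  cat(sprintf("  %s vs %s: dAUROC = %+.3f, p = %.3g\n",
              pair[1], pair[2], dl$difference, dl$p_value))
}

cal <- do.call(rbind, lapply(models, function(m)
  cbind(model = m, calibration_curve(test[[m]], test$outcome, 10))))
write.table(cal, "results/calibration.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# boosted-tree importance needs the fitted model: refit from features
tabf <- read.delim("results/feature_matrix.tsv", check.names = FALSE)
x <- as.matrix(tabf[, -(1:2)]); rownames(x) <- tabf$patient_id
sp <- split_data(x, tabf$outcome, split_spec(0.70, seed = 20220706))
gbt <- fit_gbt(sp$train$x, sp$train$outcome, nrounds = 60, seed = 20220706)
imp <- importance_report(gbt, top_k = 50)
write.table(imp, "results/gbt_importance_top50.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\ntop boosted-tree features by gain:\n")
print(head(imp, 8), digits = 3)

ehr <- read_ehr_tables("results/ehr")
cohort <- read.delim("results/cohort_labels.tsv")
for (col in c("first_date", "second_date", "index_date"))
  cohort[[col]] <- as.Date(cohort[[col]])
fx <- assemble_feature_matrix(cohort, ehr,
                              rule = exposure_rule(pair_min_patients = 40))
summ <- cohort_summary(fx)
write.table(summ, "results/cohort_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\ncohort characteristics (first rows):\n")
print(head(summ, 6), digits = 3)
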