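#!/usr/bin/env Rscript
# Step 4 -- fit the three classifiers.
#
# 70/30 stratified split, then multiple logistic regression (MLR),
# 10-fold cross-validated logistic LASSO (lambda minimizing the CV
# misclassification error), and a grid-searched gradient-boosted tree
# model. Coefficients and test-set predictions go to results/.

suppressPackageStartupMessages(library(altsynergy))

tab <- read.delim("results/feature_matrix.tsv", check.names = FALSE)
x <- as.matrix(tab[, -(1:2)])
rownames(x) <- tab$patient_id
y <- tab$outcome

sp <- split_data(x, y, split_spec(0.70, seed = 20220706, stratified = TRUE))
cat(sprintf("training %d (%.1f%% cases) / testing %d (%.1f%% cases)\n",
            length(sp$train$outcome), 100 * mean(sp$train$outcome),
            length(sp$test$outcome), 100 * mean(sp$test$outcome)))

mlr <- suppressWarnings(fit_mlr(sp$train$x, sp$train$outcome))
cat("MLR converged:", mlr$converged,
    "| max |beta|:", round(max(abs(mlr$coefficients)), 2), "\n")

lasso <- fit_lasso_cv(sp$train$x, sp$train$outcome, n_folds = 10,
                      seed = 20220706)
cat("LASSO lambda:", signif(lasso$lambda, 4), "| nonzero slopes:",
    sum(lasso$coefficients[-1] != 0), "\n")

gbt <- fit_gbt(sp$train$x, sp$train$outcome, nrounds = 60, seed = 20220706)
cat("GBT winning params: eta =", gbt$params$eta,
    "depth =", gbt$params$max_depth, "subsample =", gbt$params$subsample, "\n")

coefs <- data.frame(feature = names(mlr$coefficients),
                    mlr = unname(mlr$coefficients),
                    lasso = unname(lasso$coefficients))
write.table(coefs, "results/coefficients.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

preds <- data.frame(
  patient_id = rownames(sp$test$x), outcome = sp$test$outcome,
  mlr = predict(mlr, sp$test$x),
  lasso = predict(lasso, sp$test$x),
  gbt = predict(gbt, sp$test$x))
write.table(preds, "results/test_predictions.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
train_preds <- data.frame(
  patient_id = rownames(sp$train$x), outcome = sp$train$outcome,
  mlr = predict(mlr, sp$train$x),
  lasso = predict(lasso, sp$train$x),
  gbt = predict(gbt, sp$train$x))
write.table(train_preds, "results/train_predictions.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

for (m in c("mlr", "lasso", "gbt")) {
  tr <- roc_auc(train_preds[[m]], sp$train$outcome, ci = FALSE)$auroc
  te <- roc_auc(preds[[m]], sp$test$outcome, ci = FALSE)$auroc
  cat(sprintf("%-5s AUROC train %.3f / test %.3f\n", m, tr, te))
}
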