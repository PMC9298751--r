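#!/usr/bin/env Rscript
# Step 5 -- additive-scale interaction screen.
#
# Bootstraps the LASSO coefficients (with-replacement resamples of the
# training set, the original lambda held fixed), builds percentile
# confidence intervals by the rank rule, computes RERI for every
# product-term pair and applies the dual-criterion synergy call. 400
# replicates keep this step to a couple of minutes; the rank rule
# generalizes from the canonical 2,000.

suppressPackageStartupMessages(library(altsynergy))

tab <- read.delim("results/feature_matrix.tsv", check.names = FALSE)
x <- as.matrix(tab[, -(1:2)])
rownames(x) <- tab$patient_id
y <- tab$outcome
catalog <- read.delim("results/feature_catalog.tsv")

sp <- split_data(x, y, split_spec(0.70, seed = 20220706, stratified = TRUE))
lasso <- fit_lasso_cv(sp$train$x, sp$train$outcome, n_folds = 10,
                      seed = 20220706)

spec <- bootstrap_spec(n_replicates = 400, seed = 20220706)
boot <- bootstrap_coefficients(sp$train$x, sp$train$outcome,
                               fitter = lasso, spec = spec)

screen <- screen_all_pairs(lasso, boot, catalog, spec)
write.table(screen, "results/interaction_screen.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("screened", nrow(screen), "product terms;",
    sum(screen$synergy), "called synergistic\n")
cols <- c("product_term", "aor1", "aor2", "aor12", "reri",
          "reri_low", "reri_high", "synergy")
print(head(screen[, cols], 5), digits = 3)
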