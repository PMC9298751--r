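#!/usr/bin/env Rscript
# Step 3 -- feature engineering.
#
# Builds the patients x features table: 6 demographics, 5 history flags,
# one flag per frequent drug, product terms for pairs co-exposed in enough
# patients, and ATC level-4 class rollups for the rest. The co-exposure
# threshold is scaled to this cohort (40 patients out of ~5,400 labeled,
# roughly the same fraction as 100 out of 58,413).

suppressPackageStartupMessages(library(altsynergy))

ehr <- read_ehr_tables("results/ehr")
cohort <- read.delim("results/cohort_labels.tsv")
for (col in c("first_date", "second_date", "index_date"))
  cohort[[col]] <- as.Date(cohort[[col]])

features <- assemble_feature_matrix(cohort, ehr,
                                    rule = exposure_rule(pair_min_patients = 40))

dir.create("results", showWarnings = FALSE)
write.table(cbind(patient_id = rownames(features$x),
                  outcome = features$outcome, as.data.frame(features$x)),
            "results/feature_matrix.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(features$catalog, "results/feature_catalog.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

k <- table(features$catalog$kind)
cat(sprintf("feature matrix: %d patients x %d features\n",
            nrow(features$x), ncol(features$x)))
cat(sprintf("layout 6+5+D+P+C with D=%d drugs, P=%d product terms, C=%d classes\n",
            k[["drug"]], sum(features$catalog$kind == "product"),
            sum(features$catalog$kind == "class")))
cat("missing values:", sum(is.na(features$x)), "\n")
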