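#!/usr/bin/env Rscript
# Step 1 -- simulate the study population.
#
# Generates a synthetic longitudinal EHR with known ground truth: 6,000
# patients, 10 study drugs, one planted synergistic pair (D001 x D002 with
# aOR1 = aOR2 = 1.5 and a product-term aOR of 2.0) and three purely null
# product pairs, plus 2% contamination per exclusion class so the cohort
# builder has work to do. Tables are written under results/ehr/.

suppressPackageStartupMessages(library(altsynergy))

config <- sim_config(
  n_patients = 6000,
  n_drugs = 10,
  planted_pairs = data.frame(
    drug1 = c(1, 3, 5, 7), drug2 = c(2, 4, 6, 8),
    beta1 = c(log(1.5), 0, 0, 0),
    beta2 = c(log(1.5), 0, 0, 0),
    beta3 = c(log(2.0), 0, 0, 0)),
  contamination = c(minor = 0.02, missing_labs = 0.02,
                    liver_disease = 0.02, hepatoprotectant = 0.02),
  seed = 20220706)

ehr <- generate_cohort(config)
write_ehr_tables(ehr, "results/ehr")

cat("simulated", nrow(ehr$patients), "patients;",
    nrow(ehr$prescriptions), "prescriptions;",
    nrow(ehr$labs), "lab rows\n")
cat("true outcome prevalence:",
    round(mean(ehr$ground_truth$outcome), 4), "\n")
print(table(ehr$ground_truth$role))
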