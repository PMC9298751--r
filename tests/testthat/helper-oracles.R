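# Independent oracles and tiny fixture builders. These deliberately avoid
# the package's own code paths: the IRLS oracle is a textbook Newton-Raphson
# written from the score/Hessian, the AUROC oracle is the all-pairs
# concordance count, the pair-count oracle is a double loop.

oracle_irls <- function(X, y, maxit = 200L, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    p <- as.vector(1 / (1 + exp(-X %*% beta)))
    H <- t(X) %*% (X * (p * (1 - p)))
    g <- t(X) %*% (y - p)
    step <- solve(H, g)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

oracle_concordance <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

oracle_pair_counts <- function(exposures, min_n) {
  drugs <- sort(unique(unlist(exposures)))
  out <- list()
  for (i in seq_along(drugs)) {
    for (j in seq_along(drugs)) {
      if (j <= i) next
      n <- sum(vapply(exposures, function(e)
        drugs[i] %in% e && drugs[j] %in% e, logical(1)))
      if (n >= min_n)
        out[[length(out) + 1L]] <- data.frame(drug1 = drugs[i],
                                              drug2 = drugs[j],
                                              n_patients = n,
                                              stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(drug1 = character(), drug2 = character(),
               n_patients = integer(), stringsAsFactors = FALSE)
}

DAY0 <- as.Date("2020-06-01")

alt_labs <- function(days, values, test = "ALT", unit = "U/L") {
  data.frame(test = rep(test, length(days)), value = values,
             unit = rep(unit, length(days)), date = DAY0 + days,
             stringsAsFactors = FALSE)
}

full_panel <- function(days, alt_values) {
  rbind(alt_labs(days, alt_values),
        alt_labs(days, rep(20, length(days)), test = "AST"),
        alt_labs(days, rep(0.5, length(days)), test = "TBL",
                 unit = "mg/dL"),
        alt_labs(days, rep(200, length(days)), test = "ALP"))
}

make_bundle <- function(patient_id = "P1",
                        birth_date = as.Date("1960-01-01"),
                        sex = "male", hospital = "Itabashi",
                        diagnoses = NULL, prescriptions = NULL,
                        labs = NULL) {
  list(patient_id = patient_id, birth_date = birth_date, sex = sex,
       hospital = hospital, diagnoses = diagnoses,
       prescriptions = prescriptions, labs = labs)
}

rx_rows <- function(drug_code, days, days_of_supply, atc5 = "M01AB05") {
  data.frame(drug_code = drug_code, atc5 = atc5, date = DAY0 + days,
             days_of_supply = days_of_supply, stringsAsFactors = FALSE)
}

contaminated_config <- function(n = 800, seed = 42) {
  sim_config(n_patients = n, n_drugs = 6,
             planted_pairs = data.frame(drug1 = 1, drug2 = 2,
                                        beta1 = log(1.5), beta2 = log(1.5),
                                        beta3 = log(2)),
             contamination = c(minor = 0.05, missing_labs = 0.05,
                               liver_disease = 0.05,
                               hepatoprotectant = 0.05),
             seed = seed)
}
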