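#' Simulation configuration for the synthetic EHR generator
#'
#' Bundles and validates every knob of the synthetic cohort: the exposure
#' model (per-drug Bernoulli prevalences and planted pairwise effects on the
#' log-odds scale), the demographic model, comorbidity prevalences, the
#' liver-panel measurement model, the prescription model, and the fractions
#' of patients deliberately contaminated so that each eligibility rule of the
#' cohort builder is exercised.
#'
#' The binary outcome (abnormal ALT elevation at the index date) is drawn
#' from a logistic model
#' \deqn{logit P(Y=1) = \alpha + \sum_k (\beta_{1k} x_{i_k} + \beta_{2k} x_{j_k}
#'   + \beta_{3k} x_{i_k} x_{j_k})}
#' where the sum runs over the planted pairs; drugs outside any planted pair
#' carry no effect. Ground truth (exposures, linear predictor, outcome) is
#' kept in a sidecar table, never written into the EHR tables themselves.
#'
#' @param n_patients number of patients to simulate.
#' @param n_drugs number of study drugs.
#' @param drug_exposure_probs per-drug exposure probability in `[0,1]`,
#'   recycled to `n_drugs`. The default 0.30 is arbitrary (no empirical
#'   per-drug prevalence is being emulated) and is documented in the methods
#'   vignette.
#' @param planted_pairs `NULL` or a data frame with columns
#'   `drug1`, `drug2` (1-based drug indices) and `beta1`, `beta2`, `beta3`
#'   (log-odds effects of drug 1, drug 2 and their product term).
#' @param baseline_log_odds intercept of the outcome model; the default
#'   `qlogis(0.07)` reproduces the roughly 93:7 control:case ratio typical of
#'   abnormal-ALT case-control cohorts.
#' @param demographic_model list with `age_mean`, `age_sd` (years),
#'   `male_frac`, and `hospital_fracs` (named, summing to 1).
#' @param comorbidity_prevalences named probabilities for the five history
#'   conditions (hypertension, diabetes, dyslipidemia, heart_failure, sepsis).
#' @param lab_model list controlling the liver panel: `alt_normal_mean`,
#'   `alt_normal_sd` (U/L, truncated to the normal range 4.0--44.0),
#'   `case_alt_shift` (lower support of the case index-date ALT, must be
#'   >= 132 U/L so every case exceeds 3x the upper limit of normal),
#'   `case_alt_meanlog`, `case_alt_sdlog` (log-normal excess over the shift),
#'   `gap_days` (two positive day gaps between the three liver-test days,
#'   summing to <= 90), and means/sds for AST (U/L), TBL (mg/dL), ALP (U/L).
#' @param prescription_model list with `days_supply_mean` (Poisson mean,
#'   days), `p_span_index` (probability an exposed drug has a prescription on
#'   both sides of the index date rather than relying on days of supply),
#'   `bg_old_mean` and `bg_stopped_mean` (Poisson means for background drugs
#'   started long before the lookback window and for discontinued drugs).
#' @param contamination named fractions (`minor`, `missing_labs`,
#'   `liver_disease`, `hepatoprotectant`) of patients built to violate
#'   exactly one exclusion rule each; must sum to <= 1.
#' @param seed integer RNG seed. Default 20220706.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_patients,
                       n_drugs,
                       drug_exposure_probs = 0.30,
                       planted_pairs = NULL,
                       baseline_log_odds = stats::qlogis(0.07),
                       demographic_model = list(
                         age_mean = 58, age_sd = 19, male_frac = 0.42,
                         hospital_fracs = c(Itabashi = 0.78,
                                            Hikarigaoka = 0.11,
                                            Surugadai = 0.11)),
                       comorbidity_prevalences = c(
                         hypertension = 0.173, diabetes = 0.277,
                         dyslipidemia = 0.128, heart_failure = 0.104,
                         sepsis = 0.011),
                       lab_model = list(
                         alt_normal_mean = 16, alt_normal_sd = 7,
                         case_alt_shift = 132,
                         case_alt_meanlog = log(50), case_alt_sdlog = 0.8,
                         gap_days = c(30, 30),
                         ast_mean = 19, ast_sd = 5,
                         tbl_mean = 0.55, tbl_sd = 0.15,
                         alp_mean = 210, alp_sd = 60),
                       prescription_model = list(
                         days_supply_mean = 28, p_span_index = 0.6,
                         bg_old_mean = 1, bg_stopped_mean = 1),
                       contamination = c(minor = 0, missing_labs = 0,
                                         liver_disease = 0,
                                         hepatoprotectant = 0),
                       seed = 20220706) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1)
    stop("`n_patients` must be a positive integer", call. = FALSE)
  if (!is.numeric(n_drugs) || length(n_drugs) != 1L || n_drugs < 1)
    stop("`n_drugs` must be a positive integer", call. = FALSE)
  n_patients <- as.integer(n_patients)
  n_drugs <- as.integer(n_drugs)

  probs <- rep_len(as.numeric(drug_exposure_probs), n_drugs)
  if (any(probs < 0 | probs > 1))
    stop("`drug_exposure_probs` must lie in [0, 1]", call. = FALSE)

  if (!is.null(planted_pairs)) {
    planted_pairs <- as.data.frame(planted_pairs)
    need <- c("drug1", "drug2", "beta1", "beta2", "beta3")
    if (!all(need %in% names(planted_pairs)))
      stop("`planted_pairs` needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    bad <- planted_pairs$drug1 == planted_pairs$drug2 |
      planted_pairs$drug1 < 1 | planted_pairs$drug2 < 1 |
      planted_pairs$drug1 > n_drugs | planted_pairs$drug2 > n_drugs
    if (any(bad))
      stop("planted pair indices must be distinct and within 1..n_drugs",
           call. = FALSE)
    if (!all(is.finite(as.matrix(planted_pairs[, c("beta1", "beta2", "beta3")]))))
      stop("planted pair effects must be finite", call. = FALSE)
  }

  hf <- demographic_model$hospital_fracs
  if (abs(sum(hf) - 1) > 1e-9)
    stop("hospital fractions must sum to 1 (within 1e-9)", call. = FALSE)
  if (demographic_model$male_frac < 0 || demographic_model$male_frac > 1)
    stop("`male_frac` must lie in [0, 1]", call. = FALSE)

  if (any(comorbidity_prevalences < 0 | comorbidity_prevalences > 1))
    stop("comorbidity prevalences must lie in [0, 1]", call. = FALSE)

  if (lab_model$case_alt_shift < 132)
    stop("case index-date ALT support must be strictly > 132 U/L ",
         "(case_alt_shift >= 132)", call. = FALSE)
  gaps <- lab_model$gap_days
  if (length(gaps) != 2L || any(gaps <= 0) || sum(gaps) > 90)
    stop("`gap_days` must be two positive gaps summing to <= 90 days",
         call. = FALSE)

  cont <- contamination[c("minor", "missing_labs", "liver_disease",
                          "hepatoprotectant")]
  cont[is.na(cont)] <- 0
  names(cont) <- c("minor", "missing_labs", "liver_disease",
                   "hepatoprotectant")
  if (any(cont < 0 | cont > 1) || sum(cont) > 1)
    stop("contamination fractions must lie in [0, 1] and sum to <= 1",
         call. = FALSE)

  cfg <- list(n_patients = n_patients, n_drugs = n_drugs,
              drug_exposure_probs = probs, planted_pairs = planted_pairs,
              baseline_log_odds = baseline_log_odds,
              demographic_model = demographic_model,
              comorbidity_prevalences = comorbidity_prevalences,
              lab_model = lab_model, prescription_model = prescription_model,
              contamination = cont, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Synthetic study-drug catalog
#'
#' Assigns each simulated study drug a code (`D001`, `D002`, ...) and a
#' plausible ATC level-5 code. Codes are synthetic: they follow the ATC
#' format so that level-4 rollup logic is exercised, but encode no real
#' pharmacology.
#'
#' @param n_drugs number of drugs.
#' @return data frame with columns `drug_code`, `atc5`.
#' @export
drug_catalog <- function(n_drugs) {
  base_atc <- c("M01AB05", "N02BE01", "R05CB06", "B01AC06", "B01AC23",
                "A02BA03", "C07AB03", "C09AA02", "A10BA02", "C10AA01",
                "N05BA06", "A02BC01", "J01CA04", "C03CA01", "N02AB03",
                "H02AB06", "A06AB02", "C08CA01", "M01AE01", "N06AB04")
  atc5 <- rep_len(base_atc, n_drugs)
  # disambiguate recycled codes past the base list
  if (n_drugs > length(base_atc)) {
    extra <- seq(length(base_atc) + 1L, n_drugs)
    atc5[extra] <- sprintf("Z%02dAA%02d", (extra %/% 100) + 10L, extra %% 100)
  }
  data.frame(drug_code = sprintf("D%03d", seq_len(n_drugs)),
             atc5 = atc5, stringsAsFactors = FALSE)
}

#' Synthetic ATC level-4 to therapeutic-class map
#'
#' The real chemical-subgroup to therapeutic-class assignment used for
#' infrequent drugs is not public; this synthetic default maps each ATC
#' level-4 prefix seen in [drug_catalog()] to a class named after it
#' (`TC_<atc4>`), which preserves the rollup semantics (several level-5
#' substances can share a class) without pretending to real pharmacology.
#'
#' @param atc5_codes character vector of ATC level-5 codes to cover.
#' @return data frame with columns `atc4`, `class`.
#' @export
default_atc_class_map <- function(atc5_codes) {
  atc4 <- sort(unique(substr(atc5_codes, 1L, 5L)))
  data.frame(atc4 = atc4, class = paste0("TC_", atc4, recycle0 = TRUE),
             stringsAsFactors = FALSE)
}
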