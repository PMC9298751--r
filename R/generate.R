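# Synthetic longitudinal EHR generator. Internal time is measured in days
# relative to each patient's index date (day 0 = latest liver-test day);
# calendar dates are produced at the end by adding the per-patient anchor.

# truncated-normal draws by inverse-CDF so each value consumes one uniform
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

draw_exposures <- function(config) {
  n <- config$n_patients
  x <- vapply(config$drug_exposure_probs,
              function(p) stats::rbinom(n, 1L, p), integer(n))
  if (n == 1L) x <- matrix(x, nrow = 1L)
  colnames(x) <- sprintf("D%03d", seq_len(config$n_drugs))
  x
}

linear_predictor <- function(x, config) {
  lp <- rep(config$baseline_log_odds, nrow(x))
  pp <- config$planted_pairs
  if (!is.null(pp)) {
    for (k in seq_len(nrow(pp))) {
      xi <- x[, pp$drug1[k]]
      xj <- x[, pp$drug2[k]]
      lp <- lp + pp$beta1[k] * xi + pp$beta2[k] * xj + pp$beta3[k] * xi * xj
    }
  }
  lp
}

#' Generate a design matrix with planted interaction effects
#'
#' Fast path that bypasses the longitudinal simulation: draws binary drug
#' exposures, forms one product column per planted pair, and draws the
#' outcome from the logistic model of the configuration. Used for
#' statistical tests of the interaction machinery (parameter and RERI
#' recovery) where prescriptions and lab trajectories are irrelevant.
#'
#' @param config a [sim_config()].
#' @return list with `x` (patients x features 0/1 matrix: drug columns then
#'   one `"Di*Dj"` product column per planted pair), `outcome` (0/1 vector),
#'   `catalog` (feature catalog rows of kind `drug` / `product`), and
#'   `truth` (per-patient linear predictor and event probability).
#' @export
generate_design_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  x <- draw_exposures(config)
  drug_names <- colnames(x)
  catalog <- data.frame(name = drug_names, kind = "drug",
                        parent1 = NA_character_, parent2 = NA_character_,
                        stringsAsFactors = FALSE)
  pp <- config$planted_pairs
  if (!is.null(pp) && nrow(pp)) {
    prods <- vapply(seq_len(nrow(pp)), function(k)
      x[, pp$drug1[k]] * x[, pp$drug2[k]], numeric(nrow(x)))
    if (nrow(x) == 1L) prods <- matrix(prods, nrow = 1L)
    pnames <- paste0(drug_names[pp$drug1], "*", drug_names[pp$drug2])
    colnames(prods) <- pnames
    catalog <- rbind(catalog, data.frame(
      name = pnames, kind = "product",
      parent1 = drug_names[pp$drug1], parent2 = drug_names[pp$drug2],
      stringsAsFactors = FALSE))
    lp <- linear_predictor(x, config)
    x <- cbind(x, prods)
  } else {
    lp <- linear_predictor(x, config)
  }
  prob <- stats::plogis(lp)
  outcome <- stats::rbinom(length(lp), 1L, prob)
  list(x = x, outcome = outcome, catalog = catalog,
       truth = data.frame(linear_predictor = lp, prob = prob))
}

#' Generate a synthetic longitudinal EHR cohort
#'
#' Builds the four raw EHR tables (patients, diagnoses, prescriptions, lab
#' results) plus a ground-truth sidecar, so the cohort builder, the feature
#' engine and the models can be tested end to end without clinical data.
#'
#' Each eligible patient gets exactly three liver-test days (the minimum
#' satisfying the "at least three tests within 90 days" rule), spaced by the
#' configured gaps, with the latest day serving as index date. Cases have
#' their first two ALT values in the normal range (4.0--44.0 U/L) and an
#' index ALT above 132 U/L (3x the upper limit of normal); controls stay in
#' range on all three days. AST, TBL and ALP accompany ALT on every test
#' day. Exposed study drugs are newly started within the 90-day lookback and
#' continued to the index date (either a prescription on both sides of the
#' index date or days of supply carrying past it); background prescriptions
#' that are old-but-continued or discontinued are added so the exposure
#' rules have negatives to reject. Contaminated patients violate exactly one
#' eligibility rule each: minors, a liver panel missing on both anchor days,
#' a pre-existing liver-disease diagnosis, or a hepatoprotectant
#' prescription.
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_ehr` with data frames `patients`,
#'   `diagnoses`, `prescriptions`, `labs`, `ground_truth`, and the `catalog`
#'   of study drugs. `ground_truth` holds patient id, contamination role,
#'   true outcome, linear predictor, true exposure flags (one column per
#'   study drug) and the true concomitant-drug count.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  dm <- config$demographic_model
  lm_ <- config$lab_model
  pm <- config$prescription_model
  catalog <- drug_catalog(config$n_drugs)

  ids <- sprintf("P%06d", seq_len(n))
  roles <- sample(c(names(config$contamination), "clean"), n, replace = TRUE,
                  prob = c(config$contamination, 1 - sum(config$contamination)))

  x <- draw_exposures(config)
  lp <- linear_predictor(x, config)
  outcome <- stats::rbinom(n, 1L, stats::plogis(lp))

  index_date <- as.Date("2010-01-01") + sample.int(3650L, n, replace = TRUE)

  age <- floor(rtruncnorm(n, dm$age_mean, dm$age_sd, 18, 95))
  age[roles == "minor"] <- sample(8:17, sum(roles == "minor"), replace = TRUE)
  # offset < 365 keeps floor((index - birth)/365.25) equal to the drawn age
  birth_date <- index_date - round(age * 365.25) -
    sample.int(330L, n, replace = TRUE)
  sex <- ifelse(stats::rbinom(n, 1L, dm$male_frac) == 1L, "male", "female")
  hospital <- sample(names(dm$hospital_fracs), n, replace = TRUE,
                     prob = dm$hospital_fracs)
  patients <- data.frame(patient_id = ids, birth_date = birth_date,
                         sex = sex, hospital = hospital,
                         stringsAsFactors = FALSE)

  ## -- labs: three test days at -(g1+g2), -g2, 0 ---------------------------
  g <- lm_$gap_days
  day_off <- c(-(g[1] + g[2]), -g[2], 0)
  n_day <- length(day_off)
  alt <- matrix(rtruncnorm(n * n_day, lm_$alt_normal_mean, lm_$alt_normal_sd,
                           4, 44), n, n_day)
  case_idx <- outcome == 1L
  alt[case_idx, n_day] <- lm_$case_alt_shift +
    stats::rlnorm(sum(case_idx), lm_$case_alt_meanlog, lm_$case_alt_sdlog)
  ast <- matrix(rtruncnorm(n * n_day, lm_$ast_mean, lm_$ast_sd, 5, 60),
                n, n_day)
  ast[case_idx, n_day] <- ast[case_idx, n_day] * 4  # cases: AST rises too
  tbl <- matrix(rtruncnorm(n * n_day, lm_$tbl_mean, lm_$tbl_sd, 0.1, 2),
                n, n_day)
  alp <- matrix(rtruncnorm(n * n_day, lm_$alp_mean, lm_$alp_sd, 60, 500),
                n, n_day)
  labs <- data.frame(
    patient_id = rep(ids, each = n_day * 4L),
    test = rep(rep(c("ALT", "AST", "TBL", "ALP"), each = n_day), n),
    value = round(as.vector(rbind(t(alt), t(ast), t(tbl), t(alp))), 2),
    unit = rep(rep(c("U/L", "U/L", "mg/dL", "U/L"), each = n_day), n),
    date = rep(index_date, each = n_day * 4L) + rep(day_off, n * 4L),
    stringsAsFactors = FALSE)
  # missing-labs contaminant: AST absent on BOTH the first test day and the
  # index date (still present on the middle day)
  drop <- labs$patient_id %in% ids[roles == "missing_labs"] &
    labs$test == "AST" &
    (labs$date == rep(index_date, each = n_day * 4L) + day_off[1] |
       labs$date == rep(index_date, each = n_day * 4L))
  labs <- labs[!drop, , drop = FALSE]

  ## -- diagnoses -----------------------------------------------------------
  dx_codes <- list(
    hypertension = "I10",
    diabetes = c("E10.9", "E11.9", "E14.9"),
    dyslipidemia = paste0("E78.", 0:5),
    heart_failure = c("I50.0", "I50.1", "I50.9"),
    sepsis = c("A40.0", "A41.9"))
  dx_list <- vector("list", length(dx_codes) + 1L)
  for (j in seq_along(dx_codes)) {
    cond <- names(dx_codes)[j]
    has <- stats::rbinom(n, 1L, config$comorbidity_prevalences[[cond]]) == 1L
    if (!any(has)) next
    dx_list[[j]] <- data.frame(
      patient_id = ids[has],
      icd10 = sample(dx_codes[[j]], sum(has), replace = TRUE),
      date = index_date[has] - sample(100:400, sum(has), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  liver <- roles == "liver_disease"
  if (any(liver)) {
    dx_list[[length(dx_list)]] <- data.frame(
      patient_id = ids[liver],
      icd10 = sample(c("B18.1", "K70.3", "C22.0", "K75.8"), sum(liver),
                     replace = TRUE),
      date = index_date[liver] - sample(30:300, sum(liver), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  diagnoses <- do.call(rbind, dx_list[!vapply(dx_list, is.null, logical(1))])
  if (is.null(diagnoses))
    diagnoses <- data.frame(patient_id = character(), icd10 = character(),
                            date = as.Date(character()),
                            stringsAsFactors = FALSE)

  ## -- prescriptions -------------------------------------------------------
  rx_list <- vector("list", n)
  n_conc_true <- integer(n)
  for (i in seq_len(n)) {
    rows <- list()
    exposed <- which(x[i, ] == 1L)
    for (d in exposed) {
      start <- sample(-90:0, 1L)
      supply <- max(1L, stats::rpois(1L, pm$days_supply_mean))
      if (start == 0L || stats::runif(1) < pm$p_span_index) {
        after <- if (start == 0L) integer(0) else sample(0:21, 1L)
        days <- c(start, after)
      } else {
        supply <- -start + sample(1:30, 1L)  # carries strictly past day 0
        days <- start
      }
      rows[[length(rows) + 1L]] <- data.frame(
        drug_code = catalog$drug_code[d], atc5 = catalog$atc5[d],
        day = days, days_of_supply = supply, stringsAsFactors = FALSE)
    }
    unexposed <- setdiff(seq_len(config$n_drugs), exposed)
    n_old <- min(stats::rpois(1L, pm$bg_old_mean), length(unexposed))
    old <- unexposed[sample.int(length(unexposed), n_old)]
    for (d in old) {  # started before the lookback window, spans the index
      rows[[length(rows) + 1L]] <- data.frame(
        drug_code = catalog$drug_code[d], atc5 = catalog$atc5[d],
        day = c(sample(-300:-120, 1L), sample(0:14, 1L)),
        days_of_supply = max(1L, stats::rpois(1L, pm$days_supply_mean)),
        stringsAsFactors = FALSE)
    }
    rest <- setdiff(unexposed, old)
    n_stop <- min(stats::rpois(1L, pm$bg_stopped_mean), length(rest))
    stopped <- rest[sample.int(length(rest), n_stop)]
    for (d in stopped) {  # started in lookback but not continued to index
      rows[[length(rows) + 1L]] <- data.frame(
        drug_code = catalog$drug_code[d], atc5 = catalog$atc5[d],
        day = sample(-85:-40, 1L), days_of_supply = sample(1:10, 1L),
        stringsAsFactors = FALSE)
    }
    if (roles[i] == "hepatoprotectant") {
      rows[[length(rows) + 1L]] <- data.frame(
        drug_code = "HEP01", atc5 = "A05AA02",
        day = sample(-60:-30, 1L), days_of_supply = 14L,
        stringsAsFactors = FALSE)
    }
    n_conc_true[i] <- length(exposed) + length(old)
    if (length(rows)) {
      rx <- do.call(rbind, rows)
      rx$patient_id <- ids[i]
      rx$date <- index_date[i] + rx$day
      rx_list[[i]] <- rx[, c("patient_id", "drug_code", "atc5", "date",
                             "days_of_supply")]
    }
  }
  prescriptions <- do.call(rbind,
                           rx_list[!vapply(rx_list, is.null, logical(1))])
  if (is.null(prescriptions))
    prescriptions <- data.frame(patient_id = character(),
                                drug_code = character(),
                                atc5 = character(), date = as.Date(character()),
                                days_of_supply = integer(),
                                stringsAsFactors = FALSE)
  rownames(prescriptions) <- NULL

  gt <- data.frame(patient_id = ids, role = roles, outcome = outcome,
                   linear_predictor = lp,
                   n_concomitant_true = n_conc_true,
                   stringsAsFactors = FALSE)
  gt <- cbind(gt, as.data.frame(x))

  out <- list(patients = patients, diagnoses = diagnoses,
              prescriptions = prescriptions, labs = labs,
              ground_truth = gt, catalog = catalog)
  class(out) <- "synthetic_ehr"
  out
}

#' Write / read the synthetic EHR tables
#'
#' Tables go to tab-separated files with ISO-8601 dates: `patients.tsv`,
#' `diagnoses.tsv`, `prescriptions.tsv`, `labs.tsv`, and the ground-truth
#' sidecar `ground_truth.tsv` (kept separate so pipeline code can never read
#' it by accident).
#'
#' @param ehr a `synthetic_ehr` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ehr_tables <- function(ehr, dir) {
  stopifnot(inherits(ehr, "synthetic_ehr"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("patients", "diagnoses", "prescriptions", "labs",
               "ground_truth")) {
    utils::write.table(ehr[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_ehr_tables
#' @export
read_ehr_tables <- function(dir) {
  rd <- function(nm) utils::read.table(file.path(dir, paste0(nm, ".tsv")),
                                       sep = "\t", header = TRUE,
                                       stringsAsFactors = FALSE)
  out <- list(patients = rd("patients"), diagnoses = rd("diagnoses"),
              prescriptions = rd("prescriptions"), labs = rd("labs"))
  out$patients$birth_date <- as.Date(out$patients$birth_date)
  for (nm in c("diagnoses", "prescriptions", "labs"))
    if (nrow(out[[nm]])) out[[nm]]$date <- as.Date(out[[nm]]$date)
  gt_path <- file.path(dir, "ground_truth.tsv")
  if (file.exists(gt_path))
    out$ground_truth <- utils::read.table(gt_path, sep = "\t", header = TRUE,
                                          stringsAsFactors = FALSE)
  class(out) <- "synthetic_ehr"
  out
}

#' Split EHR tables into per-patient bundles
#'
#' @param tables a list with `patients`, `diagnoses`, `prescriptions`,
#'   `labs` data frames (e.g. a `synthetic_ehr` object).
#' @return named list of patient bundles; each bundle is a list with the
#'   patient's demographics row and their `diagnoses`, `prescriptions`,
#'   `labs` sub-tables.
#' @export
patient_bundles <- function(tables) {
  ids <- tables$patients$patient_id
  dx <- split(tables$diagnoses,
              factor(tables$diagnoses$patient_id, levels = ids))
  rx <- split(tables$prescriptions,
              factor(tables$prescriptions$patient_id, levels = ids))
  lb <- split(tables$labs, factor(tables$labs$patient_id, levels = ids))
  out <- lapply(seq_along(ids), function(i) {
    list(patient_id = ids[i],
         birth_date = tables$patients$birth_date[i],
         sex = tables$patients$sex[i],
         hospital = tables$patients$hospital[i],
         diagnoses = dx[[i]], prescriptions = rx[[i]], labs = lb[[i]])
  })
  names(out) <- ids
  out
}
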