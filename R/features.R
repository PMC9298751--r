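#' Exposure rule parameters
#'
#' @param lookback_days a drug counts as newly started when its earliest
#'   prescription falls within this many days before the index date
#'   (inclusive on both ends). Default 90.
#' @param pair_min_patients minimum number of co-exposed patients for a drug
#'   pair to earn a product-term feature. Default 100.
#' @return object of class `exposure_rule`.
#' @export
exposure_rule <- function(lookback_days = 90L, pair_min_patients = 100L) {
  stopifnot(lookback_days > 0, pair_min_patients >= 1)
  structure(list(lookback_days = as.integer(lookback_days),
                 pair_min_patients = as.integer(pair_min_patients)),
            class = "exposure_rule")
}

#' Is a drug continued to the index date?
#'
#' A drug is continued when there is a prescription date on or before the
#' index date *and* one on or after it (a prescription on the index date
#' itself counts for both sides), or when the latest prescription date plus
#' its days of supply strictly exceeds the index date.
#'
#' @param dates prescription dates of one drug (Date or numeric).
#' @param days_of_supply days of supply for each prescription.
#' @param index_date the index date.
#' @return logical scalar; `FALSE` when there are no prescriptions.
#' @export
is_continued_to_index <- function(dates, days_of_supply, index_date) {
  if (length(dates) == 0L) return(FALSE)
  if (any(dates <= index_date) && any(dates >= index_date)) return(TRUE)
  last <- which.max(as.numeric(dates))
  as.numeric(dates[last] - index_date) + days_of_supply[last] > 0
}

#' New drug exposures at the index date
#'
#' A drug is an exposure when it was newly started within the lookback
#' window before the index date (earliest prescription within
#' `[index - lookback, index]`) and continued to the index date per
#' [is_continued_to_index()].
#'
#' @param bundle a patient bundle.
#' @param index_date the patient's index date.
#' @param rule an [exposure_rule()].
#' @return character vector of exposed drug codes (possibly empty).
#' @export
new_drug_exposures <- function(bundle, index_date, rule = exposure_rule()) {
  rx <- bundle$prescriptions
  if (is.null(rx) || nrow(rx) == 0L) return(character(0))
  out <- vapply(split(rx, rx$drug_code), function(d) {
    first <- min(d$date)
    as.numeric(index_date - first) <= rule$lookback_days &&
      first <= index_date &&
      is_continued_to_index(d$date, d$days_of_supply, index_date)
  }, logical(1))
  names(out)[out]
}

#' Number of concomitant drugs at the index date
#'
#' Counts distinct drugs continued to the index date irrespective of when
#' they were started.
#'
#' @inheritParams new_drug_exposures
#' @return nonnegative integer.
#' @export
count_concomitant_drugs <- function(bundle, index_date) {
  rx <- bundle$prescriptions
  if (is.null(rx) || nrow(rx) == 0L) return(0L)
  sum(vapply(split(rx, rx$drug_code), function(d)
    is_continued_to_index(d$date, d$days_of_supply, index_date), logical(1)))
}

#' Frequent co-exposed drug pairs
#'
#' Counts, over all patients, how often each unordered pair of drugs is
#' co-exposed, and keeps pairs reaching `pair_min_patients`. The frequent
#' drug set is the union of drugs appearing in at least one qualifying pair;
#' all other drugs are routed to the therapeutic-class rollup.
#'
#' @param exposures list of per-patient exposure sets (character vectors of
#'   drug codes).
#' @param rule an [exposure_rule()].
#' @return list with `pairs` (data frame `drug1`, `drug2`, `n_patients`,
#'   `drug1 < drug2` lexicographically) and `frequent_drugs` (character).
#' @export
frequent_pairs <- function(exposures, rule = exposure_rule()) {
  counts <- new.env(hash = TRUE)
  for (ex in exposures) {
    ex <- sort(unique(ex))
    k <- length(ex)
    if (k < 2L) next
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
      key <- paste(ex[i], ex[j], sep = "\r")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  keys <- ls(counts)
  n <- vapply(keys, function(k) counts[[k]], integer(1))
  keep <- n >= rule$pair_min_patients
  if (!any(keep)) {
    return(list(pairs = data.frame(drug1 = character(), drug2 = character(),
                                   n_patients = integer(),
                                   stringsAsFactors = FALSE),
                frequent_drugs = character(0)))
  }
  parts <- strsplit(keys[keep], "\r", fixed = TRUE)
  pairs <- data.frame(drug1 = vapply(parts, `[`, "", 1L),
                      drug2 = vapply(parts, `[`, "", 2L),
                      n_patients = unname(n[keep]), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$drug1, pairs$drug2), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       frequent_drugs = sort(unique(c(pairs$drug1, pairs$drug2))))
}

history_icd_prefixes <- function() {
  list(hypertension = "I10",
       diabetes = c("E10", "E11", "E14"),
       dyslipidemia = paste0("E78.", 0:5),
       heart_failure = c("I50.0", "I50.1", "I50.9"),
       sepsis = c("A40", "A41"))
}

#' Assemble the feature matrix
#'
#' Builds the patients-by-features table over the non-excluded cohort:
#' six demographics (age at index in years, male sex, one dummy per
#' hospital, concomitant-drug count), five medical-history flags (ICD-10
#' prefix matches at or before the index date: hypertension I10; diabetes
#' E10/E11/E14; dyslipidemia E78.0--E78.5; heart failure I50.0/I50.1/I50.9;
#' sepsis A40/A41), one flag per frequent drug, one product term per
#' qualifying pair (elementwise product of the parent flags), and one
#' presence flag per therapeutic class collecting the non-frequent exposures
#' via their ATC level-4 prefix. The column count is always
#' `6 + 5 + D + P + C`. The matrix has no missing values.
#'
#' @param cohort cohort label table from [build_cohort()].
#' @param tables the EHR tables the cohort was built from.
#' @param rule an [exposure_rule()].
#' @param atc_class_map data frame `atc4`, `class` mapping ATC level-4
#'   prefixes to therapeutic classes; defaults to a synthetic map covering
#'   the codes present. Drugs with no mapped level-4 prefix are routed to an
#'   `"unclassified"` class (with a message).
#' @param catalog optional pre-specified feature sets, a list with
#'   `frequent_drugs` (character) and `pairs` (data frame `drug1`, `drug2`):
#'   when supplied, pair counting is skipped and the matrix is laid out
#'   against this catalog (columns of drugs never seen by a patient are
#'   all-zero). Classes may likewise be fixed via `classes` (character).
#' @return list with `x` (numeric matrix, rownames = patient ids),
#'   `outcome` (1 = case, 0 = control), `catalog` (data frame `name`,
#'   `kind`, `parent1`, `parent2`), `pairs` (with co-exposure counts when
#'   computed here).
#' @export
assemble_feature_matrix <- function(cohort, tables, rule = exposure_rule(),
                                    atc_class_map = NULL, catalog = NULL) {
  keep <- cohort$status %in% c("case", "control")
  cohort <- cohort[keep, , drop = FALSE]
  bundles <- patient_bundles(tables)[cohort$patient_id]
  n <- nrow(cohort)
  idx_date <- cohort$index_date

  exposures <- lapply(seq_len(n), function(i)
    new_drug_exposures(bundles[[i]], idx_date[i], rule))

  if (is.null(catalog)) {
    fp <- frequent_pairs(exposures, rule)
    pairs <- fp$pairs
    freq_drugs <- fp$frequent_drugs
    fixed_classes <- NULL
  } else {
    pairs <- as.data.frame(catalog$pairs)
    freq_drugs <- catalog$frequent_drugs
    fixed_classes <- catalog$classes
  }

  ## therapeutic-class rollup of the non-frequent drugs
  all_drugs <- sort(unique(unlist(exposures)))
  infreq <- setdiff(all_drugs, freq_drugs)
  atc_of <- tables$prescriptions$atc5[
    match(infreq, tables$prescriptions$drug_code)]
  if (is.null(atc_class_map))
    atc_class_map <- default_atc_class_map(atc_of[!is.na(atc_of)])
  cls_of <- atc_class_map$class[match(substr(atc_of, 1L, 5L),
                                      atc_class_map$atc4)]
  if (anyNA(cls_of)) {
    message(sum(is.na(cls_of)),
            " infrequent drug(s) had no ATC level-4 mapping; ",
            "routed to class 'unclassified'")
    cls_of[is.na(cls_of)] <- "unclassified"
  }
  names(cls_of) <- infreq
  classes <- if (is.null(fixed_classes)) sort(unique(cls_of)) else
    fixed_classes

  hospitals <- sort(unique(tables$patients$hospital))
  hist_pref <- history_icd_prefixes()

  D <- length(freq_drugs); P <- nrow(pairs); C <- length(classes)
  cn <- c("age", "sex_male", paste0("hospital_", hospitals), "n_concomitant",
          paste0("hist_", names(hist_pref)),
          freq_drugs,
          if (P) paste0(pairs$drug1, "*", pairs$drug2),
          if (C) paste0("class_", classes))
  x <- matrix(0, nrow = n, ncol = length(cn),
              dimnames = list(cohort$patient_id, cn))

  for (i in seq_len(n)) {
    b <- bundles[[i]]
    x[i, "age"] <- age_at(b$birth_date, idx_date[i])
    x[i, "sex_male"] <- as.numeric(b$sex == "male")
    x[i, paste0("hospital_", b$hospital)] <- 1
    x[i, "n_concomitant"] <- count_concomitant_drugs(b, idx_date[i])
    dx <- b$diagnoses
    if (!is.null(dx) && nrow(dx)) {
      dx <- dx[dx$date <= idx_date[i], , drop = FALSE]
      for (h in names(hist_pref))
        x[i, paste0("hist_", h)] <-
          as.numeric(any(starts_with_any(dx$icd10, hist_pref[[h]])))
    }
    ex <- exposures[[i]]
    hit <- intersect(ex, freq_drugs)
    if (length(hit)) x[i, hit] <- 1
    ex_cls <- unique(cls_of[intersect(ex, infreq)])
    ex_cls <- intersect(ex_cls, classes)
    if (length(ex_cls)) x[i, paste0("class_", ex_cls)] <- 1
  }
  if (P) {
    pn <- paste0(pairs$drug1, "*", pairs$drug2)
    x[, pn] <- x[, pairs$drug1, drop = FALSE] *
      x[, pairs$drug2, drop = FALSE]
  }

  feat_catalog <- data.frame(
    name = cn,
    kind = c("demographic", "demographic",
             rep("demographic", length(hospitals)), "demographic",
             rep("history", length(hist_pref)),
             rep("drug", D), rep("product", P), rep("class", C)),
    parent1 = c(rep(NA_character_, 3 + length(hospitals) + 5 + D),
                if (P) pairs$drug1, rep(NA_character_, C)),
    parent2 = c(rep(NA_character_, 3 + length(hospitals) + 5 + D),
                if (P) pairs$drug2, rep(NA_character_, C)),
    stringsAsFactors = FALSE)

  list(x = x, outcome = as.numeric(cohort$status == "case"),
       catalog = feat_catalog, pairs = pairs,
       class_map = cls_of)
}
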