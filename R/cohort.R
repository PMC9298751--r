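#' Cohort selection criteria
#'
#' Thresholds and code lists governing case/control assignment: the ALT
#' normal range (4.0--44.0 U/L), the case threshold (3x the upper limit of
#' normal, 132.0 U/L, strict), the measurement-frequency rule (at least
#' `min_tests` ALT measurement days within a `window_days`-day span), the
#' adult-age cutoff, and the ICD-10 prefixes / ATC codes driving the
#' liver-disease and hepatoprotectant exclusions.
#'
#' The liver-disease prefix list shipped as default covers the disease
#' groups the exclusion targets (infectious hepatitis B15--B19, alcoholic
#' liver disease K70, other hepatic disorders K71--K77 including NAFLD,
#' malignant neoplasm of liver C22); it is a configurable stand-in, not a
#' validated clinical code set.
#'
#' @param alt_normal_low,alt_normal_high ALT normal range bounds, U/L
#'   (closed interval).
#' @param alt_case_threshold case cutoff, U/L; a case requires index ALT
#'   strictly above it.
#' @param min_tests minimum number of ALT measurement days in a qualifying
#'   span (>= 3).
#' @param window_days span length in days; inclusive day arithmetic, a span
#'   qualifies when (last day - first day) <= `window_days`.
#' @param min_age_years minimum age at the index date.
#' @param liver_disease_icd_prefixes ICD-10 code prefixes triggering the
#'   pre-existing liver-disease exclusion.
#' @param hepatoprotectant_atc_codes ATC level-5 codes (plus non-ATC product
#'   codes, matched against the drug code) triggering the hepatoprotectant
#'   exclusion: glycyrrhizic acid A05BA08, glutathione V03AB32, lactulose
#'   A06AD11, L-arginine glutamate A05BA01, tiopronin G04BX16, lactitol
#'   A06AD12, rifaximin A07AA11, ursodeoxycholic acid A05AA02.
#' @return object of class `cohort_criteria`.
#' @export
cohort_criteria <- function(alt_normal_low = 4.0,
                            alt_normal_high = 44.0,
                            alt_case_threshold = 132.0,
                            min_tests = 3L,
                            window_days = 90L,
                            min_age_years = 18L,
                            liver_disease_icd_prefixes = c(
                              "B15", "B16", "B17", "B18", "B19",
                              "K70", "K71", "K72", "K73", "K74", "K75",
                              "K76", "K77", "C22"),
                            hepatoprotectant_atc_codes = c(
                              "A05BA08", "V03AB32", "A06AD11", "A05BA01",
                              "G04BX16", "A06AD12", "A07AA11", "A05AA02")) {
  stopifnot(alt_normal_low < alt_normal_high,
            alt_normal_high < alt_case_threshold,
            min_tests >= 3L, window_days > 0)
  structure(list(alt_normal_low = alt_normal_low,
                 alt_normal_high = alt_normal_high,
                 alt_case_threshold = alt_case_threshold,
                 min_tests = as.integer(min_tests),
                 window_days = as.integer(window_days),
                 min_age_years = as.integer(min_age_years),
                 liver_disease_icd_prefixes = liver_disease_icd_prefixes,
                 hepatoprotectant_atc_codes = hepatoprotectant_atc_codes),
            class = "cohort_criteria")
}

#' Select the anchor ALT measurements
#'
#' Scans a patient's ALT record for the earliest span of at most
#' `window_days` days holding at least `min_tests` distinct measurement
#' days. Within that span the two earliest days become the first and second
#' measurement days and the latest day becomes the index date. Multiple ALT
#' values on one calendar day are not expected (the generator never emits
#' them); if present the first is used.
#'
#' @param labs data frame of one patient's labs with columns `test`,
#'   `value`, `date` (Date or numeric day).
#' @param criteria a [cohort_criteria()].
#' @return list with either `reason = "too_few_tests"` or the anchor
#'   `first_date`, `second_date`, `index_date`, the matching ALT values
#'   `first_alt`, `second_alt`, `index_alt`, and `span_alt` (all ALT values
#'   in the span, dated).
#' @export
select_eligible_measurements <- function(labs, criteria = cohort_criteria()) {
  alt <- labs[labs$test == "ALT", , drop = FALSE]
  if (nrow(alt) == 0L) return(list(reason = "too_few_tests"))
  alt <- alt[!duplicated(alt$date), , drop = FALSE]
  alt <- alt[order(alt$date), , drop = FALSE]
  days <- alt$date
  if (length(days) >= criteria$min_tests) {
    for (i in seq_len(length(days) - criteria$min_tests + 1L)) {
      in_span <- which(as.numeric(days - days[i]) <= criteria$window_days &
                         days >= days[i])
      if (length(in_span) >= criteria$min_tests) {
        span <- alt[in_span, , drop = FALSE]
        k <- nrow(span)
        return(list(first_date = span$date[1], second_date = span$date[2],
                    index_date = span$date[k],
                    first_alt = span$value[1], second_alt = span$value[2],
                    index_alt = span$value[k], span_alt = span,
                    reason = NULL))
      }
    }
  }
  list(reason = "too_few_tests")
}

#' Assign case/control status from the anchor ALT values
#'
#' A patient whose first two ALT values sit in the normal range is a case
#' when the index-date ALT strictly exceeds the case threshold, a control
#' when every ALT in the span (index date included) stays within the normal
#' range, and excluded otherwise: `intermediate_alt` when an ALT is above
#' the normal range but the index value does not exceed the threshold, and
#' `below_range_alt` when an ALT falls below the normal range (the rules
#' define neither a case nor a "within normal range on all days" control for
#' such values).
#'
#' @param first_alt,second_alt,index_alt ALT values (U/L) on the three
#'   anchor days.
#' @param span_alt all ALT values in the qualifying span (must include the
#'   index value).
#' @param criteria a [cohort_criteria()].
#' @return list with `status` (`"case"`, `"control"`, `"excluded"`) and
#'   `reason` (`"none"` unless excluded).
#' @export
assign_outcome <- function(first_alt, second_alt, index_alt, span_alt = NULL,
                           criteria = cohort_criteria()) {
  if (is.na(index_alt)) return(list(status = "excluded",
                                    reason = "missing_labs"))
  lo <- criteria$alt_normal_low
  hi <- criteria$alt_normal_high
  in_range <- function(v) v >= lo & v <= hi
  if (!in_range(first_alt) || !in_range(second_alt))
    return(list(status = "excluded", reason = "first_two_not_normal"))
  if (index_alt > criteria$alt_case_threshold)
    return(list(status = "case", reason = "none"))
  if (is.null(span_alt)) span_alt <- c(first_alt, second_alt, index_alt)
  if (all(in_range(span_alt)))
    return(list(status = "control", reason = "none"))
  if (any(span_alt < lo))
    return(list(status = "excluded", reason = "below_range_alt"))
  list(status = "excluded", reason = "intermediate_alt")
}

age_at <- function(birth_date, at_date) {
  floor(as.numeric(at_date - birth_date) / 365.25)
}

starts_with_any <- function(x, prefixes) {
  out <- rep(FALSE, length(x))
  for (p in prefixes) out <- out | startsWith(x, p)
  out
}

#' Apply the four eligibility exclusions to a provisional label
#'
#' Exclusions are tested in a fixed order so the recorded reason is
#' reproducible: under age, missing liver panel, pre-existing liver disease,
#' hepatoprotectant use. The liver-panel rule excludes only when one of
#' ALT/AST/TBL/ALP is absent on *both* the first measurement day and the
#' index date; absence on a single day is tolerated. Diagnosis and
#' prescription matches count at any date up to and including the index
#' date.
#'
#' @param bundle a patient bundle (see [patient_bundles()]).
#' @param label provisional label list with `status`, `reason`,
#'   `first_date`, `index_date`.
#' @param criteria a [cohort_criteria()].
#' @return the final label list (same shape, possibly flipped to excluded).
#' @export
apply_exclusions <- function(bundle, label, criteria = cohort_criteria()) {
  if (identical(label$status, "excluded")) return(label)
  excl <- function(reason) {
    label$status <- "excluded"; label$reason <- reason; label
  }
  if (age_at(bundle$birth_date, label$index_date) < criteria$min_age_years)
    return(excl("under_age"))
  labs <- bundle$labs
  for (tst in c("ALT", "AST", "TBL", "ALP")) {
    on_first <- any(labs$test == tst & labs$date == label$first_date)
    on_index <- any(labs$test == tst & labs$date == label$index_date)
    if (!on_first && !on_index) return(excl("missing_labs"))
  }
  dx <- bundle$diagnoses
  if (!is.null(dx) && nrow(dx)) {
    hit <- starts_with_any(dx$icd10, criteria$liver_disease_icd_prefixes) &
      dx$date <= label$index_date
    if (any(hit)) return(excl("liver_disease"))
  }
  rx <- bundle$prescriptions
  if (!is.null(rx) && nrow(rx)) {
    hit <- (rx$atc5 %in% criteria$hepatoprotectant_atc_codes |
              rx$drug_code %in% criteria$hepatoprotectant_atc_codes) &
      rx$date <= label$index_date
    if (any(hit)) return(excl("hepatoprotectant"))
  }
  label
}

#' Build the full cohort label table
#'
#' Runs anchor-measurement selection, outcome assignment and the exclusion
#' cascade for every patient, producing an exhaustive, mutually exclusive
#' partition into cases, controls and excluded patients with a recorded
#' reason.
#'
#' @param tables EHR tables (list with `patients`, `diagnoses`,
#'   `prescriptions`, `labs`) or a `synthetic_ehr` object.
#' @param criteria a [cohort_criteria()].
#' @return data frame with one row per patient: `patient_id`, `status`,
#'   `exclusion_reason`, `first_date`, `second_date`, `index_date` (dates
#'   `NA` when no qualifying span exists).
#' @export
build_cohort <- function(tables, criteria = cohort_criteria()) {
  bundles <- patient_bundles(tables)
  rows <- lapply(bundles, function(b) {
    sel <- select_eligible_measurements(b$labs, criteria)
    if (!is.null(sel$reason)) {
      return(data.frame(patient_id = b$patient_id, status = "excluded",
                        exclusion_reason = sel$reason,
                        first_date = as.Date(NA), second_date = as.Date(NA),
                        index_date = as.Date(NA), stringsAsFactors = FALSE))
    }
    out <- assign_outcome(sel$first_alt, sel$second_alt, sel$index_alt,
                          sel$span_alt$value, criteria)
    label <- list(status = out$status, reason = out$reason,
                  first_date = sel$first_date, second_date = sel$second_date,
                  index_date = sel$index_date)
    label <- apply_exclusions(b, label, criteria)
    data.frame(patient_id = b$patient_id, status = label$status,
               exclusion_reason = label$reason,
               first_date = label$first_date,
               second_date = label$second_date,
               index_date = label$index_date, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
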