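test_that("anchor-measurement selection finds the earliest qualifying span", {
  crit <- cohort_criteria()
  sel <- select_eligible_measurements(alt_labs(c(0, 30, 80), c(20, 30, 25)),
                                      crit)
  expect_equal(sel$first_date, DAY0)
  expect_equal(sel$second_date, DAY0 + 30)
  expect_equal(sel$index_date, DAY0 + 80)

  # no 90-day span holds three measurement days
  sel <- select_eligible_measurements(alt_labs(c(0, 50, 120), c(20, 30, 25)),
                                      crit)
  expect_equal(sel$reason, "too_few_tests")

  # more than three days in the span: first, second and latest of the span
  sel <- select_eligible_measurements(
    alt_labs(c(0, 10, 40, 85), c(20, 22, 24, 26)), crit)
  expect_equal(sel$first_date, DAY0)
  expect_equal(sel$second_date, DAY0 + 10)
  expect_equal(sel$index_date, DAY0 + 85)
  expect_equal(nrow(sel$span_alt), 4L)

  # the early pair alone cannot qualify; the window slides to days 40-120
  sel <- select_eligible_measurements(
    alt_labs(c(0, 40, 100, 120), c(20, 22, 24, 150)), crit)
  expect_equal(sel$first_date, DAY0 + 40)
  expect_equal(sel$index_date, DAY0 + 120)

  expect_equal(select_eligible_measurements(
    alt_labs(integer(0), numeric(0)), crit)$reason, "too_few_tests")
})

test_that("outcome assignment follows the ALT thresholds", {
  crit <- cohort_criteria()
  expect_equal(assign_outcome(20, 30, 150, c(20, 30, 150), crit)$status,
               "case")
  out <- assign_outcome(20, 30, 40, c(20, 30, 40), crit)
  expect_equal(out$status, "control")
  expect_equal(out$reason, "none")
  out <- assign_outcome(20, 30, 100, c(20, 30, 100), crit)
  expect_equal(out$status, "excluded")
  expect_equal(out$reason, "intermediate_alt")
  # boundaries: normal range is closed, the case cutoff is strict
  expect_equal(assign_outcome(4, 44, 132, c(4, 44, 132), crit)$reason,
               "intermediate_alt")
  expect_equal(assign_outcome(4, 44, 132.01, c(4, 44, 132.01), crit)$status,
               "case")
  expect_equal(assign_outcome(20, 50, 150, c(20, 50, 150), crit)$reason,
               "first_two_not_normal")
  expect_equal(assign_outcome(20, 30, 3, c(20, 30, 3), crit)$reason,
               "below_range_alt")
  expect_equal(assign_outcome(20, 30, NA, NULL, crit)$reason,
               "missing_labs")
})

test_that("exclusion cascade fires in its fixed order", {
  crit <- cohort_criteria()
  label <- list(status = "control", reason = "none",
                first_date = DAY0, second_date = DAY0 + 30,
                index_date = DAY0 + 60)
  base <- make_bundle(birth_date = as.Date("1960-01-01"),
                      labs = full_panel(c(0, 30, 60), c(20, 22, 24)))

  # age 17 at index
  minor <- base; minor$birth_date <- DAY0 + 60 - round(17.5 * 365.25)
  expect_equal(apply_exclusions(minor, label, crit)$reason, "under_age")

  # AST absent on the first day only: not excluded
  labs1 <- base$labs
  labs1 <- labs1[!(labs1$test == "AST" & labs1$date == DAY0), ]
  one_day <- base; one_day$labs <- labs1
  expect_equal(apply_exclusions(one_day, label, crit)$status, "control")

  # AST absent on both anchor days: excluded
  labs2 <- base$labs
  labs2 <- labs2[!(labs2$test == "AST" &
                     labs2$date %in% c(DAY0, DAY0 + 60)), ]
  both_days <- base; both_days$labs <- labs2
  expect_equal(apply_exclusions(both_days, label, crit)$reason,
               "missing_labs")

  # pre-existing liver disease at any date up to the index date
  liver <- base
  liver$diagnoses <- data.frame(icd10 = "K70.3", date = DAY0 - 100,
                                stringsAsFactors = FALSE)
  expect_equal(apply_exclusions(liver, label, crit)$reason, "liver_disease")
  after <- base
  after$diagnoses <- data.frame(icd10 = "K70.3", date = DAY0 + 90,
                                stringsAsFactors = FALSE)
  expect_equal(apply_exclusions(after, label, crit)$status, "control")

  # ursodeoxycholic acid (A05AA02) before the index date
  urso <- base
  urso$prescriptions <- rx_rows("UDCA", -20, 14, atc5 = "A05AA02")
  expect_equal(apply_exclusions(urso, label, crit)$reason,
               "hepatoprotectant")

  # precedence: a minor with liver disease is recorded as under_age
  both <- minor
  both$diagnoses <- data.frame(icd10 = "K70.3", date = DAY0 - 100,
                               stringsAsFactors = FALSE)
  expect_equal(apply_exclusions(both, label, crit)$reason, "under_age")
})

test_that("cohort labels partition patients exhaustively and exclusively", {
  ehr <- generate_cohort(contaminated_config(n = 400))
  coh <- build_cohort(ehr)
  expect_equal(nrow(coh), 400L)
  expect_true(all(coh$status %in% c("case", "control", "excluded")))
  expect_true(all((coh$status == "excluded") ==
                    (coh$exclusion_reason != "none")))
  ok <- coh$status != "excluded"
  expect_true(all(coh$index_date[ok] >= coh$second_date[ok]))
  expect_true(all(coh$second_date[ok] > coh$first_date[ok]))
})

test_that("generator ground truth round-trips through the cohort builder", {
  ehr <- generate_cohort(contaminated_config(n = 800))
  coh <- build_cohort(ehr)
  m <- merge(coh, ehr$ground_truth, by = "patient_id")
  clean <- m$role == "clean"
  expect_true(all(m$status[clean] == ifelse(m$outcome[clean] == 1,
                                            "case", "control")))
  contaminated <- m[!clean, ]
  expected_reason <- c(minor = "under_age", missing_labs = "missing_labs",
                       liver_disease = "liver_disease",
                       hepatoprotectant = "hepatoprotectant")
  expect_true(all(contaminated$status == "excluded"))
  expect_true(all(contaminated$exclusion_reason ==
                    expected_reason[contaminated$role]))
})

test_that("raising the case threshold never converts a control into a case", {
  ehr <- generate_cohort(contaminated_config(n = 300))
  lo <- build_cohort(ehr, cohort_criteria(alt_case_threshold = 132))
  hi <- build_cohort(ehr, cohort_criteria(alt_case_threshold = 200))
  was_control <- lo$patient_id[lo$status == "control"]
  expect_true(all(hi$status[hi$patient_id %in% was_control] == "control"))
  # cases can only stay cases or drop to intermediate exclusion
  was_case <- lo$patient_id[lo$status == "case"]
  expect_true(all(hi$status[hi$patient_id %in% was_case] %in%
                    c("case", "excluded")))
})

test_that("shipped code-list fixtures agree with the coded defaults", {
  crit <- cohort_criteria()
  hep <- read.delim(system.file("extdata", "hepatoprotectant_atc.tsv",
                                package = "altsynergy"))
  expect_setequal(hep$atc5, crit$hepatoprotectant_atc_codes)
  liv <- read.delim(system.file("extdata",
                                "liver_disease_icd10_synthetic.tsv",
                                package = "altsynergy"))
  expect_setequal(liv$icd10_prefix, crit$liver_disease_icd_prefixes)
})
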