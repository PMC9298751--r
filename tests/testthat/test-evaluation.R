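test_that("confusion matrices count the four cells at a threshold", {
  scores <- c(0.9, 0.8, 0.2, 0.1)
  labels <- c(1, 1, 0, 0)
  cm <- confusion_at_threshold(scores, labels, 0.5)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(2, 0, 0, 2))
  cm0 <- confusion_at_threshold(rep(0, 4), labels, 0.5)
  expect_equal(c(cm0$tp, cm0$fp), c(0, 0))
  expect_equal(cm0$fn, 2)
  # cell total equals the number of patients
  set.seed(2)
  s <- runif(50); l <- rbinom(50, 1, 0.3)
  cm <- confusion_at_threshold(s, l, 0.4)
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 50)
})

test_that("threshold metrics match brute-force recounts and handle zeros", {
  set.seed(3)
  for (i in 1:20) {
    cells <- rmultinom(1, 200, c(0.2, 0.3, 0.1, 0.4))
    cm <- confusion_matrix(cells[1], cells[2], cells[3], cells[4])
    m <- suppressWarnings(threshold_metrics(cm))
    if (cells[1] + cells[3] > 0)
      expect_equal(m$sensitivity, 100 * cells[1] / (cells[1] + cells[3]))
    if (cells[4] + cells[2] > 0)
      expect_equal(m$specificity, 100 * cells[4] / (cells[4] + cells[2]))
  }
  perfect <- threshold_metrics(confusion_matrix(50, 0, 0, 50))
  expect_equal(unlist(perfect),
               c(sensitivity = 100, ppv = 100, specificity = 100,
                 npv = 100, f1 = 1))
  expect_warning(m <- threshold_metrics(confusion_matrix(0, 0, 5, 95)),
                 "PPV undefined")
  expect_true(is.na(m$ppv))
})

test_that("AUROC equals the all-pairs concordance oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0),
                       ci = FALSE)$auroc, 1.0)
  set.seed(4)
  for (i in 1:5) {
    n <- 150
    scores <- round(runif(n), 2)  # rounding forces ties
    labels <- rbinom(n, 1, 0.35)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels, ci = FALSE)$auroc,
                 oracle_concordance(scores, labels), tolerance = 1e-10)
  }
})

test_that("random scores give a null AUROC of one half", {
  set.seed(5)
  scores <- runif(10000)
  labels <- rbinom(10000, 1, 0.5)
  expect_lt(abs(roc_auc(scores, labels, ci = FALSE)$auroc - 0.5), 0.02)
})

test_that("ROC and PR areas are invariant to monotone score transforms", {
  set.seed(6)
  scores <- runif(300)
  labels <- rbinom(300, 1, 0.3)
  trans <- plogis(5 * scores - 2)  # strictly increasing
  expect_equal(roc_auc(scores, labels, ci = FALSE)$auroc,
               roc_auc(trans, labels, ci = FALSE)$auroc)
  expect_equal(pr_auc(scores, labels), pr_auc(trans, labels))
})

test_that("AUPR behaves at the edges and under imbalance", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # all-equal scores: a single step with precision = prevalence
  expect_equal(pr_auc(rep(0.4, 100), rep(c(1, 0), c(10, 90))), 0.1)
  set.seed(7)
  s <- runif(2000); l <- rbinom(2000, 1, 0.07)
  a <- pr_auc(s, l)
  expect_true(a > 0.02 && a < 0.2)  # near prevalence for useless scores
})

test_that("DeLong comparisons are symmetric and degenerate correctly", {
  set.seed(8)
  n <- 300
  labels <- rbinom(n, 1, 0.3)
  sa <- runif(n)
  sb <- plogis(rnorm(n) + labels)
  same <- delong_test(sa, sa, labels)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  ab <- delong_test(sa, sb, labels)
  ba <- delong_test(sb, sa, labels)
  expect_equal(ab$statistic, -ba$statistic, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
})

test_that("DeLong variance agrees with a bootstrap of the AUROC", {
  set.seed(9)
  n <- 400
  labels <- rbinom(n, 1, 0.3)
  scores <- plogis(rnorm(n, mean = labels))
  v_delong <- delong_variance(scores, labels)
  B <- 1200
  aucs <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    while (length(unique(labels[idx])) < 2)
      idx <- sample.int(n, n, replace = TRUE)
    aucs[b] <- oracle_concordance(scores[idx], labels[idx])
  }
  v_boot <- var(aucs)
  expect_lt(abs(v_delong - v_boot) / v_boot, 0.25)
})

test_that("calibration curves sit on the diagonal for honest probabilities", {
  set.seed(10)
  scores <- runif(5000)
  labels <- rbinom(5000, 1, scores)
  cal <- calibration_curve(scores, labels, n_bins = 10)
  expect_true(all(abs(cal$observed_rate - cal$mean_predicted) <=
                    3 * sqrt(cal$mean_predicted *
                               (1 - cal$mean_predicted) / cal$n) + 0.01))
  # constant score whose outcome rate matches: a single diagonal point
  cal1 <- calibration_curve(rep(0.3, 10), rep(c(1, 0), c(3, 7)), 10)
  expect_equal(nrow(cal1), 1L)
  expect_equal(cal1$mean_predicted, 0.3)
  expect_equal(cal1$observed_rate, 0.3)
  # all-negative labels: observed rate zero in every occupied bin
  cal0 <- calibration_curve(runif(200), rep(0, 200), 5)
  expect_true(all(cal0$observed_rate == 0))
})

test_that("importance reports rank product terms and truncate correctly", {
  set.seed(11)
  n <- 300
  x <- cbind("D001" = rbinom(n, 1, 0.5), "D002" = rbinom(n, 1, 0.5))
  x <- cbind(x, "D001*D002" = x[, 1] * x[, 2],
             noise = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-1 + 2 * x[, "D001*D002"]))
  fit <- fit_gbt(x, y, nrounds = 20, seed = 2)
  rep_all <- importance_report(fit, top_k = 100)
  expect_lte(nrow(rep_all), 4L)  # never longer than the used-feature set
  expect_equal(sum(rep_all$gain), 1, tolerance = 1e-8)
  expect_true(rep_all$is_product_term[rep_all$feature == "D001*D002"])
  expect_equal(rep_all$gain, sort(rep_all$gain, decreasing = TRUE))
  expect_equal(nrow(importance_report(fit, top_k = 2)), 2L)
})

test_that("cohort summaries run the stated tests per characteristic", {
  ehr <- generate_cohort(sim_config(600, 4, seed = 23))
  coh <- build_cohort(ehr)
  fx <- assemble_feature_matrix(coh, ehr)
  tab <- cohort_summary(fx)
  expect_true(all(c("Age (years), mean (SD)", "Male, n (%)",
                    "Concomitant drugs, median (IQR)") %in%
                    tab$characteristic))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))

  # Welch t on age matches the closed-form statistic
  case <- fx$outcome == 1
  a <- fx$x[case, "age"]; b <- fx$x[!case, "age"]
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  df <- (var(a) / length(a) + var(b) / length(b))^2 /
    ((var(a) / length(a))^2 / (length(a) - 1) +
       (var(b) / length(b))^2 / (length(b) - 1))
  p_hand <- 2 * pt(-abs(tstat), df)
  expect_equal(tab$p_value[tab$characteristic == "Age (years), mean (SD)"],
               p_hand, tolerance = 1e-10)

  # identical groups: p-values near 1
  fake <- list(x = fx$x[c(1:50, 1:50), ], outcome = rep(c(1, 0), each = 50))
  tab2 <- suppressWarnings(cohort_summary(fake))
  expect_true(all(tab2$p_value > 0.9, na.rm = TRUE))
})

test_that("training AUROC dominates test AUROC for an over-fit wide model", {
  set.seed(12)
  n <- 160
  x <- matrix(rbinom(n * 80, 1, 0.4), n, 80,
              dimnames = list(NULL, paste0("w", 1:80)))
  y <- rbinom(n, 1, plogis(-1 + 0.8 * x[, 1]))
  sp <- split_data(x, y, split_spec(0.7, seed = 3))
  fit <- suppressWarnings(fit_mlr(sp$train$x, sp$train$outcome))
  auc_tr <- roc_auc(predict(fit, sp$train$x), sp$train$outcome,
                    ci = FALSE)$auroc
  auc_te <- roc_auc(predict(fit, sp$test$x), sp$test$outcome,
                    ci = FALSE)$auroc
  expect_gte(auc_tr, auc_te)
})
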