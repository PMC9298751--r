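#' Confusion matrix at a probability threshold
#'
#' A patient is predicted a case when the score is greater than or equal to
#' the threshold.
#'
#' @param scores predicted probabilities in `[0, 1]`.
#' @param labels 0/1 outcomes.
#' @param threshold decision threshold.
#' @return object of class `confusion_matrix`: list with `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels),
            all(scores >= 0 & scores <= 1), all(labels %in% c(0, 1)))
  pred <- as.integer(scores >= threshold)
  structure(list(tp = sum(pred == 1L & labels == 1),
                 fp = sum(pred == 1L & labels == 0),
                 fn = sum(pred == 0L & labels == 1),
                 tn = sum(pred == 0L & labels == 0),
                 threshold = threshold),
            class = "confusion_matrix")
}

#' Construct a confusion matrix from cell counts
#'
#' @param tp,fp,fn,tn nonnegative cell counts.
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, threshold = NA_real_),
            class = "confusion_matrix")
}

#' Threshold classification metrics
#'
#' Sensitivity (recall), positive predictive value (precision),
#' specificity and negative predictive value as percentages, plus the
#' F1-score on the 0--1 scale:
#' sensitivity = TP/(TP+FN), PPV = TP/(TP+FP), specificity = TN/(TN+FP),
#' NPV = TN/(TN+FN), F1 = 2TP/(2TP+FP+FN). A metric with a zero
#' denominator is reported as `NA` with a warning, never silently as 0.
#'
#' @param cm a `confusion_matrix`.
#' @return list with `sensitivity`, `ppv`, `specificity`, `npv`
#'   (percentages) and `f1`.
#' @export
threshold_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  rate <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NA_real_)
    }
    100 * num / den
  }
  list(sensitivity = rate(cm$tp, cm$tp + cm$fn, "sensitivity"),
       ppv = rate(cm$tp, cm$tp + cm$fp, "PPV"),
       specificity = rate(cm$tn, cm$tn + cm$fp, "specificity"),
       npv = rate(cm$tn, cm$tn + cm$fn, "NPV"),
       f1 = if (2 * cm$tp + cm$fp + cm$fn == 0) NA_real_ else
         2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn))
}

make_roc <- function(scores, labels) {
  pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
            direction = "<", quiet = TRUE)
}

#' Area under the ROC curve (C statistic)
#'
#' Concordance-statistic AUROC with a 95% DeLong confidence interval
#' (via pROC).
#'
#' @param scores predicted probabilities or any monotone risk score.
#' @param labels 0/1 outcomes; both classes must be present.
#' @param ci compute the DeLong interval (default `TRUE`).
#' @return list with `auroc` and, when requested, `ci_low`, `ci_high`.
#' @export
roc_auc <- function(scores, labels, ci = TRUE) {
  stopifnot(length(unique(labels)) == 2L)
  r <- make_roc(scores, labels)
  out <- list(auroc = as.numeric(pROC::auc(r)))
  if (ci) {
    ci_ <- pROC::ci.auc(r, method = "delong")
    out$ci_low <- ci_[1]
    out$ci_high <- ci_[3]
  }
  out
}

#' Area under the precision-recall curve
#'
#' Step-wise integration (average-precision form): with the observations
#' ranked by decreasing score, AUPR is the sum over distinct thresholds of
#' precision times the recall increment,
#' \eqn{\sum_k P_k (R_k - R_{k-1})}. No interpolation between points, so a
#' strictly monotone transform of the scores leaves the value unchanged.
#'
#' @inheritParams roc_auc
#' @return AUPR in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), sum(labels == 1) > 0)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  # keep the last row of each tied-score block
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / sum(labels == 1)
  sum(precision * diff(c(0, recall)))
}

#' DeLong test for two correlated AUROCs
#'
#' Nonparametric comparison of the AUROCs of two models scored on the same
#' test patients (paired), via pROC's DeLong implementation.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels shared 0/1 outcomes.
#' @return list with `auroc_a`, `auroc_b`, `difference`, `statistic`
#'   (z value) and two-sided `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  ra <- make_roc(scores_a, labels)
  rb <- make_roc(scores_b, labels)
  if (identical(as.numeric(scores_a), as.numeric(scores_b))) {
    # identical predictions: zero difference with zero variance
    return(list(auroc_a = as.numeric(pROC::auc(ra)),
                auroc_b = as.numeric(pROC::auc(rb)),
                difference = 0, statistic = 0, p_value = 1))
  }
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  list(auroc_a = as.numeric(pROC::auc(ra)),
       auroc_b = as.numeric(pROC::auc(rb)),
       difference = as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb)),
       statistic = unname(tst$statistic),
       p_value = tst$p.value)
}

#' DeLong variance of a single AUROC
#'
#' @inheritParams roc_auc
#' @return variance estimate of the AUROC.
#' @export
delong_variance <- function(scores, labels) {
  pROC::var(make_roc(scores, labels), method = "delong")
}

#' Calibration curve
#'
#' Bins predicted probabilities into `n_bins` equal-width bins on `[0, 1]`
#' and reports, per occupied bin, the mean prediction and the observed
#' event rate. Empty bins are omitted.
#'
#' @inheritParams roc_auc
#' @param n_bins number of bins (>= 2).
#' @return data frame `bin`, `n`, `mean_predicted`, `observed_rate`.
#' @export
calibration_curve <- function(scores, labels, n_bins = 10L) {
  stopifnot(n_bins >= 2L)
  bin <- pmin(pmax(ceiling(scores * n_bins), 1L), n_bins)
  occupied <- sort(unique(bin))
  data.frame(
    bin = occupied,
    n = vapply(occupied, function(b) sum(bin == b), integer(1)),
    mean_predicted = vapply(occupied, function(b) mean(scores[bin == b]),
                            numeric(1)),
    observed_rate = vapply(occupied, function(b) mean(labels[bin == b]),
                           numeric(1)))
}

#' Youden-J-optimal threshold from a ROC curve
#'
#' The threshold maximizing sensitivity + specificity - 1; intended to be
#' estimated on the training scores and then applied to the test set.
#'
#' @inheritParams roc_auc
#' @return threshold value.
#' @export
youden_threshold <- function(scores, labels) {
  r <- make_roc(scores, labels)
  co <- pROC::coords(r, "best", best.method = "youden", transpose = FALSE)
  co$threshold[1]
}

#' Ranked gain-importance report for a boosted-tree model
#'
#' @param fit an `alt_model` of kind `"gbt"`.
#' @param top_k number of features to keep (default 50); when larger than
#'   the number of used features the full list is returned.
#' @return data frame `feature`, `gain` (descending, normalized to sum to 1
#'   over all used features), `is_product_term`.
#' @export
importance_report <- function(fit, top_k = 50L) {
  stopifnot(inherits(fit, "alt_model"), fit$kind == "gbt")
  imp <- fit$importance[order(-fit$importance$gain), , drop = FALSE]
  imp$is_product_term <- grepl("*", imp$feature, fixed = TRUE)
  head(imp, top_k)
}

#' Cohort characteristics table with group comparisons
#'
#' Compares cases and controls on the feature-matrix characteristics:
#' Welch's unpaired two-tailed t-test for age, Wilcoxon rank-sum for the
#' concomitant-drug count, and the chi-squared test for the categorical
#' rows (sex, hospital, medical history). Two-sided p-values; the 5%
#' significance convention is left to the reader.
#'
#' @param features output of [assemble_feature_matrix()].
#' @return data frame with one row per characteristic: descriptive
#'   statistics per group (`mean (sd)`, `median (IQR)` or `n (%)`), the
#'   test used and its p-value.
#' @export
cohort_summary <- function(features) {
  x <- features$x
  case <- features$outcome == 1
  fmt_mean <- function(v) sprintf("%.1f (%.1f)", mean(v), stats::sd(v))
  fmt_med <- function(v) sprintf("%.1f (%.1f-%.1f)", stats::median(v),
                                 stats::quantile(v, 0.25),
                                 stats::quantile(v, 0.75))
  fmt_n <- function(v) sprintf("%d (%.1f)", sum(v == 1),
                               100 * mean(v == 1))
  safe_chisq <- function(v) {
    tab <- table(factor(v, levels = c(0, 1)), case)
    tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
             error = function(e) NA_real_)
  }
  rows <- list(
    data.frame(characteristic = "Age (years), mean (SD)",
               cases = fmt_mean(x[case, "age"]),
               controls = fmt_mean(x[!case, "age"]),
               test = "Welch t",
               p_value = stats::t.test(x[case, "age"],
                                       x[!case, "age"])$p.value),
    data.frame(characteristic = "Male, n (%)",
               cases = fmt_n(x[case, "sex_male"]),
               controls = fmt_n(x[!case, "sex_male"]),
               test = "chi-squared",
               p_value = safe_chisq(x[, "sex_male"])),
    data.frame(characteristic = "Concomitant drugs, median (IQR)",
               cases = fmt_med(x[case, "n_concomitant"]),
               controls = fmt_med(x[!case, "n_concomitant"]),
               test = "Wilcoxon rank-sum",
               p_value = suppressWarnings(
                 stats::wilcox.test(x[case, "n_concomitant"],
                                    x[!case, "n_concomitant"])$p.value)))
  cat_cols <- grep("^(hospital_|hist_)", colnames(x), value = TRUE)
  for (cc in cat_cols) {
    rows[[length(rows) + 1L]] <- data.frame(
      characteristic = paste0(sub("^(hospital|hist)_", "", cc), ", n (%)"),
      cases = fmt_n(x[case, cc]), controls = fmt_n(x[!case, cc]),
      test = "chi-squared", p_value = safe_chisq(x[, cc]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
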