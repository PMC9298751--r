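#' Bootstrap specification for coefficient confidence intervals
#'
#' Percentile bootstrap over training-set resamples: `n_replicates`
#' with-replacement resamples, each of the same size as the training set,
#' are refit and each coefficient's 95% interval is read off order
#' statistics of the sorted replicate estimates. At the canonical 2,000
#' replicates the interval runs from the 50th to the 1,950th sorted value;
#' for other replicate counts the ranks generalize to
#' `max(1, floor(0.025 B))` and `min(B, ceiling(0.975 B))`.
#'
#' @param n_replicates number of bootstrap replicates (default 2000).
#' @param lower_rank,upper_rank 1-based ranks into the ascending-sorted
#'   replicate estimates; defaults derive from `n_replicates` as above.
#' @param refit_lambda for LASSO refits: `"fixed"` reuses the lambda
#'   selected on the original training set in every replicate (default);
#'   `"cv"` re-runs the cross-validation inside each replicate.
#' @param seed integer seed for the resampling.
#' @return object of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(n_replicates = 2000L, lower_rank = NULL,
                           upper_rank = NULL,
                           refit_lambda = c("fixed", "cv"), seed = 1L) {
  n_replicates <- as.integer(n_replicates)
  if (is.null(lower_rank)) lower_rank <- max(1L, floor(0.025 * n_replicates))
  if (is.null(upper_rank))
    upper_rank <- min(n_replicates, ceiling(0.975 * n_replicates))
  stopifnot(1L <= lower_rank, lower_rank < upper_rank,
            upper_rank <= n_replicates)
  structure(list(n_replicates = n_replicates,
                 lower_rank = as.integer(lower_rank),
                 upper_rank = as.integer(upper_rank),
                 refit_lambda = match.arg(refit_lambda),
                 seed = as.integer(seed)),
            class = "bootstrap_spec")
}

#' Relative excess risk due to interaction
#'
#' Additive-scale interaction of two binary exposures in a logistic model:
#' \deqn{RERI = e^{\beta_1+\beta_2+\beta_3} - e^{\beta_1} - e^{\beta_2} + 1}
#' where \eqn{\beta_1}, \eqn{\beta_2} are the log-odds main effects and
#' \eqn{\beta_3} the product-term coefficient. RERI = 0 means the combined
#' odds-ratio excess equals the sum of the individual excesses (exact
#' additivity); RERI > 0 means super-additive (synergistic) risk.
#'
#' @param beta1,beta2,beta3 log-odds coefficients (vectorized).
#' @return RERI (dimensionless).
#' @export
compute_reri <- function(beta1, beta2, beta3) {
  if (!all(is.finite(beta1), is.finite(beta2), is.finite(beta3)))
    stop("RERI requires finite coefficients", call. = FALSE)
  exp(beta1 + beta2 + beta3) - exp(beta1) - exp(beta2) + 1
}

#' Combined odds ratio of co-exposure
#'
#' \eqn{e^{\beta_1+\beta_2+\beta_3}}: the adjusted odds ratio of using both
#' drugs versus neither, i.e. the product of the two individual aORs and
#' the product-term aOR.
#'
#' @inheritParams compute_reri
#' @return combined odds ratio.
#' @export
combined_or <- function(beta1, beta2, beta3) {
  if (!all(is.finite(beta1), is.finite(beta2), is.finite(beta3)))
    stop("combined OR requires finite coefficients", call. = FALSE)
  exp(beta1 + beta2 + beta3)
}

#' Percentile confidence interval by the rank rule
#'
#' Sorts the replicate estimates ascending and returns the values at the
#' specification's lower and upper 1-based ranks (50 and 1,950 for 2,000
#' replicates). Ties are handled positionally: ranks index sorted
#' positions, not distinct values.
#'
#' @param estimates numeric vector of replicate estimates; its length must
#'   equal `spec$n_replicates`.
#' @param spec a [bootstrap_spec()].
#' @return numeric `c(lower, upper)`.
#' @export
percentile_ci <- function(estimates,
                          spec = bootstrap_spec(length(estimates))) {
  if (length(estimates) != spec$n_replicates)
    stop("expected ", spec$n_replicates, " estimates, got ",
         length(estimates), call. = FALSE)
  s <- sort(estimates, method = "radix")
  c(lower = s[spec$lower_rank], upper = s[spec$upper_rank])
}

#' Bootstrap the model coefficients
#'
#' Draws `spec$n_replicates` with-replacement resamples of the training
#' rows (each of full training size), refits the supplied procedure on
#' each, and collects the coefficient vectors. A resample containing a
#' single outcome class cannot be fit and is redrawn (the number of
#' redraws is recorded), keeping the replicate count exact.
#'
#' @param x training feature matrix.
#' @param outcome 0/1 training outcome.
#' @param fitter either an `alt_model` from [fit_mlr()] / [fit_lasso_cv()]
#'   (refit with its own settings; for a LASSO model the original lambda is
#'   reused or re-cross-validated per `spec$refit_lambda`), or a function
#'   `function(x, outcome)` returning a named coefficient vector with the
#'   intercept first. The default refits an unpenalized logistic model via
#'   the package's IRLS routine.
#' @param spec a [bootstrap_spec()].
#' @return matrix of `n_replicates` rows by `ncol(x) + 1` coefficient
#'   columns (`"(Intercept)"` first), with attribute `"n_redrawn"`.
#' @export
bootstrap_coefficients <- function(x, outcome, fitter = NULL,
                                   spec = bootstrap_spec()) {
  n <- nrow(x)
  stopifnot(n == length(outcome))
  fit_fun <- bootstrap_fitter(fitter, spec)
  set.seed(spec$seed)
  out <- matrix(NA_real_, nrow = spec$n_replicates, ncol = ncol(x) + 1L,
                dimnames = list(NULL, c("(Intercept)", colnames(x))))
  n_redrawn <- 0L
  for (b in seq_len(spec$n_replicates)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(outcome[idx])) > 1L) break
      n_redrawn <- n_redrawn + 1L
    }
    out[b, ] <- fit_fun(x[idx, , drop = FALSE], outcome[idx])
  }
  if (n_redrawn > 0L)
    message(n_redrawn, " degenerate resample(s) redrawn")
  attr(out, "n_redrawn") <- n_redrawn
  out
}

bootstrap_fitter <- function(fitter, spec) {
  if (is.null(fitter)) return(function(x, y) fit_logistic_irls(x, y))
  if (is.function(fitter)) return(fitter)
  stopifnot(inherits(fitter, "alt_model"))
  if (fitter$kind == "lasso") {
    if (spec$refit_lambda == "fixed") {
      lam <- fitter$lambda
      function(x, y) {
        fit <- glmnet::glmnet(x, y, family = "binomial", lambda = lam)
        beta <- as.numeric(stats::coef(fit))
        names(beta) <- c("(Intercept)", colnames(x))
        beta
      }
    } else {
      function(x, y) fit_lasso_cv(x, y, seed = sample.int(2^30, 1))$coefficients
    }
  } else if (fitter$kind == "mlr") {
    function(x, y) fit_logistic_irls(x, y)
  } else {
    stop("cannot bootstrap a model of kind '", fitter$kind, "'",
         call. = FALSE)
  }
}

#' Dual-criterion synergy call
#'
#' A drug pair is called synergistic when the lower limit of the
#' product-term aOR bootstrap interval exceeds 1 *and* the lower limit of
#' the RERI bootstrap interval exceeds 0.
#'
#' @param aor12_ci_lower lower 95% bootstrap limit of the product-term aOR.
#' @param reri_ci_lower lower 95% bootstrap limit of RERI.
#' @return logical (vectorized).
#' @export
classify_synergy <- function(aor12_ci_lower, reri_ci_lower) {
  aor12_ci_lower > 1 & reri_ci_lower > 0
}

#' Screen every product-term pair for additive-scale synergy
#'
#' For each product-term feature in the catalog, reads the point
#' coefficients of the two parent drugs and the product term off the fitted
#' model, computes the three aORs, the combined aOR and RERI, attaches 95%
#' bootstrap percentile intervals (aOR intervals are the exponentiated
#' percentile intervals of the coefficients, equivalent to percentile
#' intervals of the aORs by monotonicity; RERI intervals come from
#' replicate-wise RERI), and applies the dual-criterion synergy call.
#'
#' @param fit an `alt_model` with linear coefficients.
#' @param boot replicate coefficient matrix from
#'   [bootstrap_coefficients()].
#' @param catalog feature catalog containing `kind == "product"` rows with
#'   `parent1`, `parent2`.
#' @param spec the [bootstrap_spec()] used for `boot`.
#' @return data frame, one row per product term, ranked by decreasing RERI:
#'   parents, `aor1`, `aor2`, `aor12`, `combined_aor`, `reri`, their CI
#'   limits, and `synergy`.
#' @export
screen_all_pairs <- function(fit, boot, catalog,
                             spec = bootstrap_spec(nrow(boot))) {
  prods <- catalog[catalog$kind == "product", , drop = FALSE]
  beta <- fit$coefficients
  rows <- lapply(seq_len(nrow(prods)), function(k) {
    d1 <- prods$parent1[k]; d2 <- prods$parent2[k]; pt <- prods$name[k]
    b1 <- beta[[d1]]; b2 <- beta[[d2]]; b3 <- beta[[pt]]
    ci1 <- exp(percentile_ci(boot[, d1], spec))
    ci2 <- exp(percentile_ci(boot[, d2], spec))
    ci3 <- exp(percentile_ci(boot[, pt], spec))
    reri_rep <- compute_reri(boot[, d1], boot[, d2], boot[, pt])
    ci_reri <- percentile_ci(reri_rep, spec)
    data.frame(
      product_term = pt, drug1 = d1, drug2 = d2,
      aor1 = exp(b1), aor1_low = ci1[1], aor1_high = ci1[2],
      aor2 = exp(b2), aor2_low = ci2[1], aor2_high = ci2[2],
      aor12 = exp(b3), aor12_low = ci3[1], aor12_high = ci3[2],
      combined_aor = combined_or(b1, b2, b3),
      reri = compute_reri(b1, b2, b3),
      reri_low = ci_reri[1], reri_high = ci_reri[2],
      synergy = classify_synergy(ci3[1], ci_reri[1]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$reri), , drop = FALSE]
  rownames(out) <- NULL
  out
}
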