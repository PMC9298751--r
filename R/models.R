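#' Train/test split specification
#'
#' @param train_fraction fraction of rows assigned to the training set
#'   (default 0.70).
#' @param seed integer seed making the split reproducible.
#' @param stratified draw the split within outcome classes so both sets
#'   keep the cohort's class ratio (default `TRUE`; with a roughly 93:7
#'   control:case cohort an unstratified split can wobble the minority
#'   class).
#' @return object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.70, seed = 1L, stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction, seed = as.integer(seed),
                 stratified = isTRUE(stratified)), class = "split_spec")
}

#' Split a feature matrix into training and testing sets
#'
#' @param x feature matrix.
#' @param outcome 0/1 outcome vector, one per row of `x`.
#' @param spec a [split_spec()].
#' @return list with `train` and `test`, each holding `x`, `outcome`, and
#'   the original row indices `idx`. Warns (does not fail) when a split ends
#'   up with a single outcome class.
#' @export
split_data <- function(x, outcome, spec = split_spec()) {
  stopifnot(nrow(x) == length(outcome))
  n <- nrow(x)
  set.seed(spec$seed)
  if (spec$stratified) {
    train_idx <- integer(0)
    for (cl in sort(unique(outcome))) {
      rows <- which(outcome == cl)
      train_idx <- c(train_idx,
                     sample(rows, round(spec$train_fraction * length(rows))))
    }
    train_idx <- sort(train_idx)
  } else {
    train_idx <- sort(sample.int(n, round(spec$train_fraction * n)))
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  for (part in list(train_idx, test_idx)) {
    if (length(unique(outcome[part])) < 2L)
      warning("a split contains a single outcome class", call. = FALSE)
  }
  list(train = list(x = x[train_idx, , drop = FALSE],
                    outcome = outcome[train_idx], idx = train_idx),
       test = list(x = x[test_idx, , drop = FALSE],
                   outcome = outcome[test_idx], idx = test_idx))
}

new_fitted_model <- function(kind, coefficients = NULL, ...) {
  structure(c(list(kind = kind, coefficients = coefficients), list(...)),
            class = "alt_model")
}

#' @export
print.alt_model <- function(x, ...) {
  cat("<alt_model>", x$kind)
  if (!is.null(x$lambda)) cat(sprintf("  lambda = %.5g", x$lambda))
  if (!is.null(x$converged)) cat("  converged:", x$converged)
  cat("\n")
  if (!is.null(x$coefficients))
    cat("  ", sum(x$coefficients[-1] != 0), "of",
        length(x$coefficients) - 1L, "slopes nonzero\n")
  invisible(x)
}

#' Multiple logistic regression
#'
#' Unpenalized maximum-likelihood logistic regression via `stats::glm.fit`
#' with a bounded iteration count. On wide, collinear feature sets (many
#' product terms) the solution can be ill-conditioned; the fit then reports
#' `converged = FALSE` and possibly very large coefficients instead of
#' raising, mirroring the over-fitting failure mode this model is known for
#' on such data.
#'
#' @param x feature matrix (no intercept column).
#' @param outcome 0/1 vector.
#' @param maxit IRLS iteration cap.
#' @return an `alt_model` with named `coefficients` (intercept first) on the
#'   log-odds scale and a `converged` flag.
#' @export
fit_mlr <- function(x, outcome, maxit = 25L) {
  xm <- cbind("(Intercept)" = 1, x)
  fit <- suppressWarnings(
    stats::glm.fit(xm, outcome, family = stats::binomial(),
                   control = stats::glm.control(maxit = maxit)))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0  # aliased columns dropped by glm.fit
  if (!fit$converged)
    warning("MLR did not converge within ", maxit,
            " iterations (ill-conditioned design?)", call. = FALSE)
  new_fitted_model("mlr", beta, converged = fit$converged)
}

# fast unpenalized logistic fit used in bootstrap resampling loops
fit_logistic_irls <- function(x, outcome, maxit = 30L, tol = 1e-8) {
  xm <- cbind(1, x)
  beta <- drop(irls_logistic_cpp(xm, as.numeric(outcome),
                                 maxit = maxit, tol = tol))
  names(beta) <- c("(Intercept)", colnames(x))
  beta
}

#' L1-penalized logistic regression with cross-validated lambda
#'
#' Runs `glmnet::cv.glmnet` (binomial family) with the misclassification
#' error rate as the cross-validation criterion, selects the lambda
#' minimizing it, and keeps the coefficients of the path model refit on the
#' full training set at that lambda. The candidate grid is glmnet's
#' standard path: 100 log-spaced values descending four decades from the
#' smallest lambda that zeroes every slope.
#'
#' @param x feature matrix.
#' @param outcome 0/1 vector.
#' @param n_folds number of cross-validation folds (default 10).
#' @param seed seed controlling fold assignment.
#' @return an `alt_model` with exact-zero-preserving `coefficients`,
#'   the selected `lambda`, the `lambda_grid` with CV `cv_error`, and the
#'   underlying `cv_fit`.
#' @export
fit_lasso_cv <- function(x, outcome, n_folds = 10L, seed = 1L) {
  stopifnot(min(table(outcome)) >= n_folds)
  set.seed(seed)
  cv <- glmnet::cv.glmnet(x, outcome, family = "binomial",
                          type.measure = "class", nfolds = n_folds)
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
  names(beta) <- c("(Intercept)", colnames(x))
  if (all(beta[-1] == 0))
    warning("all slopes shrunk to zero; intercept-only model", call. = FALSE)
  new_fitted_model("lasso", beta, lambda = cv$lambda.min,
                   lambda_grid = cv$lambda, cv_error = cv$cvm, cv_fit = cv)
}

#' Gradient-boosted trees with grid-searched booster parameters
#'
#' Fits an xgboost binary-logistic model. Booster parameters are chosen by
#' grid search: each candidate is trained on a stratified 80% inner split
#' of the training data and scored by AUROC on the held-out 20%; the winner
#' is refit on the full training set. Gain importances are normalized to
#' sum to 1 over the features the trees actually use.
#'
#' @param x feature matrix.
#' @param outcome 0/1 vector.
#' @param grid data frame of candidate booster parameters with columns
#'   `eta`, `max_depth`, `subsample`; default is a small grid
#'   `{0.1, 0.3} x {3, 6} x {0.8, 1.0}`.
#' @param nrounds boosting rounds.
#' @param seed seed for the inner split and xgboost RNG.
#' @return an `alt_model` with the fitted `booster`, the winning
#'   `params`, the full `grid` with validation AUROC, and `importance`
#'   (data frame `feature`, `gain`).
#' @export
fit_gbt <- function(x, outcome,
                    grid = expand.grid(eta = c(0.1, 0.3),
                                       max_depth = c(3L, 6L),
                                       subsample = c(0.8, 1.0)),
                    nrounds = 60L, seed = 1L) {
  stopifnot(nrow(grid) >= 1L)
  set.seed(seed)
  inner <- split_data(x, outcome, split_spec(0.8, seed = seed))
  dtr <- xgboost::xgb.DMatrix(inner$train$x, label = inner$train$outcome)
  dva_x <- inner$test$x
  grid$val_auroc <- NA_real_
  for (g in seq_len(nrow(grid))) {
    params <- list(objective = "binary:logistic",
                   eta = grid$eta[g], max_depth = grid$max_depth[g],
                   subsample = grid$subsample[g], nthread = 1L,
                   seed = seed)
    bst <- xgboost::xgb.train(params, dtr, nrounds = nrounds, verbose = 0)
    pred <- stats::predict(bst, xgboost::xgb.DMatrix(dva_x))
    grid$val_auroc[g] <- roc_auc(pred, inner$test$outcome, ci = FALSE)$auroc
  }
  best <- which.max(grid$val_auroc)
  params <- list(objective = "binary:logistic",
                 eta = grid$eta[best], max_depth = grid$max_depth[best],
                 subsample = grid$subsample[best], nthread = 1L, seed = seed)
  dall <- xgboost::xgb.DMatrix(x, label = outcome)
  booster <- xgboost::xgb.train(params, dall, nrounds = nrounds, verbose = 0)
  imp <- tryCatch(xgboost::xgb.importance(model = booster),
                  error = function(e) NULL)
  importance <- if (is.null(imp) || nrow(imp) == 0L) {
    data.frame(feature = character(), gain = numeric(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(feature = imp$Feature, gain = imp$Gain / sum(imp$Gain),
               stringsAsFactors = FALSE)
  }
  new_fitted_model("gbt", NULL, booster = booster, params = params,
                   grid = grid, importance = importance)
}

#' Predict event probabilities from a fitted model
#'
#' @param object an `alt_model`.
#' @param newx feature matrix with the training columns.
#' @param ... unused.
#' @return vector of probabilities in `[0, 1]`.
#' @export
predict.alt_model <- function(object, newx, ...) {
  if (object$kind %in% c("mlr", "lasso")) {
    beta <- object$coefficients
    stopifnot(!is.null(colnames(newx)))
    eta <- drop(cbind(1, newx[, names(beta)[-1], drop = FALSE]) %*% beta)
    stats::plogis(eta)
  } else {
    stats::predict(object$booster, xgboost::xgb.DMatrix(newx))
  }
}
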