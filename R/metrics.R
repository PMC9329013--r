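#' Regression and classification performance report
#'
#' Computes the measures used to compare the two models: mean absolute
#' error `mean(|e|)`, mean squared error and its root, the coefficient of
#' determination `R2 = 1 - SS_res / SS_tot`, and — because regression
#' software often reports the correlation between predictions and targets
#' instead — the squared Pearson correlation, which equals the coefficient
#' of determination only when the predictions are affinely calibrated to
#' the targets. When the true outcomes are binary, the continuous scores
#' are additionally thresholded into labels and confusion counts and
#' accuracy are reported.
#'
#' @param y_true Numeric vector of observed outcomes.
#' @param y_pred Numeric vector of predicted scores, same length.
#' @param threshold Decision threshold for the label metrics.
#' @return An `eval_report` list: `n`, `mae`, `mse`, `rmse`,
#'   `r2_determination`, `r2_pearson`, `threshold`, and, for binary
#'   `y_true`, `tp`, `fp`, `tn`, `fn`, `accuracy`.
#' @export
#' @examples
#' evaluate_predictions(c(0, 1, 1, 0), c(0.2, 0.8, 0.6, 0.4))
evaluate_predictions <- function(y_true, y_pred, threshold = 0.5) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  n <- length(y_true)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  e <- y_pred - y_true
  mse <- mean(e^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot > 0) {
    r2_det <- 1 - sum(e^2) / ss_tot
    r2_pear <- suppressWarnings(stats::cor(y_true, y_pred))^2
    if (is.na(r2_pear)) r2_pear <- NA_real_  # constant predictions
  } else {
    r2_det <- NA_real_
    r2_pear <- NA_real_
  }

  rep <- list(n = n, mae = mean(abs(e)), mse = mse, rmse = sqrt(mse),
              r2_determination = r2_det, r2_pearson = r2_pear,
              threshold = threshold)
  if (all(y_true %in% c(0, 1))) {
    lab <- as.numeric(y_pred > threshold)
    rep$tp <- sum(lab == 1 & y_true == 1)
    rep$fp <- sum(lab == 1 & y_true == 0)
    rep$tn <- sum(lab == 0 & y_true == 0)
    rep$fn <- sum(lab == 0 & y_true == 1)
    rep$accuracy <- (rep$tp + rep$tn) / n
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("n = %d | R2 = %.4f (Pearson r^2 = %.4f) | MAE = %.4f | RMSE = %.4f\n",
              x$n, x$r2_determination, x$r2_pearson, x$mae, x$rmse))
  if (!is.null(x$accuracy)) {
    cat(sprintf("threshold %.2f: accuracy %.4f (tp %d, fp %d, tn %d, fn %d)\n",
                x$threshold, x$accuracy, x$tp, x$fp, x$tn, x$fn))
  }
  invisible(x)
}

#' Flatten an evaluation report to a one-row data frame
#' @param x An `eval_report`.
#' @param row.names,optional,... Passed on per the generic; unused.
#' @return A one-row data frame.
#' @export
as.data.frame.eval_report <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  as.data.frame(unclass(x), row.names = row.names)
}

#' Permutation feature importance
#'
#' Model-agnostic importance: each feature column is shuffled (destroying
#' its association with the outcome while preserving its marginal), the
#' model is re-evaluated, and the importance is the degradation of the
#' chosen metric relative to the intact data, averaged over repeats.
#' For error metrics (`mae`, `rmse`) degradation is the increase; for
#' `r2_determination` it is the decrease, so larger is always "more
#' important".
#'
#' @param object A fitted model with a `predict` method (`cascade_model`,
#'   `ann_weights`) or a function mapping a feature matrix to scores.
#' @param data A normalized `heart_dataset` including the outcome.
#' @param metric One of `"mae"`, `"rmse"`, `"r2_determination"`.
#' @param repeats Number of shuffles averaged per feature.
#' @param seed RNG seed; the same seed reproduces the scores exactly.
#' @return A data frame with columns `feature` and `importance`, in schema
#'   order.
#' @export
permutation_importance <- function(object, data, metric = "rmse",
                                   repeats = 5, seed = 1) {
  stopifnot(inherits(data, "heart_dataset"))
  if (!(metric %in% c("mae", "rmse", "r2_determination"))) {
    stop("unknown metric '", metric,
         "': use mae, rmse or r2_determination", call. = FALSE)
  }
  if (!(HEART_OUTCOME %in% names(data))) {
    stop("outcome column required", call. = FALSE)
  }
  predict_fun <- if (is.function(object)) {
    object
  } else {
    function(X) stats::predict(object, X)
  }
  X <- feature_matrix(data)
  y <- as.data.frame(data)[[HEART_OUTCOME]]
  score <- function(Xm) {
    rep <- evaluate_predictions(y, predict_fun(Xm))
    rep[[metric]]
  }
  base <- score(X)
  set.seed(seed)
  imp <- vapply(seq_along(HEART_FEATURES), function(j) {
    mean(vapply(seq_len(repeats), function(r) {
      Xp <- X
      Xp[, j] <- X[sample.int(nrow(X)), j]
      if (metric == "r2_determination") base - score(Xp) else score(Xp) - base
    }, 0))
  }, 0)
  data.frame(feature = HEART_FEATURES, importance = imp,
             stringsAsFactors = FALSE)
}
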