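#' Univariate least-squares fit
#'
#' Closed-form ordinary least squares of a target on a single feature:
#' `slope = cov(x, t) / var(x)`, `intercept = mean(t) - slope * mean(x)`.
#' This two-parameter fit is the building block of every cascade stage; it
#' is computed from the normal equations directly, with no iterative
#' optimizer, so stage coefficients are exact and reproducible.
#'
#' @param x Numeric vector of (normalized) feature values.
#' @param t Numeric vector of targets, same length as `x`.
#' @return Named numeric vector `c(slope, intercept)`.
#' @export
#' @examples
#' fit_univariate(c(0, 1), c(0, 1))  # slope 1, intercept 0
fit_univariate <- function(x, t) {
  if (length(x) != length(t)) stop("x and t must have equal length",
                                   call. = FALSE)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  mx <- mean(x)
  vx <- mean((x - mx)^2)  # population moments; the n divisors cancel
  if (vx <= 0) stop("zero-variance x: degenerate univariate fit",
                    call. = FALSE)
  slope <- mean((x - mx) * (t - mean(t))) / vx
  c(slope = slope, intercept = mean(t) - slope * mx)
}

#' Fit the residual curve-fitting cascade
#'
#' Fits the outcome one feature at a time, in schema order (`Ac` first,
#' `Th` last). Stage 1 regresses `Hd` on `Ac`; the per-sample residual
#' constant `r <- r - slope * x` (the target minus the explained part) is
#' carried forward as the next stage's target, so stage k's coefficient is
#' the univariate slope of the running residual on feature k. The final
#' stage's intercept becomes the model constant `M0`, yielding the additive
#' closed-form correlation
#' `Hd = M0 + sum_k slope_k * x_k`.
#'
#' With empirically uncorrelated feature columns this recovers the joint
#' least-squares solution exactly; with correlated columns the stagewise
#' coefficients generally differ from joint OLS (each stage sees only the
#' residual left by earlier features).
#'
#' @param data A normalized `heart_dataset` containing the outcome `Hd`.
#' @return A `cascade_model`: list with `stages` (data frame: `feature`,
#'   `slope`, `intercept`, `r2` — the squared correlation between the
#'   running residual and the stage feature) and `final_intercept` (`M0`).
#' @seealso [published_cascade()], [predict.cascade_model()]
#' @export
fit_cascade <- function(data) {
  stopifnot(inherits(data, "heart_dataset"))
  if (!is_normalized(data)) {
    stop("cascade is fit on normalized data; call normalize_heart() first",
         call. = FALSE)
  }
  if (!(HEART_OUTCOME %in% names(data))) {
    stop("outcome column '", HEART_OUTCOME, "' required to fit", call. = FALSE)
  }
  X <- feature_matrix(data)
  r <- as.data.frame(data)[[HEART_OUTCOME]]

  k <- length(HEART_FEATURES)
  slopes <- intercepts <- r2 <- numeric(k)
  for (i in seq_len(k)) {
    x <- X[, i]
    fit <- tryCatch(
      fit_univariate(x, r),
      error = function(e) stop("stage ", i, " (", HEART_FEATURES[i], "): ",
                               conditionMessage(e), call. = FALSE)
    )
    slopes[i] <- fit[["slope"]]
    intercepts[i] <- fit[["intercept"]]
    r2[i] <- if (stats::var(r) > 0) stats::cor(x, r)^2 else 0
    # carry the per-sample residual constant forward as the next target
    r <- r - slopes[i] * x
  }

  new_cascade_model(
    stages = data.frame(feature = HEART_FEATURES, slope = slopes,
                        intercept = intercepts, r2 = r2,
                        stringsAsFactors = FALSE),
    final_intercept = intercepts[k]
  )
}

#' @keywords internal
#' @noRd
new_cascade_model <- function(stages, final_intercept) {
  stopifnot(is.data.frame(stages),
            identical(stages$feature, HEART_FEATURES),
            all(is.finite(stages$slope)), all(is.finite(stages$intercept)),
            is.finite(final_intercept))
  structure(list(stages = stages, final_intercept = final_intercept),
            class = "cascade_model")
}

#' The published curve-fitting cascade model
#'
#' The frozen stagewise model as printed: 13 stage slopes
#' (-0.0123 for `Ac` through -0.2223 for `Th`), each stage's intercept
#' (the running constants 1.2152, 0.7647, ..., 0.6861), and the final
#' model constant `M0 = 0.6861`. Evaluating it gives the closed-form
#' correlation
#' `Hd = 0.6861 - 0.0123 Ac - 0.3069 Sc + 0.606 Cp - 0.544 Bp - 0.3923 Ch
#'  - 0.0336 Fb + 0.1179 Re + 0.7868 Hr - 0.1128 Ex - 0.4702 Op
#'  + 0.0258 Sp - 0.2628 Ca - 0.2223 Th`
#' on min-max normalized inputs.
#'
#' @return A `cascade_model`.
#' @export
#' @examples
#' m <- published_cascade()
#' predict(m, rep(0, 13))  # the model constant M0 = 0.6861
published_cascade <- function() {
  slopes <- c(-0.0123, -0.3069, 0.606, -0.544, -0.3923, -0.0336, 0.1179,
              0.7868, -0.1128, -0.4702, 0.0258, -0.2628, -0.2223)
  intercepts <- c(1.2152, 0.7647, 0.5688, 0.7619, 0.87, 0.875, 0.8439,
                  0.3717, 0.408, 0.4871, 0.469, 0.5168, 0.6861)
  new_cascade_model(
    stages = data.frame(feature = HEART_FEATURES, slope = slopes,
                        intercept = intercepts, r2 = NA_real_,
                        stringsAsFactors = FALSE),
    final_intercept = 0.6861
  )
}

#' Predict heart-disease scores from a cascade model
#'
#' Evaluates the closed-form correlation
#' `Hd = M0 + sum_k slope_k * x_k` on normalized inputs. The continuous
#' score approximates the binary outcome; `type = "label"` thresholds it
#' (default 0.5) into a 0/1 diagnosis.
#'
#' @param object A `cascade_model`.
#' @param newdata A normalized `heart_dataset`, a numeric matrix with 13
#'   columns in schema order, or a single 13-vector.
#' @param type `"score"` (continuous) or `"label"` (thresholded 0/1).
#' @param threshold Decision threshold for `type = "label"`.
#' @param ... Unused.
#' @return Numeric vector of scores or 0/1 labels.
#' @export
predict.cascade_model <- function(object, newdata, type = c("score", "label"),
                                  threshold = 0.5, ...) {
  type <- match.arg(type)
  X <- as_feature_input(newdata)
  scores <- drop(X %*% object$stages$slope) + object$final_intercept
  if (type == "label") as.numeric(scores > threshold) else unname(scores)
}

#' @keywords internal
#' @noRd
as_feature_input <- function(newdata) {
  if (inherits(newdata, "heart_dataset") || is.data.frame(newdata)) {
    missing_feats <- setdiff(HEART_FEATURES, names(newdata))
    if (length(missing_feats)) {
      stop("newdata is missing feature(s): ",
           paste(missing_feats, collapse = ", "), call. = FALSE)
    }
    X <- as.matrix(as.data.frame(newdata)[, HEART_FEATURES, drop = FALSE])
  } else if (is.matrix(newdata)) {
    if (ncol(newdata) != length(HEART_FEATURES)) {
      stop("feature matrix must have ", length(HEART_FEATURES), " columns",
           call. = FALSE)
    }
    X <- newdata
  } else if (is.numeric(newdata)) {
    if (length(newdata) != length(HEART_FEATURES)) {
      stop("feature vector must have length ", length(HEART_FEATURES),
           call. = FALSE)
    }
    X <- matrix(newdata, nrow = 1)
  } else {
    stop("unsupported newdata type", call. = FALSE)
  }
  storage.mode(X) <- "double"
  X
}

#' @export
print.cascade_model <- function(x, ...) {
  cat("Residual curve-fitting cascade (13 stages)\n")
  cat("Hd =", format(x$final_intercept), "+ sum_k slope_k * x_k\n\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' @export
coef.cascade_model <- function(object, ...) {
  stats::setNames(c(object$final_intercept, object$stages$slope),
                  c("(Intercept)", HEART_FEATURES))
}

#' Save or load a cascade model as JSON
#'
#' @param model A `cascade_model`.
#' @param path JSON file path.
#' @return `write_cascade()` returns `path` invisibly; `read_cascade()`
#'   returns a `cascade_model`.
#' @export
write_cascade <- function(model, path) {
  stopifnot(inherits(model, "cascade_model"))
  obj <- list(
    stages = lapply(seq_len(nrow(model$stages)), function(i) {
      list(feature = model$stages$feature[i],
           slope = model$stages$slope[i],
           intercept = model$stages$intercept[i])
    }),
    final_intercept = model$final_intercept
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cascade
#' @export
read_cascade <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  stages <- do.call(rbind, lapply(obj$stages, function(s) {
    data.frame(feature = s$feature, slope = s$slope, intercept = s$intercept,
               r2 = NA_real_, stringsAsFactors = FALSE)
  }))
  new_cascade_model(stages = stages, final_intercept = obj$final_intercept)
}
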