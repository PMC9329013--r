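test_that("univariate fit matches trivial cases and the normal-equations oracle", {
  expect_equal(fit_univariate(c(0, 1), c(0, 1)),
               c(slope = 1, intercept = 0))
  # constant target: zero slope, intercept at the constant
  expect_equal(fit_univariate(c(0, 0.4, 1), c(0.7, 0.7, 0.7)),
               c(slope = 0, intercept = 0.7))
  expect_error(fit_univariate(rep(0.5, 10), runif(10)), "zero-variance")
  expect_error(fit_univariate(1:3, 1:4), "equal length")

  set.seed(9)
  for (rep in 1:5) {
    x <- runif(50); t <- runif(50)
    expect_equal(fit_univariate(x, t), normal_eq_fit(x, t), tolerance = 1e-10)
  }
})

test_that("noise-free recovery on orthogonal designs matches truth and joint OLS", {
  X <- make_orthogonal_features(150, seed = 4)
  truth <- c(-0.5, 1.2, 0.3, -0.1, 0.8, 0, 0.05, 2, -0.7, 0.4, -1.5, 0.9, 0.2)
  c0 <- 0.37
  ds <- regression_ds(X, c0 + as.matrix(X) %*% truth)
  model <- fit_cascade(ds)
  expect_lt(max(abs(model$stages$slope - truth)), 1e-8)
  expect_lt(abs(model$final_intercept - c0), 1e-8)
  # independent route: joint multivariate least squares
  joint <- lm(Hd ~ ., data = as.data.frame(ds))
  expect_lt(max(abs(coef(joint)[-1] - model$stages$slope)), 1e-8)
  # refitting the cascade on its own predictions reproduces it
  refit <- fit_cascade(regression_ds(X, predict(model, ds)))
  expect_lt(max(abs(refit$stages$slope - model$stages$slope)), 1e-10)
})

test_that("every stage slope equals the brute-force cov/var of the running residual", {
  set.seed(12)
  sim <- generate_heart_data(table2_default_spec(n = 120, seed = 12))
  params <- fit_normalization(sim$data)
  norm <- normalize_heart(sim$data, params)
  model <- fit_cascade(norm)

  X <- as.matrix(as.data.frame(norm)[, FEATS])
  r <- as.data.frame(norm)$Hd
  for (k in seq_along(FEATS)) {
    x <- X[, k]
    slope_oracle <- sum((x - mean(x)) * (r - mean(r))) /
      sum((x - mean(x))^2)
    expect_lt(abs(model$stages$slope[k] - slope_oracle), 1e-10)
    # stage intercept bookkeeping
    expect_lt(abs(model$stages$intercept[k] -
                    (mean(r) - model$stages$slope[k] * mean(x))), 1e-10)
    r <- r - model$stages$slope[k] * x
  }
  # final intercept is the last stage's intercept
  expect_identical(model$final_intercept,
                   model$stages$intercept[length(FEATS)])
})

test_that("correlated features bias the stagewise slopes but not joint OLS", {
  Q <- make_orthogonal_features(200, seed = 8)
  X <- as.matrix(Q)
  # make the first two columns positively correlated
  mix <- 0.7 * X[, 1] + 0.3 * X[, 2]
  X[, 2] <- (mix - min(mix)) / (max(mix) - min(mix))
  expect_gt(cor(X[, 1], X[, 2]), 0.5)
  y <- 1 * X[, 1] + 1 * X[, 2]
  ds <- regression_ds(X, y)
  model <- fit_cascade(ds)
  # the first stage absorbs part of the correlated partner's effect
  expect_gt(model$stages$slope[1], 1.1)
  joint <- lm(Hd ~ ., data = as.data.frame(ds))
  expect_lt(max(abs(coef(joint)[2:3] - c(1, 1))), 1e-8)
})

test_that("the published model evaluates the closed-form correlation", {
  model <- published_cascade()
  expect_identical(model$stages$slope[1], -0.0123)
  expect_identical(model$stages$slope[3], 0.606)
  expect_identical(model$final_intercept, 0.6861)
  # all-zero input returns the model constant exactly
  expect_identical(predict(model, rep(0, 13)), 0.6861)
  # all-ones input: constant plus the sum of the 13 slopes
  expect_equal(predict(model, rep(1, 13)), -0.1346, tolerance = 1e-12)
  # linearity in the input
  x <- runif(13); y <- runif(13); a <- 0.3
  lhs <- predict(model, a * x + (1 - a) * y)
  rhs <- a * predict(model, x) + (1 - a) * predict(model, y)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(predict(model, rep(0, 12)), "length 13")
})

test_that("any fitted model at the all-zero input returns its final intercept", {
  X <- make_orthogonal_features(60, seed = 14)
  ds <- regression_ds(X, 0.2 + as.matrix(X) %*% runif(13, -1, 1))
  model <- fit_cascade(ds)
  expect_identical(predict(model, rep(0, 13)), model$final_intercept)
})

test_that("cascade models survive the JSON round trip", {
  model <- published_cascade()
  f <- tempfile(fileext = ".json")
  write_cascade(model, f)
  back <- read_cascade(f)
  expect_equal(back$stages$slope, model$stages$slope)
  expect_equal(back$stages$intercept, model$stages$intercept)
  expect_identical(back$final_intercept, model$final_intercept)
})

test_that("degenerate features and unnormalized data are refused", {
  X <- make_orthogonal_features(40, seed = 2)
  X$Fb <- 0.5  # constant
  ds <- regression_ds(as.matrix(X), runif(40))
  expect_error(fit_cascade(ds), "stage 6 \\(Fb\\)")

  raw <- heart_dataset(tiny_raw_df())
  expect_error(fit_cascade(raw), "normalized")
})
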