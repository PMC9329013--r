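test_that("tansig equals tanh, is odd, stays in (-1, 1) and never overflows", {
  expect_identical(tansig(0), 0)
  for (x in c(-3, -0.5, 0.7, 4)) {
    expect_equal(tansig(x), tanh(x), tolerance = 1e-12)
  }
  set.seed(5)
  x <- runif(200, -6, 6)
  expect_equal(tansig(x), tanh(x), tolerance = 1e-12)
  expect_equal(tansig(-x), -tansig(x), tolerance = 1e-15)
  expect_true(all(abs(tansig(x)) < 1))
  # extreme inputs saturate instead of overflowing
  expect_identical(tansig(c(-1e4, 1e4)), c(-1, 1))
  expect_identical(purelin(3.7), 3.7)
  expect_identical(purelin(x), x)
})

test_that("forward pass matches the loop-based oracle and handles edge shapes", {
  # zero weights give zero output for any input
  zero <- ann_weights(matrix(0, 3, 13), rep(0, 3), rep(0, 3), 0)
  expect_identical(ann_forward(zero, runif(13)), 0)

  # h = 1 toy network, hand-computable
  toy <- ann_weights(matrix(c(2, rep(0, 12)), 1, 13), 0.5, 3, -1)
  x <- c(0.25, runif(12))
  expect_equal(ann_forward(toy, x), 3 * tanh(2 * 0.25 + 0.5) - 1,
               tolerance = 1e-14)

  # published weights against the independent element-by-element oracle
  w <- published_ann()
  set.seed(31)
  for (i in 1:100) {
    x <- runif(13)
    expect_equal(ann_forward(w, x), loop_forward(w, x), tolerance = 1e-12)
  }
  expect_error(ann_forward(w, rep(0.5, 12)), "length 13")
})

test_that("the published network matches its printed constants", {
  w <- published_ann()
  expect_identical(dim(w$input_weights), c(10L, 13L))
  expect_identical(w$output_bias, 3.38)
  expect_identical(w$output_weights[1], 1.35)
  expect_identical(w$hidden_biases[10], 3.49)
  expect_identical(w$input_weights[1, 1], 0.26)
  expect_identical(w$input_weights[10, 13], -0.39)
  # at the all-zero input only the biases drive the hidden layer;
  # frozen from the loop oracle: a negative score, hence label 0
  at_zero <- loop_forward(w, rep(0, 13))
  expect_equal(ann_forward(w, rep(0, 13)), at_zero, tolerance = 1e-12)
  expect_equal(at_zero, -0.8449133733638963, tolerance = 1e-12)
  expect_identical(predict(w, rep(0, 13), type = "label"), 0)
})

test_that("backprop gradients match central finite differences", {
  set.seed(17)
  w <- ann_weights(matrix(runif(4 * 13, -0.5, 0.5), 4, 13),
                   runif(4, -0.5, 0.5), runif(4, -0.5, 0.5), runif(1))
  X <- matrix(runif(25 * 13), 25, 13)
  y <- runif(25)
  g <- ann_gradients(w, X, y)$gradients
  h <- 1e-6
  loss_at <- function(w2) ann_gradients(w2, X, y)$loss
  rel_err <- function(analytic, bump) {
    wp <- bump(h); wm <- bump(-h)
    numeric <- (loss_at(wp) - loss_at(wm)) / (2 * h)
    abs(analytic - numeric) / max(abs(analytic) + abs(numeric), 1e-10)
  }
  for (i in 1:4) for (j in seq(1, 13, by = 3)) {
    expect_lt(rel_err(g$input_weights[i, j], function(d) {
      w2 <- w; w2$input_weights[i, j] <- w2$input_weights[i, j] + d; w2
    }), 1e-4)
  }
  for (k in 1:4) {
    expect_lt(rel_err(g$hidden_biases[k], function(d) {
      w2 <- w; w2$hidden_biases[k] <- w2$hidden_biases[k] + d; w2
    }), 1e-4)
    expect_lt(rel_err(g$output_weights[k], function(d) {
      w2 <- w; w2$output_weights[k] <- w2$output_weights[k] + d; w2
    }), 1e-4)
  }
  expect_lt(rel_err(g$output_bias, function(d) {
    w2 <- w; w2$output_bias <- w2$output_bias + d; w2
  }), 1e-4)
})

test_that("training learns an XOR-style fixture and beats the constant baseline", {
  ds <- xor_ds(reps = 20)
  config <- train_config(hidden_sizes = 4, max_epochs = 3000,
                         learn_rate = 0.5, patience = 400, seed = 3)
  result <- train_ann(ds, config)
  train_rows <- result$split$train
  mse <- mean((ann_forward(result$best_weights,
                           as.data.frame(ds)[train_rows, FEATS]) -
                 as.data.frame(ds)$Hd[train_rows])^2)
  expect_lt(mse, 0.05)

  # labels from the published network: training must beat the
  # constant-predictor baseline (the label variance)
  set.seed(23)
  X <- matrix(runif(200 * 13), 200, 13)
  y <- as.numeric(ann_forward(published_ann(), X) > 0.5)
  ds2 <- regression_ds(X, y)
  res2 <- train_ann(ds2, train_config(hidden_sizes = 6, max_epochs = 800,
                                      patience = 100, seed = 7))
  tr <- res2$split$train
  mse2 <- mean((ann_forward(res2$best_weights, X[tr, ]) - y[tr])^2)
  expect_lt(mse2, var(y[tr]))
})

test_that("training is deterministic under a fixed seed", {
  ds <- xor_ds(reps = 10)
  config <- train_config(hidden_sizes = c(3, 4), max_epochs = 200,
                         patience = 50, seed = 11)
  r1 <- train_ann(ds, config)
  r2 <- train_ann(ds, config)
  expect_identical(r1$best_weights, r2$best_weights)
  expect_identical(r1$sweep, r2$sweep)
  expect_identical(r1$history, r2$history)
})

test_that("early stopping restores the best-validation weights", {
  set.seed(41)
  X <- matrix(runif(120 * 13), 120, 13)
  y <- drop(X %*% runif(13, -1, 1)) + rnorm(120, 0, 0.2)
  ds <- regression_ds(X, (y - min(y)) / (max(y) - min(y)))
  res <- train_ann(ds, train_config(hidden_sizes = c(3, 5), max_epochs = 400,
                                    patience = 30, seed = 2))
  # winner's validation MSE is the minimum among non-degenerate runs
  expect_equal(res$best_val_mse, min(res$sweep$val_mse[res$sweep$learned]))
  # restored weights reproduce the recorded best validation MSE
  va <- res$split$validation
  mse_restored <- mean((ann_forward(res$best_weights, X[va, ]) -
                          as.data.frame(ds)$Hd[va])^2)
  expect_equal(mse_restored, res$best_val_mse, tolerance = 1e-12)
  # and no recorded epoch beat it
  for (hist in res$history) {
    expect_gte(min(hist$val_mse, na.rm = TRUE), res$best_val_mse - 1e-12)
  }
})

test_that("the sweep report has one row per size with the winner flagged", {
  ds <- xor_ds(reps = 10)
  res <- train_ann(ds, train_config(hidden_sizes = 5:7, max_epochs = 100,
                                    patience = 30, seed = 1))
  tbl <- sweep_report(res)
  expect_equal(nrow(tbl), 3)
  expect_identical(tbl$hidden, 5:7)
  expect_equal(sum(tbl$winner), 1)
  expect_equal(tbl$val_mse[tbl$winner], min(tbl$val_mse[tbl$learned]))
  expect_true(res$best_hidden %in% 5:7)
  # serializes to CSV and round-trips
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tbl, f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_equal(back$val_mse, tbl$val_mse)
})

test_that("network weights survive the JSON round trip", {
  w <- published_ann()
  f <- tempfile(fileext = ".json")
  write_ann(w, f)
  back <- read_ann(f)
  expect_equal(back$input_weights, w$input_weights)
  expect_equal(back$hidden_biases, w$hidden_biases)
  expect_equal(back$output_weights, w$output_weights)
  expect_identical(back$output_bias, w$output_bias)
})

test_that("configuration invariants are enforced", {
  expect_error(train_config(train = 0.5, validation = 0.3, test = 0.3),
               "sum to 1")
  expect_error(train_config(hidden_sizes = integer(0)), "non-empty")
  expect_error(ann_weights(matrix(0, 2, 12), rep(0, 2), rep(0, 2), 0),
               "13 columns")
  expect_error(ann_weights(matrix(Inf, 2, 13), rep(0, 2), rep(0, 2), 0),
               "non-finite")
  # split too small for 90/5/5
  ds <- xor_ds(reps = 2)
  expect_error(train_ann(ds, train_config(hidden_sizes = 3)), "too small")
})
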