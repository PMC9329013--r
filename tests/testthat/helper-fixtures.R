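# Shared fixtures, all built in code at test time.

FEATS <- c("Ac", "Sc", "Cp", "Bp", "Ch", "Fb", "Re",
           "Hr", "Ex", "Op", "Sp", "Ca", "Th")

# A tiny valid raw-scale clinical table (3 patients).
tiny_raw_df <- function() {
  data.frame(
    Ac = c(45, 60, 33), Sc = c(1, 0, 1), Cp = c(1, 3, 2),
    Bp = c(120, 140, 110), Ch = c(200, 250, 180), Fb = c(0, 1, 0),
    Re = c(0, 2, 1), Hr = c(150, 120, 170), Ex = c(0, 1, 0),
    Op = c(1.0, 2.3, 0.0), Sp = c(1, 2, 0), Ca = c(0, 2, 1),
    Th = c(2, 3, 1), Hd = c(0, 1, 0)
  )
}

write_tiny_csv <- function(df = tiny_raw_df()) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}

# Wrap a normalized design + continuous target into the dataset container.
regression_ds <- function(X, y) {
  df <- as.data.frame(X)
  names(df) <- FEATS
  df$Hd <- as.numeric(y)
  heart_dataset(df, normalized = TRUE, binary_outcome = FALSE)
}

# Independent element-by-element (loop-based) network evaluation used as
# the oracle for the vectorized forward pass.
loop_forward <- function(w, x) {
  h <- nrow(w$input_weights)
  acc <- w$output_bias
  for (k in seq_len(h)) {
    z <- w$hidden_biases[k]
    for (i in seq_along(x)) z <- z + w$input_weights[k, i] * x[i]
    acc <- acc + w$output_weights[k] * tanh(z)
  }
  acc
}

# Brute-force univariate OLS via the 2x2 normal equations.
normal_eq_fit <- function(x, t) {
  n <- length(x)
  A <- matrix(c(n, sum(x), sum(x), sum(x^2)), 2, 2)
  b <- c(sum(t), sum(x * t))
  sol <- solve(A, b)
  c(slope = sol[2], intercept = sol[1])
}

# An XOR-style learnable fixture padded into the 13-column frame.
xor_ds <- function(reps = 20) {
  grid <- expand.grid(a = c(0, 1), b = c(0, 1))
  grid <- grid[rep(seq_len(4), reps), ]
  X <- matrix(0, nrow(grid), 13)
  X[, 1] <- grid$a
  X[, 2] <- grid$b
  regression_ds(X, as.numeric(xor(grid$a == 1, grid$b == 1)))
}
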