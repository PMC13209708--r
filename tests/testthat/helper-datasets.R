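# Fixtures built in code: small datasets with known generating models.

# dataset with pic50 = intercept + X beta + N(0, sigma), descriptors drawn iid
make_linear_dataset <- function(n, beta, intercept = 0, sigma = 0, seed = 1,
                                split = "train", x_sd = 1) {
  set.seed(seed)
  p <- length(beta)
  nms <- if (!is.null(names(beta))) names(beta) else paste0("x", seq_len(p))
  X <- matrix(rnorm(n * p, sd = x_sd), n, p, dimnames = list(NULL, nms))
  y <- intercept + drop(X %*% beta) + rnorm(n, 0, sigma)
  df <- data.frame(id = sprintf("c%03d", seq_len(n)), X, check.names = FALSE)
  df$pic50 <- y
  df$split <- split
  schema <- descriptor_schema(extra = setdiff(nms, modeling_descriptors()))
  ds <- compound_dataset(df, schema = schema)
  # incomplete-descriptor flagging only applies to the six modeling columns;
  # force completeness for generic synthetic descriptor sets
  ds$complete <- TRUE
  ds$split <- split
  ds
}

# six-descriptor dataset from the package generator, pre-split
make_reference_split <- function(n = 121, sigma = 0.59, seed = 1,
                                 fractions = c(train = 100 / 121, test = 21 / 121)) {
  ds <- synthetic_reference(n = n, sigma = sigma, seed = seed)
  random_split(ds, fractions = fractions, seed = seed + 1000)
}

# normal-equations OLS oracle, independent of the qr-based implementation
ols_oracle <- function(X, y) {
  Xd <- cbind(1, X)
  solve(t(Xd) %*% Xd, t(Xd) %*% y)[, 1]
}

# brute-force leave-one-out Q2 oracle: refit with each record left out
q2_oracle <- function(X, y) {
  n <- length(y)
  press <- 0
  for (i in seq_len(n)) {
    b <- ols_oracle(X[-i, , drop = FALSE], y[-i])
    pred <- unname(b[1] + sum(X[i, ] * b[-1]))
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

# two-pass Pearson correlation oracle
pearson_oracle <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
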