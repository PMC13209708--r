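test_that("MLP with identity activations represents linear maps", {
  ds <- make_linear_dataset(40, beta = c(x1 = 0.5), sigma = 0, seed = 1)
  m <- train_mlp(ds,
    hidden = 1, activations = c("identity", "identity"),
    seed = 1, descriptors = "x1"
  )
  expect_lt(m$sos_train, 1e-6)

  const <- make_linear_dataset(20, beta = c(x1 = 0), intercept = 3.3, sigma = 0, seed = 2)
  mc <- train_mlp(const,
    hidden = 2, activations = c("tanh", "identity"),
    seed = 1, descriptors = "x1"
  )
  expect_lt(mc$sos_train, 1e-8)
  expect_equal(unname(predict(mc, data.frame(x1 = c(-2, 0, 5)))), rep(3.3, 3),
    tolerance = 1e-3
  )
})

test_that("a tanh network fits a smooth nonlinear curve", {
  set.seed(3)
  x <- seq(0, 2 * pi, length.out = 120)
  df <- data.frame(id = sprintf("p%03d", seq_along(x)), x1 = x, pic50 = sin(3 * x))
  ds <- compound_dataset(df, schema = descriptor_schema(extra = "x1"))
  ds$complete <- TRUE
  ds$split <- "train"
  m <- train_mlp(ds,
    hidden = 8, activations = c("tanh", "identity"),
    seed = 4, maxit = 500, descriptors = "x1"
  )
  pred <- predict(m, as.data.frame(ds))
  r2 <- 1 - sum((pred - ds$pic50)^2) / sum((ds$pic50 - mean(ds$pic50))^2)
  expect_gt(r2, 0.95)
})

test_that("automated search retains ranked networks reproducibly", {
  ds <- make_reference_split(
    n = 60, sigma = 0.59, seed = 11,
    fractions = c(train = 0.7, test = 0.15, validation = 0.15)
  )
  s1 <- ann_search(ds, n_train = 6, n_retain = 3, seed = 5, maxit = 60)
  expect_equal(nrow(s1$table), 3)
  expect_true(all(diff(s1$table$sos_validation) >= 0))
  s2 <- ann_search(ds, n_train = 6, n_retain = 3, seed = 5, maxit = 60)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$models[[1]]$W1, s2$models[[1]]$W1)

  single <- ann_search(ds, n_train = 1, n_retain = 1, seed = 5, maxit = 60)
  expect_equal(length(single$models), 1)
  expect_error(ann_search(ds, n_train = 2, n_retain = 3, seed = 1), "n_retain")
})

test_that("GSA scores ignored inputs at exactly 1 and informative inputs above", {
  ds <- make_linear_dataset(120,
    beta = c(x1 = 2, x2 = 0), sigma = 0.1, seed = 6,
    split = "train"
  )
  m <- train_mlp(ds,
    hidden = 4, activations = c("tanh", "identity"), seed = 7,
    maxit = 300, descriptors = c("x1", "x2")
  )
  g <- gsa(m, ds)
  expect_gt(g$score[g$descriptor == "x1"], 2)
  expect_lt(abs(g$score[g$descriptor == "x2"] - 1), 0.2)
  expect_equal(g$descriptor[1], "x1")

  # provably ignored input: zero all weights out of x2
  m0 <- m
  m0$W1[, 3] <- 0 # column 1 is the bias; column 3 feeds x2
  g0 <- gsa(m0, ds)
  expect_identical(g0$score[g0$descriptor == "x2"], 1)

  # retraining-based ablation agrees on which input matters
  gr <- gsa(m, ds, method = "retrain")
  expect_gt(gr$score[gr$descriptor == "x1"], gr$score[gr$descriptor == "x2"])
  expect_gt(gr$score[gr$descriptor == "x1"], 2)
})

test_that("duplicating an informative input dilutes its sensitivity score", {
  # exact duplicate columns with a linear network: the fitted weight mass is
  # shared between the copies, so ablating either one costs less than
  # ablating the single informative input of the reference fit
  base <- make_linear_dataset(150, beta = c(x1 = 2), sigma = 0.2, seed = 8)
  base$x1b <- base$x1
  attr(base, "schema") <- descriptor_schema(extra = c("x1", "x1b"))
  m_single <- train_mlp(base,
    hidden = 2, activations = c("identity", "identity"),
    seed = 9, maxit = 300, descriptors = "x1"
  )
  m_dup <- train_mlp(base,
    hidden = 2, activations = c("identity", "identity"),
    seed = 9, maxit = 300, descriptors = c("x1", "x1b")
  )
  s_single <- gsa(m_single, base)$score[1]
  g_dup <- gsa(m_dup, base)
  expect_lt(max(g_dup$score), s_single)
})

test_that("a retained network matches OLS accuracy on linear reference data", {
  ds <- make_reference_split(
    n = 121, sigma = 0.59, seed = 13,
    fractions = c(train = 0.7, test = 0.15, validation = 0.15)
  )
  search <- ann_search(ds, n_train = 40, n_retain = 5, seed = 13, maxit = 200)
  ols <- fit_ols(ds)
  test_rows <- as.data.frame(ds)[ds$split == "test", ]
  r2_of <- function(pred) {
    1 - sum((pred - test_rows$pic50)^2) /
      sum((test_rows$pic50 - mean(test_rows$pic50))^2)
  }
  r2_ann <- r2_of(predict(search$models[[1]], test_rows))
  r2_ols <- r2_of(predict(ols, test_rows))
  expect_gte(r2_ann, r2_ols - 0.1)
})
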