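test_that("OLS recovers exact linear data and matches the normal-equations oracle", {
  ds <- make_linear_dataset(20, beta = c(x1 = 3), intercept = 2, sigma = 0, seed = 1)
  m <- fit_ols(ds, subset = "x1")
  expect_equal(unname(m$coefficients), c(2, 3), tolerance = 1e-10)
  expect_equal(m$stats$r2, 1, tolerance = 1e-12)

  # minimal n = k + 2 case: statistics still defined
  ds_min <- make_linear_dataset(5, beta = c(x1 = 1, x2 = -1, x3 = 0.5), sigma = 0.3, seed = 2)
  m_min <- fit_ols(ds_min, subset = c("x1", "x2", "x3"))
  expect_true(all(is.finite(m_min$se)))
  expect_true(is.finite(m_min$stats$r2_adj))

  # random designs: equality with an independent normal-equations solve
  for (seed in 1:5) {
    beta <- c(x1 = 1.5, x2 = -2, x3 = 0.7)
    ds_r <- make_linear_dataset(40, beta = beta, intercept = 0.5, sigma = 0.5, seed = seed)
    m_r <- fit_ols(ds_r, subset = names(beta))
    X <- as.matrix(as.data.frame(ds_r)[, names(beta)])
    oracle <- ols_oracle(X, ds_r$pic50)
    expect_equal(unname(m_r$coefficients), unname(oracle), tolerance = 1e-8)
    expect_true(all(abs(m_r$coefficients[-1] - beta) < 3 * m_r$se[-1] + 1e-9))
  }

  # rank deficiency is reported with the offending column
  ds_dup <- make_linear_dataset(30, beta = c(x1 = 1, x2 = 2), sigma = 0.1, seed = 3)
  ds_dup$x1dup <- ds_dup$x1
  attr(ds_dup, "schema") <- descriptor_schema(extra = c("x1", "x2", "x1dup"))
  expect_error(fit_ols(ds_dup, subset = c("x1", "x2", "x1dup")), "collinear.*x1dup")
})

test_that("LOO Q2 equals the brute-force refit oracle and behaves at limits", {
  ds0 <- make_linear_dataset(25, beta = c(x1 = 2, x2 = -1), intercept = 1, sigma = 0, seed = 4)
  expect_equal(q2_loo(ds0, subset = c("x1", "x2")), 1, tolerance = 1e-10)

  ds <- make_linear_dataset(25, beta = c(x1 = 2, x2 = -1), intercept = 1, sigma = 0.8, seed = 5)
  X <- as.matrix(as.data.frame(ds)[, c("x1", "x2")])
  expect_equal(
    q2_loo(ds, subset = c("x1", "x2")),
    q2_oracle(X, ds$pic50),
    tolerance = 1e-8
  )

  # response independent of the predictors: no predictive power
  ds_null <- make_linear_dataset(500, beta = c(x1 = 0, x2 = 0), sigma = 1, seed = 6)
  expect_lt(q2_loo(ds_null, subset = c("x1", "x2")), 0.1)
})

test_that("test-set RMSE is computed over held-out records", {
  m <- published_mlr()
  ds <- synthetic_reference(n = 40, sigma = 0, seed = 7)
  ds$split <- "test"
  expect_equal(evaluate_test(m, ds), 0, tolerance = 1e-9)

  one <- as.data.frame(ds)[1, ]
  one$pic50 <- one$pic50 + 0.59
  ds1 <- compound_dataset(one[, setdiff(names(one), "ic50_nM")])
  ds1$split <- "test"
  expect_equal(evaluate_test(m, ds1), 0.59, tolerance = 1e-9)

  # 21 points with N(0, 0.6^2) errors: RMSE near 0.6
  ds21 <- synthetic_reference(n = 21, sigma = 0.6, seed = 1)
  ds21$split <- "test"
  rmse <- evaluate_test(m, ds21)
  expect_gt(rmse, 0.4)
  expect_lt(rmse, 0.8)

  ds_na <- ds21
  ds_na$pic50[3] <- NA
  ds_na$complete[3] <- TRUE
  expect_error(evaluate_test(m, ds_na), "pic50")
})

test_that("best-subset search finds the generating descriptors among decoys", {
  set.seed(9)
  beta <- c(x1 = 2, x2 = -1.5, x3 = 1)
  ds <- make_linear_dataset(500,
    beta = c(beta, n1 = 0, n2 = 0, n3 = 0),
    sigma = 1, seed = 9
  )
  res <- best_subset_search(ds,
    pool = c(names(beta), "n1", "n2", "n3"),
    kmin = 2, kmax = 3, tolerance_threshold = 0.1
  )
  expect_equal(sort(res$models[[1]]$descriptors), sort(names(beta)))

  res2 <- best_subset_search(ds, pool = c("x1", "x2"), kmin = 2, kmax = 2)
  expect_equal(nrow(res2$table), 1)

  # a duplicated column can never co-occur in a retained subset
  ds$dup <- ds$x1
  attr(ds, "schema") <- descriptor_schema(extra = c(names(beta), "n1", "n2", "n3", "dup"))
  res3 <- best_subset_search(ds,
    pool = c("x1", "dup", "x2"), kmin = 2, kmax = 3,
    tolerance_threshold = 0.1
  )
  both <- grepl("x1", res3$table$subset, fixed = TRUE) &
    grepl("dup", res3$table$subset, fixed = TRUE)
  expect_false(any(both))
})

test_that("the frozen published equation reproduces the printed predictions", {
  m <- published_mlr()
  ds <- sunscreen_descriptors()
  pred <- predict(m, ds)
  printed <- sunscreen_published_predictions()
  expect_true(max(abs(pred[printed$id] - printed$MLR)) <= 0.02)
  expect_lt(abs(pred[["OCR"]] - 6.13), 0.02)
  expect_lt(abs(pred[["ET"]] - 13.82), 0.02)
  expect_lt(abs(pred[["PABA"]] - 4.48), 0.02)

  zero <- data.frame(id = "z", nRot = 0, Flex = 0, Fsp3 = 0, logD = 0, caco2 = 0, PPB = 0)
  expect_equal(unname(predict(m, zero)), 1.68)

  expect_error(predict(m, zero[, -3]), "Flex")
})

test_that("published statistics line is self-consistent under the fit formulas", {
  st <- fit_stats_from_r2(r2 = 0.706, n = 100, k = 6)
  expect_equal(st$r2_adj, 0.687, tolerance = 0.001 / 0.687)
  expect_equal(st$f_stat, 37.15, tolerance = 0.15 / 37.15)
  expect_lt(st$p_value, 0.001)
})

test_that("mean aggregation reproduces the printed consensus columns", {
  printed <- sunscreen_published_predictions()
  agg <- aggregate_means(printed[, c("id", "MLR", "ANN1", "SVR")],
    sets = list(Mean1 = c("MLR", "ANN1", "SVR"))
  )
  expect_equal(round_half_up(agg$Mean1[agg$id == "OCR"], 2), 5.94)
  expect_equal(round_half_up(agg$Mean1[agg$id == "DHHB"], 2), 5.30)
  expect_equal(round_half_up(agg$Mean1, 2), printed$Mean1)

  same <- data.frame(id = "s", MLR = 4.4, ANN1 = 4.4, SVR = 4.4)
  expect_equal(aggregate_means(same, sets = list(Mean1 = c("MLR", "ANN1", "SVR")))$Mean1, 4.4)

  expect_error(
    aggregate_means(printed[, c("id", "MLR")], sets = list(Mean1 = c("MLR", "ANN1", "SVR"))),
    "missing member"
  )
})

test_that("model serialization round-trips through JSON", {
  ds <- make_linear_dataset(30, beta = c(x1 = 1.2, x2 = -0.4), sigma = 0.2, seed = 10)
  m <- fit_ols(ds, subset = c("x1", "x2"))
  f <- withr::local_tempfile(fileext = ".json")
  write_mlr_json(m, f)
  back <- read_mlr_json(f)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$se, m$se)
  expect_equal(back$stats$r2, m$stats$r2)
  expect_equal(predict(back, as.data.frame(ds)), predict(m, as.data.frame(ds)))
})
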