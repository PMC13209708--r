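test_that("correlation matrix matches hand and brute-force Pearson values", {
  df <- data.frame(
    id = c("a", "b", "c", "d", "e"),
    x = c(1, 2, 3, 4, 5), y = -c(1, 2, 3, 4, 5), z = c(2, 1, 4, 3, 6)
  )
  ds <- compound_dataset(df, schema = descriptor_schema(extra = c("x", "y", "z")))
  cm <- correlation_matrix(ds, vars = c("x", "y", "z"))
  expect_equal(diag(cm$r), c(x = 1, y = 1, z = 1))
  expect_equal(cm$r["x", "y"], -1)
  expect_equal(max(abs(cm$r - t(cm$r))), 0, tolerance = 1e-12)

  ds3 <- compound_dataset(
    data.frame(id = c("a", "b", "c"), x = c(1, 2, 3), y = c(1, 3, 2)),
    schema = descriptor_schema(extra = c("x", "y"))
  )
  expect_equal(correlation_matrix(ds3, vars = c("x", "y"))$r["x", "y"], 0.5)

  # brute-force two-pass oracle on random 20 x 6 tables
  for (seed in 1:3) {
    set.seed(seed)
    M <- matrix(rnorm(120), 20, 6, dimnames = list(NULL, paste0("v", 1:6)))
    dsr <- compound_dataset(
      data.frame(id = sprintf("r%02d", 1:20), M, check.names = FALSE),
      schema = descriptor_schema(extra = colnames(M))
    )
    cmr <- correlation_matrix(dsr, vars = colnames(M))$r
    for (i in 1:5) {
      for (j in (i + 1):6) {
        expect_equal(cmr[i, j], pearson_oracle(M[, i], M[, j]), tolerance = 1e-10)
      }
    }
  }

  dsz <- compound_dataset(
    data.frame(id = letters[1:4], x = rnorm(4), y = rep(2, 4)),
    schema = descriptor_schema(extra = c("x", "y"))
  )
  expect_error(correlation_matrix(dsz, vars = c("x", "y")), "zero-variance.*y")
})

test_that("tolerance equals 1 - R2 of an OLS fit and behaves at its limits", {
  set.seed(21)
  n <- 1000
  x1 <- rnorm(n)
  # noise SD 1/sqrt(3) makes R2 = var(x)/ (var(x)+1/3) ~ 0.75
  x2 <- x1 + rnorm(n, sd = sqrt(1 / 3))
  x3 <- rnorm(n)
  ds <- compound_dataset(
    data.frame(id = sprintf("i%04d", 1:n), x1 = x1, x2 = x2, x3 = x3),
    schema = descriptor_schema(extra = c("x1", "x2", "x3"))
  )
  # duplicated target among co-regressors
  expect_equal(tolerance(ds, "x1", c("x1", "x3")), 0)
  # independence limit
  expect_equal(tolerance(ds, "x3", c("x1", "x2")), 1, tolerance = 0.02)
  # near-collinear pair: tolerance ~ 0.25, equal to direct lm-based 1 - R2
  tol <- tolerance(ds, "x2", "x1")
  expect_equal(tol, 0.25, tolerance = 0.2)
  lm_r2 <- summary(lm(x2 ~ x1))$r.squared
  expect_equal(tol, 1 - lm_r2, tolerance = 1e-10)
})

test_that("adding a co-regressor never increases tolerance", {
  set.seed(31)
  for (rep in 1:5) {
    M <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("v", 1:5)))
    ds <- compound_dataset(
      data.frame(id = sprintf("r%02d", 1:40), M, check.names = FALSE),
      schema = descriptor_schema(extra = colnames(M))
    )
    t2 <- tolerance(ds, "v1", c("v2", "v3"))
    t3 <- tolerance(ds, "v1", c("v2", "v3", "v4"))
    t4 <- tolerance(ds, "v1", c("v2", "v3", "v4", "v5"))
    expect_true(t3 <= t2 + 1e-12)
    expect_true(t4 <= t3 + 1e-12)
    expect_true(all(c(t2, t3, t4) >= 0 & c(t2, t3, t4) <= 1))
  }
})

test_that("subset screening flags collinear subsets and passes clean ones", {
  set.seed(41)
  x <- rnorm(50)
  ds <- compound_dataset(
    data.frame(id = sprintf("i%02d", 1:50), x = x, x2 = 2 * x, z = rnorm(50)),
    schema = descriptor_schema(extra = c("x", "x2", "z"))
  )
  rep_fail <- screen_subset(ds, c("x", "x2"), threshold = 0.05)
  expect_false(attr(rep_fail, "passes"))
  expect_true(all(rep_fail$tolerance < 1e-10))

  rep_one <- screen_subset(ds, "z", threshold = 0.1)
  expect_true(attr(rep_one, "passes"))
  expect_equal(rep_one$tolerance, 1)

  expect_error(screen_subset(ds, "z", threshold = 0), "threshold")

  # six-descriptor set with the published correlation structure passes at 0.1
  ref <- synthetic_reference(n = 10000, seed = 17)
  rep6 <- screen_subset(ref, modeling_descriptors(), threshold = 0.1)
  expect_true(attr(rep6, "passes"))
  expect_true(min(rep6$tolerance) > 0.1)
  # and each tolerance agrees with a direct OLS computation
  for (i in seq_along(modeling_descriptors())) {
    d <- modeling_descriptors()[i]
    others <- setdiff(modeling_descriptors(), d)
    fml <- stats::reformulate(others, response = d)
    direct <- 1 - summary(lm(fml, data = as.data.frame(ref)))$r.squared
    expect_equal(rep6$tolerance[rep6$descriptor == d], direct, tolerance = 1e-10)
  }
})
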