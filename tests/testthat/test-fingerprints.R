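test_that("fingerprints are deterministic and minimal for single atoms", {
  fp_methane <- morgan_fingerprint("C")
  expect_equal(fp_methane$n_atoms, 1)
  expect_equal(length(fp_methane$bits), 1) # only the radius-0 environment

  a <- morgan_fingerprint("CCCCC(CC)COC(=O)c1ccccc1O")
  b <- morgan_fingerprint("CCCCC(CC)COC(=O)c1ccccc1O")
  expect_identical(a$bits, b$bits)
  expect_identical(a$bit_atoms, b$bit_atoms)

  expect_error(parse_smiles(""), "empty")
  expect_error(morgan_fingerprint("C", n_bits = 1000), "power of two")
})

test_that("bit-atom maps cover each environment's neighborhood", {
  fp <- morgan_fingerprint("Nc1ccc(cc1)C(=O)O") # PABA: 10 heavy atoms
  expect_equal(fp$n_atoms, 10)
  expect_true(all(fp$environments$radius %in% 0:2))
  for (b in fp$bits) {
    atoms <- fp$bit_atoms[[as.character(b)]]
    expect_true(all(atoms >= 1 & atoms <= fp$n_atoms))
  }
  # radius-0 environments map to single atoms
  r0 <- fp$environments[fp$environments$radius == 0, ]
  solo <- vapply(
    as.character(setdiff(r0$bit, fp$environments$bit[fp$environments$radius > 0])),
    function(b) length(fp$bit_atoms[[b]]),
    integer(1)
  )
  if (length(solo)) expect_true(all(solo >= 1))
})

test_that("PLS with as many components as features reproduces OLS", {
  set.seed(1)
  X <- matrix(rnorm(15 * 4), 15, 4)
  y <- drop(X %*% c(1, -2, 0.5, 3)) + rnorm(15, 0, 0.2)
  pw <- bcheqsar:::pls_weights(X, y, nc = 4)
  pred_pls <- drop(X %*% pw$w) + pw$intercept
  pred_ols <- unname(fitted(lm(y ~ X)))
  expect_equal(pred_pls, pred_ols, tolerance = 1e-6)
})

test_that("fingerprint PLS is seeded, conserves contributions, and flags signal bits", {
  lib <- toy_smiles_library()
  # constructed activity: benzimidazole/triazine motifs high, chains low
  y <- ifelse(lib$motif == "positive", 7.5,
    ifelse(lib$motif == "negative", 4.0, 5.5)
  ) + seq(-0.2, 0.2, length.out = nrow(lib))
  m1 <- train_fingerprint_pls(lib$smiles, y, n_components = 4, seed = 3)
  m2 <- train_fingerprint_pls(lib$smiles, y, n_components = 4, seed = 3)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$train_idx, m2$train_idx)

  # conservation identity for every molecule
  for (i in seq_len(nrow(lib))) {
    cm <- atom_contributions(m1, lib$smiles[i], id = lib$id[i])
    expect_equal(attr(cm, "total"),
      attr(cm, "prediction") - attr(cm, "intercept"),
      tolerance = 1e-9
    )
    pred_direct <- predict(m1, lib$smiles[i])
    expect_equal(attr(cm, "prediction"), pred_direct, tolerance = 1e-9)
  }

  # motif atoms carry the sign of their class on average
  pos_mol <- atom_contributions(m1, "c1ccc(cc1)-c1nc2ccccc2[nH]1")
  neg_mol <- atom_contributions(m1, "CCCCCCc1ccccc1")
  expect_gt(mean(pos_mol$contribution), mean(neg_mol$contribution))
})

test_that("symmetric atoms receive identical contributions", {
  lib <- toy_smiles_library()
  y <- ifelse(lib$motif == "positive", 7, 4) + seq(0, 0.5, length.out = nrow(lib))
  smiles <- c(lib$smiles, "c1ccccc1")
  yy <- c(y, 5)
  m <- train_fingerprint_pls(smiles, yy, n_components = 3, seed = 5)
  cm <- atom_contributions(m, "c1ccccc1")
  expect_equal(length(unique(round(cm$contribution, 12))), 1)
})

test_that("molecules sharing no vocabulary bits get intercept-only predictions", {
  alkanes <- c("CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CCCCCCC", "CCCCCCCC")
  y <- seq(4, 7, length.out = length(alkanes))
  m <- train_fingerprint_pls(alkanes, y,
    n_components = 2, train_fraction = 0.9,
    seed = 7
  )
  cm <- atom_contributions(m, "c1ccccc1") # aromatic carbons: disjoint bits
  expect_true(all(cm$contribution == 0))
  expect_equal(attr(cm, "prediction"), m$intercept)
})

test_that("a constant response yields the constant predictor", {
  alkanes <- c("CC", "CCC", "CCCC", "CCCCC", "CCCCCC")
  m <- train_fingerprint_pls(alkanes, rep(5.5, 5),
    n_components = 2,
    train_fraction = 0.9, seed = 9
  )
  expect_true(all(m$weights == 0))
  expect_equal(predict(m, "CCCCCCCCC"), 5.5)
})

test_that("single-substructure signal concentrates weight on its bits", {
  base <- c("CCO", "CCCO", "CCCCO", "CCN", "CCCN", "CCCCN")
  acid <- c("OC(=O)CC", "OC(=O)CCC", "OC(=O)CCCC", "OC(=O)CCN", "OC(=O)CCCN", "OC(=O)CCCCN")
  smiles <- c(base, acid)
  y <- c(rep(4, 6), rep(8, 6)) # presence of the carboxyl environments
  m <- train_fingerprint_pls(smiles, y, n_components = 2, train_fraction = 0.9, seed = 11)
  fp_acid <- morgan_fingerprint("OC(=O)CCC")
  fp_base <- morgan_fingerprint("CCCO")
  acid_only <- setdiff(fp_acid$bits, fp_base$bits)
  w_abs <- abs(m$weights)
  top_bit <- m$active_bits[which.max(w_abs)]
  expect_true(top_bit %in% acid_only)
})
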