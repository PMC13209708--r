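test_that("pIC50 conversion follows the molar convention and is monotone", {
  expect_equal(to_pic50(1), 9)
  expect_equal(to_pic50(1000), 6)
  expect_equal(to_pic50(53.7), 7.27, tolerance = 0.005 / 7.27)
  expect_error(to_pic50(0), "positive")
  expect_error(to_pic50(-5), "positive")
  set.seed(11)
  x <- sort(rlnorm(50, meanlog = 3, sdlog = 2))
  expect_true(all(diff(to_pic50(x)) < 0))
})

test_that("the packaged sunscreen table reads with the printed values", {
  ds <- sunscreen_descriptors()
  expect_s3_class(ds, "compound_dataset")
  expect_equal(nrow(ds), 16)
  expect_true(all(ds$complete))
  ocr <- as.data.frame(ds)[ds$id == "OCR", ]
  expect_equal(ocr$nRot, 10)
  expect_equal(ocr$Flex, 0.667)
  expect_equal(ocr$logD, 4.52)
  expect_equal(ocr$caco2, -4.94)
})

test_that("CSV reading handles headers-only files, Unicode minus, and bad cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,nRot,Flex,Fsp3,logD,caco2,PPB", f)
  empty <- read_compound_table(f)
  expect_equal(nrow(empty), 0)

  writeLines(c(
    "id,nRot,Flex,Fsp3,logD,caco2,PPB",
    "a,1,0.1,0.2,1.5,−4.94,50",
    "b,2,0.2,0.3,2.5,−5.1,60",
    "c,3,0.3,0.4,3.5,−4.2,70"
  ), f, useBytes = FALSE)
  ds <- read_compound_table(f)
  expect_equal(ds$caco2, c(-4.94, -5.1, -4.2))

  writeLines(c("nRot,Flex", "1,0.1"), f)
  expect_error(read_compound_table(f), "'id' column")

  writeLines(c("id,nRot,Flex,Fsp3,logD,caco2,PPB", "a,oops,0.1,0.2,1.5,-4,50"), f)
  expect_error(read_compound_table(f), "non-numeric.*'nRot'.*row 1")
})

test_that("rows missing modeling descriptors are retained but unassigned", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,nRot,Flex,Fsp3,logD,caco2,PPB",
    "full,1,0.1,0.2,1.5,-4.9,50",
    "hole,2,,0.3,2.5,-5.1,60"
  ), f)
  ds <- read_compound_table(f)
  expect_equal(nrow(ds), 2)
  expect_equal(ds$complete, c(TRUE, FALSE))
  expect_equal(ds$split[2], "unassigned")
})

test_that("write/read round trip preserves descriptor doubles bit-exactly", {
  ds <- synthetic_reference(n = 25, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_compound_table(ds, f)
  back <- read_compound_table(f)
  for (d in modeling_descriptors()) {
    expect_identical(back[[d]], ds[[d]])
  }
  expect_identical(back$pic50, ds$pic50)
})

test_that("dataset invariants are enforced on construction", {
  df <- data.frame(
    id = "x", nRot = 4, Flex = 0.4, Fsp3 = 0.2, logD = 2, caco2 = -5, PPB = 50,
    ic50_nM = 100, pic50 = 7.5
  )
  expect_error(compound_dataset(df), "inconsistent")
  df$pic50 <- to_pic50(100)
  expect_s3_class(compound_dataset(df), "compound_dataset")
  df2 <- data.frame(
    id = "y", nRot = 6, nRig = 10, Flex = 0.7, Fsp3 = 0.2,
    logD = 2, caco2 = -5, PPB = 50
  )
  expect_error(compound_dataset(df2), "Flex deviates")
  df2$Flex <- 0.6
  expect_s3_class(compound_dataset(df2), "compound_dataset")
})

test_that("random splitting gives deterministic counts with remainder to train", {
  ds <- synthetic_reference(n = 121, seed = 5)
  sp <- random_split(ds, c(train = 100 / 121, test = 21 / 121), seed = 9)
  expect_equal(sum(sp$split == "train"), 100)
  expect_equal(sum(sp$split == "test"), 21)

  ds4 <- synthetic_reference(n = 4, seed = 5)
  expect_equal(unique(random_split(ds4, c(train = 1.0), seed = 1)$split), "train")

  ds8 <- synthetic_reference(n = 8, seed = 5)
  s1 <- random_split(ds8, c(train = 0.75, test = 0.25), seed = 1)
  s2 <- random_split(ds8, c(train = 0.75, test = 0.25), seed = 2)
  for (s in list(s1, s2)) {
    expect_equal(sum(s$split == "train"), 6)
    expect_equal(sum(s$split == "test"), 2)
  }
  expect_false(identical(s1$split, s2$split))
  expect_identical(
    random_split(ds8, c(train = 0.75, test = 0.25), seed = 1)$split,
    s1$split
  )
  # counts do not depend on record order
  perm <- compound_dataset(as.data.frame(ds8)[sample(8), ])
  sp_perm <- random_split(perm, c(train = 0.75, test = 0.25), seed = 1)
  expect_equal(table(sp_perm$split), table(s1$split))

  expect_error(random_split(ds8, c(train = 0.6, test = 0.2), seed = 1), "sum to 1")
  empty <- compound_dataset(data.frame(id = character(0)))
  expect_error(random_split(empty, c(train = 1), seed = 1), "no records")
})
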