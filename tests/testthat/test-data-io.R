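test_that("PaDEL-dialect feature tables parse with kind validation", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Name,FP1,FP2", "c1,0,1", "c2,1,1"), tf)
  b <- read_feature_table(tf, "toy", "binary")
  expect_s3_class(b, "dili_feature_block")
  expect_identical(b$compound_ids, c("c1", "c2"))
  expect_identical(b$feature_names, c("FP1", "FP2"))
  expect_equal(b$values, matrix(c(0, 1, 1, 1), 2))

  writeLines(c("Name,FP1,FP2", "c1,0,2", "c2,1,1"), tf)
  expect_error(read_feature_table(tf, "toy", "binary"), "non-binary value")
  b2 <- read_feature_table(tf, "toy", "count")
  expect_equal(b2$values[1, 2], 2)

  writeLines(c("Name,FP1", "c1,x"), tf)
  expect_error(read_feature_table(tf, "toy", "binary"), "non-numeric")
  writeLines(c("Name,FP1", "c1,1", "c1,0"), tf)
  expect_error(read_feature_table(tf, "toy", "binary"), "duplicate")
  expect_error(read_feature_table(file.path(tempdir(), "nope.csv"),
                                  "toy", "binary"), "not found")
})

test_that("write/read round-trip is the identity on random blocks", {
  for (kind in c("binary", "count", "continuous")) {
    for (seed in 1:3) {
      b <- random_block("RT", kind, n = 7, p = 5, seed = seed)
      tf <- withr::local_tempfile(fileext = ".csv")
      write_feature_table(b, tf)
      expect_equal(read_feature_table(tf, "RT", kind), b)
    }
  }
})

test_that("parsing is order-stable under row permutation", {
  b <- random_block("P", "binary", n = 8, p = 4, seed = 9)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(b, tf)
  lines <- readLines(tf)
  set.seed(1)
  perm <- sample(2:9)
  writeLines(c(lines[1], lines[perm]), tf)
  b2 <- read_feature_table(tf, "P", "binary")
  expect_identical(b2$compound_ids, b$compound_ids[perm - 1])
  expect_equal(b2$values, b$values[perm - 1, ])
})

test_that("labels parse both codings and reject bad input", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,label", "c1,most-DILI", "c2,no-DILI"), tf)
  expect_identical(read_labels(tf), c(c1 = 1L, c2 = 0L))
  writeLines(c("id,label", "c1,1", "c2,0"), tf)
  expect_identical(read_labels(tf), c(c1 = 1L, c2 = 0L))
  writeLines(c("id,label", "c1,1", "c1,0"), tf)
  expect_error(read_labels(tf), "duplicate")
  writeLines(c("id,label", "c1,maybe"), tf)
  expect_error(read_labels(tf), "unknown label")
})

test_that("SDF ids come from the CID field, else the title line", {
  tf <- withr::local_tempfile(fileext = ".sdf")
  write_test_sdf(tf)
  expect_identical(extract_sdf_ids(tf), c("MoleculeA", "2244"))
  empty <- withr::local_tempfile(fileext = ".sdf")
  file.create(empty)
  expect_identical(extract_sdf_ids(empty), character(0))
})

test_that("assemble_dataset intersects, aligns and validates", {
  b1 <- random_block("B1", "binary", n = 6, p = 4, seed = 1)   # c01..c06
  b2 <- random_block("B2", "count", n = 4, p = 3, seed = 2)    # c01..c04
  labels <- setNames(c(1L, 0L, 1L, 0L, 1L), sprintf("c%02d", 1:5))
  expect_message(ds <- assemble_dataset(list(b1, b2), labels), "dropped 2")
  expect_identical(ds$compound_ids, sprintf("c%02d", 1:4))
  expect_identical(names(ds$blocks), c("B1", "B2"))

  # alignment oracle: brute-force row lookup per kept compound
  for (id in ds$compound_ids) {
    expect_equal(ds$blocks$B1$values[match(id, ds$compound_ids), ],
                 b1$values[match(id, b1$compound_ids), ])
    expect_equal(ds$blocks$B2$values[match(id, ds$compound_ids), ],
                 b2$values[match(id, b2$compound_ids), ])
  }
  expect_silent(validate_dataset(ds))

  # single class after intersection
  lab1 <- setNames(rep(1L, 4), sprintf("c%02d", 1:4))
  expect_error(suppressMessages(assemble_dataset(list(b1, b2), lab1)),
               "single-class")
  # empty intersection
  b3 <- random_block("B3", "binary", n = 3, p = 2, seed = 3)
  b3$compound_ids <- paste0("z", 1:3)
  expect_error(suppressMessages(assemble_dataset(list(b1, b3), labels)),
               "empty intersection")
})

test_that("concat_blocks binds columns with block-prefixed names", {
  ds <- tiny_dataset(n = 30, seed = 5)
  X <- concat_blocks(ds, c("ExtendedFP", "MaccsFP"))
  expect_equal(ncol(X), 24 + 12)
  expect_true(all(startsWith(colnames(X)[1:24], "ExtendedFP.")))
  expect_equal(unname(X[, 1]), unname(ds$blocks$ExtendedFP$values[, 1]))
  expect_error(concat_blocks(ds, "NotABlock"), "no block")
})
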