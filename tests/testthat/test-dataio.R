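test_that("scan_dataset parses a BreakHis-style tree and orders records deterministically", {
  root <- withr::local_tempdir()
  tiny <- array(128, c(2, 2, 3))
  for (st in c("adenosis", "ductal")) {
    cls <- if (st == "adenosis") "benign" else "malignant"
    for (mag in c("40X", "100x")) {
      for (i in 1:2)
        write_patch(tiny, file.path(root, cls, st, mag, sprintf("p%d.png", i)))
    }
  }
  m <- scan_dataset(root, layout = "breakhis")
  expect_equal(manifest_size(m), 8)
  expect_identical(m$records$path, sort(m$records$path, method = "radix"))
  expect_setequal(unique(m$records$subtype), c("adenosis", "ductal"))
  expect_setequal(unique(m$records$magnification), c(40L, 100L))  # "40X" parses
  expect_identical(m$records$tumor_class[m$records$subtype == "ductal"][1], "malignant")

  # unparseable component keeps record with unknown fields, warns
  write_patch(tiny, file.path(root, "benign", "mystery_dir", "p.png"))
  expect_warning(m2 <- scan_dataset(root, layout = "breakhis"), "mystery_dir")
  expect_equal(manifest_size(m2), 9)
  odd <- m2$records[grepl("mystery_dir", m2$records$path), ]
  expect_identical(odd$tumor_class, "benign")
  expect_true(is.na(odd$subtype))

  empty <- withr::local_tempdir()
  expect_equal(manifest_size(scan_dataset(empty)), 0)
  expect_error(scan_dataset(file.path(empty, "nope")), "does not exist")
})

test_that("sample_subset draws exact per-class counts, reproducibly, and errors when short", {
  m <- fake_manifest(50)
  s <- sample_subset(m, "binary", per_class = 10, seed = 3)
  expect_equal(manifest_size(s), 20)
  expect_equal(unname(table(s$records$tumor_class)), c(10L, 10L), ignore_attr = TRUE)
  s2 <- sample_subset(m, "binary", per_class = 10, seed = 3)
  expect_identical(s$records, s2$records)
  s3 <- sample_subset(m, "binary", per_class = 10, seed = 4)
  expect_false(identical(s$records$path, s3$records$path))
  expect_error(sample_subset(m, "binary", per_class = 51, seed = 1), "benign")

  m8 <- fake_manifest(9, classes = ns$ALL_SUBTYPES)
  s8 <- sample_subset(m8, "multiclass", per_class = 4, seed = 1)
  expect_equal(manifest_size(s8), 32)
  expect_true(all(table(s8$records$subtype) == 4))
})

test_that("make_splits conserves records, hits largest-remainder counts per class, is seeded", {
  m <- fake_manifest(37)
  s <- make_splits(m, c(0.7, 0.1, 0.2), seed = 9)
  counts <- table(s$records$split)
  expect_equal(sum(counts), 74)
  per_class_expected <- apportion_oracle(37, c(0.7, 0.1, 0.2))
  for (cl in c("benign", "malignant")) {
    got <- table(factor(s$records$split[s$records$tumor_class == cl],
                        levels = c("train", "val", "test")))
    expect_equal(unname(c(got)), per_class_expected)
  }
  expect_identical(s$records, make_splits(m, c(0.7, 0.1, 0.2), seed = 9)$records)
  expect_error(make_splits(m, c(0.5, 0.4, 0.2), seed = 1), "sum to 1")
  expect_error(make_splits(ns$new_manifest(m$records[0, ]), c(.7, .1, .2)), "empty")
})

test_that("split proportions stay within one record of the request in every stratum", {
  for (n in c(10, 23, 101)) {
    m <- fake_manifest(n)
    s <- make_splits(m, c(0.7, 0.1, 0.2), seed = n)
    for (cl in c("benign", "malignant")) {
      got <- table(factor(s$records$split[s$records$tumor_class == cl],
                          levels = c("train", "val", "test")))
      expect_true(all(abs(got - n * c(0.7, 0.1, 0.2)) < 1),
                  label = sprintf("stratified within 1 record at n=%d", n))
    }
  }
})

test_that("manifests round-trip through CSV", {
  fix <- local_synth_dataset()
  m <- make_splits(fix$manifest, c(0.5, 0.25, 0.25), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, path)
  m2 <- read_manifest(path)
  expect_identical(m2$records[, c("path", "tumor_class", "subtype", "magnification", "split")],
                   m$records[, c("path", "tumor_class", "subtype", "magnification", "split")])
})
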