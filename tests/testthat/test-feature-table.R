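# catalog giving gene/position structure for imputation: one gene with
# mutations at increasing positions, plus a second gene far away
imp_catalog <- bind_catalog(
  cat_row("a1", "GA", 100, "S1"), cat_row("a2", "GA", 200, "S2"),
  cat_row("a3", "GA", 300, "S3"), cat_row("a4", "GA", 400, "S4"),
  cat_row("a5", "GA", 500, "S5"),
  cat_row("b1", "GB", 90000, "S6"), cat_row("b2", "GB", 90100, "S7")
)

test_that("missing_fraction reports per-feature and overall fractions", {
  m <- matrix(1, 5, 4, dimnames = list(paste0("m", 1:5), paste0("f", 1:4)))
  expect_equal(missing_fraction(feature_table(m))$overall, 0)
  m[1:3, 2] <- NA
  mf <- missing_fraction(feature_table(m))
  expect_equal(mf$overall, 3 / 20)
  expect_equal(unname(mf$per_feature), c(0, 0.6, 0, 0))
  m2 <- matrix(c(rep(NA_real_, 5), rep(1, 15)), 5, 4,
               dimnames = list(paste0("m", 1:5), paste0("f", 1:4)))
  mf2 <- missing_fraction(feature_table(m2))
  expect_equal(unname(mf2$per_feature[1]), 1)
  expect_equal(mf2$overall, 1 / 4)
})

test_that("kNN imputation aggregates nearest same-gene donors", {
  m <- matrix(NA_real_, 5, 1, dimnames = list(paste0("a", 1:5), "f"))
  m[c(1, 2, 4), 1] <- c(1, 2, 10)
  # a3 at pos 300: donors a2 (100 bp), a4 (100 bp), a1 (200 bp); k=3 median
  imp <- impute_features(feature_table(m), imp_catalog, k = 3)
  expect_equal(unname(imp$values["a3", "f"]), 2)
  # observed cells unchanged
  expect_equal(unname(imp$values[c("a1", "a2", "a4"), "f"]), c(1, 2, 10))
  # a5 at 500 with k=1: unique nearest donor a4 (100 bp)
  imp1 <- impute_features(feature_table(m), imp_catalog, k = 1)
  expect_equal(unname(imp1$values["a5", "f"]), 10)
})

test_that("distance ties break to the lower position", {
  m <- matrix(NA_real_, 3, 1, dimnames = list(c("a2", "a3", "a4"), "f"))
  m[c(1, 3), 1] <- c(7, 9)    # a2 at 200 and a4 at 400, both 100 bp from a3
  imp <- impute_features(feature_table(m), imp_catalog, k = 1)
  expect_equal(unname(imp$values["a3", "f"]), 7)
})

test_that("imputation is idempotent and falls back without same-gene donors", {
  m <- matrix(c(1, 2, NA, 5, NA, NA, 8), 7, 1,
              dimnames = list(c("a1", "a2", "a3", "a4", "a5", "b1", "b2"), "f"))
  ft <- feature_table(m)
  imp <- impute_features(ft, imp_catalog, k = 2)
  expect_false(anyNA(imp$values))
  expect_identical(impute_features(imp, imp_catalog, k = 2)$values, imp$values)
  # b1 has one same-gene donor (b2), any distance
  expect_equal(unname(imp$values["b1", "f"]), 8)

  # id not in the catalog: table-wide median with a warning
  m2 <- rbind(m, zz = NA_real_)
  expect_warning(imp2 <- impute_features(feature_table(m2), imp_catalog),
                 "absent from catalog")
  expect_equal(unname(imp2$values["zz", "f"]),
               median(m[!is.na(m)]))
})

test_that("fully missing features are an error; binary mode ties go to 0", {
  m <- matrix(NA_real_, 3, 1, dimnames = list(c("a1", "a2", "a3"), "dead"))
  expect_error(impute_features(feature_table(m), imp_catalog), "dead")

  mb <- matrix(c(0, 1, NA, 0, 1, NA), 3, 2,
               dimnames = list(c("a1", "a2", "a3"), c("b1", "b2")))
  ft <- feature_table(mb, c(b1 = "binary", b2 = "binary"))
  imp <- impute_features(ft, imp_catalog, k = 2)
  expect_equal(unname(imp$values["a3", ]), c(0, 0))   # 0/1 tie -> 0
})

test_that("binary features must be 0/1 where observed", {
  m <- matrix(c(0, 2), 2, 1, dimnames = list(c("a1", "a2"), "b"))
  expect_error(feature_table(m, c(b = "binary")), "outside")
})

test_that("feature tables round-trip through TSV with kinds sidecar", {
  spec <- fixture_spec(n_drivers = 10, n_passengers = 10, n_features = 4,
                       n_informative = 1, binary_fraction = 0.5,
                       missing_rate = 0.1, seed = 5)
  ft <- make_feature_table(spec)$table
  path <- withr::local_tempfile(fileext = ".tsv")
  kpath <- withr::local_tempfile(fileext = ".yaml")
  write_feature_table(ft, path, kpath)
  back <- read_feature_table(path, kpath)
  expect_equal(back$values, ft$values, tolerance = 1e-12)
  expect_equal(back$kinds, ft$kinds)
})
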