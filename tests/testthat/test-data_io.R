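test_that("delimited tables round-trip through write/read", {
  co <- tiny_cohort(seed = 4, missing_rate = 0.005)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_omics_table(co$table, path)
  back <- read_omics_table(path)
  expect_identical(back$sample_ids, co$table$sample_ids)
  expect_identical(back$feature_ids, co$table$feature_ids)
  expect_equal(back$values, co$table$values, tolerance = 1e-9)
  expect_identical(is.na(back$values), is.na(co$table$values))
})

test_that("reading applies layer prefixes and validates cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,F1,F2", "s1,1.5,2", "s2,3,4", "s3,5,"), path)
  tab <- read_omics_table(path, layer = "glycomics", missing_ceiling = 0.2)
  expect_equal(dim(tab), c(3L, 2L))
  expect_identical(tab$feature_ids, c("gly:F1", "gly:F2"))
  expect_true(is.na(tab$values[3L, 2L]))  # empty cell is missing, not zero

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,F1", "s1,1.5", "s2,oops"), bad)
  expect_error(read_omics_table(bad, layer = "proteomics"),
               "row 2.*F1", ignore.case = TRUE)

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,F1,F1", "s1,1,2"), dup)
  expect_error(read_omics_table(dup, layer = "proteomics"), "duplicate")
})

test_that("missingness above the ceiling is rejected", {
  vals <- matrix(1, 10, 10)
  vals[1, 1:2] <- NA  # 2% missing
  expect_error(omics_table(vals, feature_ids = sprintf("F%d", 1:10),
                           layer = "proteomics", missing_ceiling = 0.01),
               "missingness")
  expect_s3_class(omics_table(vals, feature_ids = sprintf("F%d", 1:10),
                              layer = "proteomics", missing_ceiling = 0.05),
                  "omics_table")
})

test_that("merge_layers concatenates in canonical order and aligns samples", {
  make <- function(p, layer, ids, seed) {
    set.seed(seed)
    omics_table(matrix(rnorm(length(ids) * p), length(ids), p,
                       dimnames = list(ids, sprintf("F%d", 1:p))),
                layer = layer)
  }
  ids <- sprintf("s%d", 1:5)
  tp <- make(100, "proteomics", ids, 1)
  tg <- make(82, "glycomics", rev(ids), 2)   # permuted sample order
  tm <- make(60, "metabolomics", ids, 3)
  merged <- merge_layers(list(tp, tg, tm))
  expect_equal(ncol(merged$values), 242L)
  expect_identical(merged$sample_ids, ids)
  expect_identical(unique(layer_of(merged$feature_ids)),
                   c("proteomics", "glycomics", "metabolomics"))
  # alignment: permuted layer re-ordered to the first table's samples
  expect_equal(merged$values[, "gly:F1"], tg$values[match(ids, tg$sample_ids), "gly:F1"])
  # identity and associativity
  expect_equal(merge_layers(list(tp))$values, tp$values)
  m1 <- merge_layers(list(merge_layers(list(tp, tg)), tm))
  expect_equal(m1$values, merged$values)
  tg_bad <- make(5, "glycomics", sprintf("x%d", 1:5), 4)
  expect_error(merge_layers(list(tp, tg_bad)), "sample sets differ")
})

test_that("impute_and_standardize uses fit-row statistics only", {
  ids <- sprintf("s%d", 1:6)
  vals <- cbind(f1 = c(1, 2, 3, 10, 11, 12), f2 = c(5, 5, 5, 5, 5, 5),
                f3 = c(1, NA, 3, 4, 5, 6))
  tab <- omics_table(vals, sample_ids = ids, layer = "metabolomics",
                     missing_ceiling = 0.1)
  # full fit: (1,2,3)-style feature standardized with sample sd
  z_all <- suppressWarnings(impute_and_standardize(tab))
  expect_equal(unname(z_all$values[1:3, "met:f1"]),
               (c(1, 2, 3) - mean(vals[, 1])) / sd(vals[, 1]))
  expect_true(all(z_all$values[, "met:f2"] == 0))      # constant -> zeros
  expect_warning(impute_and_standardize(tab), "zero-variance")

  # fit on first half: held-out rows transformed with fit statistics
  z_half <- suppressWarnings(impute_and_standardize(tab, fit_rows = 1:3))
  expect_equal(unname(z_half$values[4:6, "met:f1"]), (c(10, 11, 12) - 2) / 1)
  # missing cell imputed with fit-row median (median of 1,3 = 2)
  expect_equal(unname(z_half$values[2, "met:f3"]),
               (2 - mean(c(1, 2, 3))) / sd(c(1, 2, 3)))
  # idempotence with the same fit rows
  z_twice <- suppressWarnings(impute_and_standardize(z_all))
  expect_equal(z_twice$values, z_all$values, tolerance = 1e-12)
})

test_that("simple feature sets yield three-by-two tables", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tA\tB", "s1\t1\t2", "s2\t3\t4", "s3\t5\t6"), path)
  tab <- read_omics_table(path, layer = "metabolomics")
  expect_equal(dim(tab), c(3L, 2L))
  expect_equal(mean(is.na(tab$values)), 0)
})
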