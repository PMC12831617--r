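test_that("stratified folds deal both classes as evenly as possible", {
  y <- c(rep(1L, 40), rep(0L, 49))
  fold <- omicspanel:::.with_seed(1L, make_stratified_folds(y, 5L))
  for (f in 1:5) {
    expect_equal(sum(y == 1L & fold == f), 8L)
    expect_true(sum(y == 0L & fold == f) %in% c(9L, 10L))
  }
})

test_that("evaluate_panel validates input and is seed-reproducible", {
  co <- tiny_cohort(seed = 51, n_case = 15, n_control = 15,
                    n_informative = 2, effect_size = 2)
  expect_error(evaluate_panel(co$table, co$labels, c("met:nope")), "missing")
  expect_error(evaluate_panel(co$table, co$labels,
                              co$table$feature_ids[1], n_folds = 20), "n_folds")
  ev1 <- evaluate_panel(co$table, co$labels, co$truth$informative_features,
                        seed = 9)
  ev2 <- evaluate_panel(co$table, co$labels, co$truth$informative_features,
                        seed = 9)
  expect_identical(ev1$fold_auc, ev2$fold_auc)
  expect_identical(ev1$oof_scores, ev2$oof_scores)
  # ROC step function spans (0,0) to (1,1)
  expect_equal(ev1$roc_points[1, ], data.frame(fpr = 0, tpr = 0),
               ignore_attr = TRUE)
  expect_equal(unlist(ev1$roc_points[nrow(ev1$roc_points), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(ev1$roc_points$fpr) >= 0))
  expect_true(all(diff(ev1$roc_points$tpr) >= 0))
})

test_that("cross-validated single-feature AUC agrees with the univariate AUC", {
  co <- generate_cohort(synthetic_spec(
    n_case = 1000, n_control = 1000, layer_sizes = c(metabolomics = 2),
    n_informative = 1, effect_size = 1, block_rho = 0, missing_rate = 0,
    seed = 52))
  f <- co$truth$informative_features
  ev <- evaluate_panel(co$table, co$labels, f, seed = 3)
  uni <- feature_auc(co$table$values[, f], co$labels$label)$auc
  expect_lt(abs(ev$auc_mean - uni), 0.03)
})

test_that("permuted labels give chance-level panel AUC", {
  aucs <- vapply(1:10, function(s) {
    co <- tiny_cohort(seed = 800 + s, n_case = 20, n_control = 20,
                      n_informative = 2, effect_size = 2)
    y_perm <- omicspanel:::.with_seed(s, sample(co$labels$label))
    lb <- phenotype_labels(co$labels$sample_ids, y_perm)
    evaluate_panel(co$table, lb, co$truth$informative_features,
                   seed = s)$auc_mean
  }, numeric(1))
  expect_gte(mean(aucs), 0.35)
  expect_lte(mean(aucs), 0.65)
})

test_that("consensus counting matches its definition and input order", {
  a <- c("f1", "f2", "f3", "f4", "f5")
  b <- c("f1", "f6", "f7", "f8", "f9")
  expect_identical(consensus_features(list(a, a))$consensus_set, a)
  expect_identical(consensus_features(list(a, c("x1", "x2", "x3", "x4", "x5")))$consensus_set,
                   character(0))
  c1 <- consensus_features(list(a, b, rev(b)))
  c2 <- consensus_features(list(rev(b), a, b))
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$consensus_set, c2$consensus_set)
  expect_equal(unname(c1$counts["f1"]), 3L)
})

test_that("select-then-evaluate is optimistic relative to leakage-safe CV", {
  diffs <- vapply(1:25, function(s) {
    co <- tiny_cohort(seed = 900 + s, n_case = 15, n_control = 15,
                      layers = c(proteomics = 12, glycomics = 8))
    full <- benchmark_all(co$table, co$labels, methods = "selectkbest",
                          n_select = 3, seed = s)
    safe <- benchmark_all(co$table, co$labels, methods = "selectkbest",
                          n_select = 3, seed = s, leakage_safe = TRUE)
    full$report$auc_mean - safe$report$auc_mean
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})

test_that("the benchmark report has one row per requested method", {
  co <- tiny_cohort(seed = 53, n_case = 15, n_control = 15,
                    n_informative = 1, effect_size = 2)
  rep <- benchmark_all(co$table, co$labels,
                       methods = c("selectkbest", "svmrfe"), n_select = 3,
                       seed = 2)
  expect_equal(nrow(rep$report), 2L)
  expect_identical(rep$report$method, c("selectkbest", "svmrfe"))
  expect_true(all(rep$report$auc_mean >= 0 & rep$report$auc_mean <= 1))
  out <- withr::local_tempdir()
  write_benchmark_report(rep, out)
  expect_setequal(list.files(out),
                  c("report.tsv", "ranking_selectkbest.tsv", "ranking_svmrfe.tsv",
                    "roc_selectkbest.tsv", "roc_svmrfe.tsv", "manifest.json"))
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$seed, 2L)
})
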