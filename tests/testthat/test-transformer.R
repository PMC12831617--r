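test_that("analytic gradients match finite differences", {
  cfg <- transformer_config(d_model = 8, n_heads = 2, n_attention_layers = 2,
                            d_ff = 12, weight_decay = 0, seed = 3)
  set.seed(31)
  n <- 7; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  lidx <- c(1L, 1L, 2L, 3L)
  y <- c(1, 0, 1, 0, 1, 0, 1)
  par <- omicspanel:::.with_seed(5L, omicspanel:::.tf_init(p, 3L, cfg))
  lg <- omicspanel:::.tf_loss_grad(par, X, y, lidx, cfg)
  eps <- 1e-6
  for (nm in names(par)) {
    for (ii in seq_len(min(length(par[[nm]]), 4L))) {
      p1 <- par; p1[[nm]][ii] <- p1[[nm]][ii] + eps
      p2 <- par; p2[[nm]][ii] <- p2[[nm]][ii] - eps
      num <- (omicspanel:::.tf_loss_grad(p1, X, y, lidx, cfg)$loss -
                omicspanel:::.tf_loss_grad(p2, X, y, lidx, cfg)$loss) / (2 * eps)
      expect_equal(lg$grad[[nm]][ii], num, tolerance = 1e-4,
                   label = paste("grad", nm, ii))
    }
  }
})

test_that("the transformer separates an easy cohort and is reproducible", {
  co <- tiny_cohort(seed = 32, n_case = 40, n_control = 49,
                    layers = c(proteomics = 4, glycomics = 3, metabolomics = 3),
                    n_informative = 1, effect_size = 4)
  xy <- std_xy(co)
  cfg <- fast_tf_config(seed = 7, max_epochs = 150)
  m <- fit_transformer(xy$X, xy$y, cfg)
  expect_gte(mean((predict(m, xy$X) > 0.5) == xy$y), 0.95)
  m2 <- fit_transformer(xy$X, xy$y, cfg)
  expect_equal(predict(m, xy$X), predict(m2, xy$X), tolerance = 1e-6)
  expect_error(fit_transformer(xy$X, rep(1, nrow(xy$X)), cfg), "both classes")
  # SHAP puts the dominant mass on the separating feature
  sh <- shap_importance(m, xy$X, n_permutations = 16, seed = 1)
  expect_identical(names(which.max(sh$scores)), co$truth$informative_features)
  expect_equal(unname(rowSums(sh$phi)), predict(m, xy$X) - sh$base,
               tolerance = 1e-10)
})

test_that("label-permuted training yields chance-level held-out AUC", {
  aucs <- vapply(1:6, function(s) {
    co <- tiny_cohort(seed = 700 + s, n_case = 22, n_control = 22,
                      layers = c(proteomics = 4, glycomics = 3, metabolomics = 3),
                      n_informative = 1, effect_size = 3)
    xy <- std_xy(co)
    y_perm <- omicspanel:::.with_seed(s, sample(xy$y))
    tr <- c(1:15, 23:37); te <- setdiff(seq_along(y_perm), tr)
    m <- fit_transformer(xy$X[tr, ], y_perm[tr],
                         fast_tf_config(seed = s, max_epochs = 120))
    feature_auc(predict(m, xy$X[te, ]), y_perm[te])$auc
  }, numeric(1))
  expect_gte(mean(aucs), 0.35)
  expect_lte(mean(aucs), 0.65)
})

test_that("transformer RFE trace eliminates exactly one feature per iteration", {
  co <- tiny_cohort(seed = 33, n_case = 20, n_control = 20,
                    layers = c(proteomics = 3, glycomics = 3, metabolomics = 2),
                    n_informative = 1, effect_size = 3)
  xy <- std_xy(co)
  cfg <- fast_tf_config(seed = 4, max_epochs = 80, early_stop_patience = 20)
  res <- transformer_rfe_rank(xy$X, xy$y, n_select = 3, config = cfg)
  expect_equal(nrow(res$trace), ncol(xy$X) - 3L)
  expect_equal(res$trace$iteration, seq_len(nrow(res$trace)))
  expect_equal(res$trace$n_surviving, seq(ncol(xy$X) - 1L, 3L))
  # strictly nested surviving sets: eliminated features never reappear
  expect_equal(anyDuplicated(res$trace$eliminated_feature), 0L)
  expect_setequal(c(res$ranking$selected[1:3],
                    res$trace$eliminated_feature), colnames(xy$X))
  # no-elimination limit: single-fit Shapley ordering
  full <- transformer_rfe_rank(xy$X, xy$y, n_select = ncol(xy$X), config = cfg)
  expect_equal(nrow(full$trace), 0L)
  cfg1 <- cfg; cfg1$seed <- cfg$seed + 7919L
  m <- fit_transformer(xy$X, xy$y, cfg1)
  sh <- shap_importance(m, xy$X, seed = cfg1$seed + 1L)
  expect_identical(full$ranking$ordered_features,
                   names(sh$scores)[order(-sh$scores, names(sh$scores),
                                          method = "radix")])
})

test_that("the elimination loop reproduces SVM-RFE when driven by SVM weights", {
  co <- tiny_cohort(seed = 34, n_case = 15, n_control = 15)
  xy <- std_xy(co)
  svm_scores <- function(surv, it) {
    list(scores = omicspanel:::.svm_weights2(xy$X[, surv, drop = FALSE],
                                             xy$y, C = 1, iteration = it))
  }
  generic <- omicspanel:::.rfe_generic(colnames(xy$X), svm_scores, n_select = 3L)
  direct <- svm_rfe_rank(xy$X, xy$y, n_select = 3L)
  expect_identical(generic$ordered, direct$ordered_features)
})

test_that("transformer RFE is deterministic end to end", {
  co <- tiny_cohort(seed = 35, n_case = 18, n_control = 18,
                    layers = c(proteomics = 3, glycomics = 2, metabolomics = 2),
                    n_informative = 1, effect_size = 3)
  xy <- std_xy(co)
  cfg <- fast_tf_config(seed = 11, max_epochs = 60, early_stop_patience = 15)
  a <- transformer_rfe_rank(xy$X, xy$y, n_select = 2, config = cfg)
  b <- transformer_rfe_rank(xy$X, xy$y, n_select = 2, config = cfg)
  expect_identical(a$ranking$ordered_features, b$ranking$ordered_features)
  expect_identical(a$trace, b$trace)
})
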