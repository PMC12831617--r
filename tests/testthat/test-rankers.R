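test_that("the F filter equals squared Student t and orders like p", {
  co <- tiny_cohort(seed = 13, n_case = 15, n_control = 12)
  xy <- std_xy(co)
  rk <- select_kbest_rank(xy$X, xy$y, k = ncol(xy$X))
  for (j in colnames(xy$X)) {
    tt <- student_t(xy$X[, j], xy$y)
    expect_equal(unname(rk$scores[j]), tt$t^2, tolerance = 1e-9)
  }
  scr <- univariate_screen(suppressWarnings(impute_and_standardize(co$table)),
                           co$labels)
  expect_identical(rk$ordered_features,
                   scr$feature_id[order(scr$p, scr$feature_id)])
  # worked example: (1,2,3) vs (2,3,4) -> F = 1.5
  X1 <- cbind(`met:f` = c(1, 2, 3, 2, 3, 4))
  r1 <- select_kbest_rank(X1, c(1, 1, 1, 0, 0, 0), k = 1)
  expect_equal(unname(r1$scores), 1.5, tolerance = 1e-9)
})

test_that("elastic net shrinks fully, recovers signal, and groups duplicates", {
  co <- tiny_cohort(seed = 14, n_case = 40, n_control = 49,
                    layers = c(proteomics = 20, glycomics = 15, metabolomics = 15),
                    n_informative = 1, effect_size = 3)
  xy <- std_xy(co)
  expect_warning(
    elastic_net_rank(xy$X, xy$y,
                     config = elastic_net_config(lambda_grid = c(1e6, 2e6))),
    "all elastic-net coefficients are zero")
  rk <- elastic_net_rank(xy$X, xy$y, k = 5)
  expect_true(co$truth$informative_features %in% rk$selected)
  # grouping effect: duplicated informative column gets a similar coefficient
  f <- co$truth$informative_features
  Xd <- cbind(xy$X, `met:dup` = xy$X[, f])
  rd <- elastic_net_rank(Xd, xy$y, k = 5)
  cf <- abs(rd$raw_scores[c(f, "met:dup")])
  expect_true(all(cf > 0))
  expect_lt(abs(cf[1] - cf[2]) / max(cf), 0.2)
})

test_that("SVM-RFE eliminates one feature per step down to n_select", {
  co <- tiny_cohort(seed = 15, n_case = 20, n_control = 20,
                    layers = c(proteomics = 10, glycomics = 10, metabolomics = 10))
  xy <- std_xy(co)
  rk <- svm_rfe_rank(xy$X, xy$y, n_select = 5)
  expect_length(rk$ordered_features, 30L)
  expect_length(rk$selected, 5L)
  expect_setequal(rk$ordered_features, colnames(xy$X))
  # no-elimination limit: a single fit ranked by squared weights
  full <- svm_rfe_rank(xy$X, xy$y, n_select = ncol(xy$X))
  w2 <- omicspanel:::.svm_weights2(xy$X, xy$y, C = 1, iteration = 1L)
  expect_identical(full$ordered_features,
                   names(w2)[order(-w2, names(w2), method = "radix")])
  # determinism
  expect_identical(svm_rfe_rank(xy$X, xy$y, n_select = 5)$ordered_features,
                   rk$ordered_features)
})

test_that("rankings are invariant to feature column order", {
  co <- tiny_cohort(seed = 16, n_case = 15, n_control = 15,
                    n_informative = 1, effect_size = 2)
  xy <- std_xy(co)
  set.seed(99)
  perm <- sample(ncol(xy$X))
  Xp <- xy$X[, perm]
  expect_identical(select_kbest_rank(xy$X, xy$y, 3)$ordered_features,
                   select_kbest_rank(Xp, xy$y, 3)$ordered_features)
  expect_identical(svm_rfe_rank(xy$X, xy$y, 3)$ordered_features,
                   svm_rfe_rank(Xp, xy$y, 3)$ordered_features)
})

test_that("random forest SHAP importance separates signal from the null scale", {
  layers <- c(proteomics = 20, glycomics = 15, metabolomics = 15)
  planted <- vapply(1:5, function(s) {
    co <- tiny_cohort(seed = 500 + s, n_case = 40, n_control = 49,
                      layers = layers, n_informative = 1, effect_size = 3,
                      block_rho = 0)
    xy <- std_xy(co)
    rk <- rf_rank(xy$X, xy$y, k = 5, config = rf_config(n_trees = 300, seed = s))
    expect_true(co$truth$informative_features %in% rk$selected)
    rk$scores[[co$truth$informative_features]]
  }, numeric(1))
  null_max <- vapply(1:5, function(s) {
    co <- tiny_cohort(seed = 600 + s, n_case = 40, n_control = 49,
                      layers = layers, block_rho = 0)
    xy <- std_xy(co)
    max(rf_rank(xy$X, xy$y, k = 5,
                config = rf_config(n_trees = 300, seed = s))$scores)
  }, numeric(1))
  # a d = 3 effect dominates the largest importance pure noise ever reaches
  expect_gt(mean(planted), 2 * mean(null_max))
})

test_that("TreeSHAP satisfies exact local accuracy on the forest probability", {
  co <- tiny_cohort(seed = 17, n_case = 20, n_control = 20,
                    n_informative = 1, effect_size = 2)
  xy <- std_xy(co)
  fit <- omicspanel:::.with_seed(3L, randomForest::randomForest(
    x = xy$X, y = factor(xy$y, levels = c(0L, 1L)), ntree = 150,
    keep.inbag = TRUE, keep.forest = TRUE))
  shap <- rf_shap(fit, xy$X)
  prob <- predict(fit, xy$X, type = "prob")[, "1"]
  expect_equal(unname(shap$base + rowSums(shap$phi)), unname(prob),
               tolerance = 1e-6)
})

test_that("TreeSHAP matches brute-force Shapley on a hand-built tree", {
  # split f1 at 0; left child splits f2 at 0 (leaves 1, 2); right leaf 3
  tree <- list(left = c(1L, 3L, -1L, -1L, -1L), right = c(2L, 4L, -1L, -1L, -1L),
               var = c(0L, 1L, -1L, -1L, -1L), thr = rep(0, 5),
               value = c(0, 0, 3, 1, 2), weight = rep(1, 40))
  set.seed(18)
  Xtr <- matrix(rnorm(120), 40, 3)
  x <- c(-0.3, 0.4, 1.2)
  res <- omicspanel:::treeshap_forest_cpp(list(tree), matrix(x, 1, 3), Xtr)

  expv_tree <- function(M) {  # prediction function over a matrix, for the oracle
    apply(M, 1L, function(z) {
      node <- 0L
      repeat {
        if (tree$var[node + 1L] < 0L) return(tree$value[node + 1L])
        node <- if (z[tree$var[node + 1L] + 1L] <= tree$thr[node + 1L])
          tree$left[node + 1L] else tree$right[node + 1L]
      }
    })
  }
  # brute-force Shapley of the cover-weighted expectation game
  expv <- function(S) {
    walk <- function(node) {
      if (tree$var[node + 1L] < 0L) return(tree$value[node + 1L])
      d <- tree$var[node + 1L]
      if (d %in% S) {
        nxt <- if (x[d + 1L] <= tree$thr[node + 1L]) tree$left[node + 1L]
               else tree$right[node + 1L]
        return(walk(nxt))
      }
      cov <- function(nd) sum(apply(Xtr, 1L, function(z) {
        node2 <- 0L
        repeat {
          if (node2 == nd) return(TRUE)
          if (tree$var[node2 + 1L] < 0L) return(FALSE)
          node2 <- if (z[tree$var[node2 + 1L] + 1L] <= tree$thr[node2 + 1L])
            tree$left[node2 + 1L] else tree$right[node2 + 1L]
        }
      }))
      l <- tree$left[node + 1L]; r <- tree$right[node + 1L]
      (cov(l) * walk(l) + cov(r) * walk(r)) / cov(node)
    }
    walk(0L)
  }
  phi <- numeric(3)
  for (j in 1:3) {
    others <- setdiff(1:3, j)
    for (k in 0:2) {
      subs <- if (k == 0) list(integer(0)) else utils::combn(others, k, simplify = FALSE)
      for (S in subs) {
        w <- factorial(length(S)) * factorial(3 - length(S) - 1) / factorial(3)
        phi[j] <- phi[j] + w * (expv(c(S - 1L, j - 1L)) - expv(S - 1L))
      }
    }
  }
  expect_equal(as.numeric(res$phi), phi, tolerance = 1e-10)
  expect_equal(res$base, expv(integer(0)), tolerance = 1e-10)
  expect_equal(res$base + sum(res$phi), expv_tree(matrix(x, 1, 3)),
               tolerance = 1e-10)
})
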