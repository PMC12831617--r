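#' Univariate F-filter ranking (top-K-best)
#'
#' Ranks features by the one-way ANOVA F statistic between the two classes.
#' For two groups F equals the square of the pooled-variance Student t, so
#' this ordering coincides with ascending t-test p-values. Constant features
#' get F = 0 and sink to the bottom; ties break lexicographically.
#'
#' @param X standardized numeric matrix (samples x features) with feature
#'   ids as column names.
#' @param y 0/1 labels or [phenotype_labels].
#' @param k number of features to flag as selected.
#' @return A [feature_ranking] with F statistics as scores.
#' @export
select_kbest_rank <- function(X, y, k = 5L) {
  y <- if (inherits(y, "phenotype_labels")) y$label else as.integer(y)
  feats <- colnames(X)
  Fstat <- vapply(seq_len(ncol(X)), function(j) {
    tt <- student_t(X[, j], y)
    if (is.infinite(tt$t)) Inf else tt$t^2
  }, numeric(1))
  ord <- .order_by_score(feats, Fstat)
  feature_ranking("selectkbest", feats[ord], Fstat[ord], n_select = k)
}

#' Elastic net configuration
#'
#' @param l1_ratio mix between the L1 (lasso) and L2 (ridge) penalties,
#'   in `[0, 1]`; 0.5 by default.
#' @param cv_folds_for_alpha internal cross-validation folds used to choose
#'   the overall penalty weight from `lambda_grid`.
#' @param lambda_grid fixed logarithmic grid of candidate penalty weights.
#' @param seed seed for the internal CV fold assignment.
#' @return An `elastic_net_config` list.
#' @export
elastic_net_config <- function(l1_ratio = 0.5, cv_folds_for_alpha = 5L,
                               lambda_grid = 10^seq(0.5, -4, length.out = 60),
                               seed = 1L) {
  stopifnot(l1_ratio >= 0, l1_ratio <= 1, cv_folds_for_alpha >= 2L,
            all(lambda_grid > 0))
  list(l1_ratio = l1_ratio, cv_folds_for_alpha = as.integer(cv_folds_for_alpha),
       lambda_grid = sort(lambda_grid, decreasing = TRUE), seed = as.integer(seed))
}

#' Elastic-net coefficient ranking
#'
#' Fits the penalized linear-regression objective (0/1 labels as the
#' response) at a penalty weight chosen by seeded internal cross-validation
#' over a fixed logarithmic grid, then ranks features by absolute
#' coefficient. Zero-coefficient features are appended after all nonzero
#' ones in input column order.
#'
#' @inheritParams select_kbest_rank
#' @param config an [elastic_net_config()].
#' @return A [feature_ranking]; `raw_scores` holds the signed coefficients.
#' @export
elastic_net_rank <- function(X, y, k = 5L, config = elastic_net_config()) {
  y <- if (inherits(y, "phenotype_labels")) y$label else as.integer(y)
  feats <- colnames(X)
  foldid <- .with_seed(config$seed,
                       make_stratified_folds(y, config$cv_folds_for_alpha))
  cv <- glmnet::cv.glmnet(X, as.numeric(y), family = "gaussian",
                          alpha = config$l1_ratio, lambda = config$lambda_grid,
                          foldid = foldid, standardize = FALSE)
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1L]
  if (all(beta == 0)) {
    warning("all elastic-net coefficients are zero; ranking degenerates to input order")
    return(feature_ranking("elasticnet", feats, rep(0, length(feats)),
                           n_select = k, raw_scores = beta))
  }
  nz <- which(beta != 0)
  zo <- which(beta == 0)
  ord <- c(nz[.order_by_score(feats[nz], abs(beta[nz]))], zo)
  feature_ranking("elasticnet", feats[ord], abs(beta)[ord], n_select = k,
                  raw_scores = beta[ord])
}

#' SVM-RFE configuration
#'
#' @param C soft-margin penalty of the linear support vector machine.
#' @param step features eliminated per iteration (default 1).
#' @return An `svm_rfe_config` list.
#' @export
svm_rfe_config <- function(C = 1, step = 1L) {
  stopifnot(C > 0, step >= 1L)
  list(C = C, step = as.integer(step))
}

# Linear-SVM squared weights per feature; deterministic given the data.
.svm_weights2 <- function(X, y, C, iteration) {
  fit <- tryCatch(
    e1071::svm(X, factor(y, levels = c(0L, 1L)), kernel = "linear",
               cost = C, scale = FALSE),
    error = function(e) stop(sprintf("SVM training failed at iteration %d: %s",
                                     iteration, conditionMessage(e))))
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  stats::setNames(w^2, colnames(X))
}

#' Recursive feature elimination with a linear SVM
#'
#' Trains a soft-margin linear SVM, scores each feature by the square of its
#' weight-vector component, removes the `step` lowest-scoring features, and
#' repeats on the surviving set until `n_select` features remain. The
#' reversed elimination order defines the full ranking; survivors are
#' ordered by their squared weights in the final fit.
#'
#' @inheritParams select_kbest_rank
#' @param n_select number of features to retain.
#' @param config an [svm_rfe_config()].
#' @return A [feature_ranking]; `raw_scores` holds each feature's squared
#'   weight frozen at its elimination (survivors: final-fit value).
#' @export
svm_rfe_rank <- function(X, y, n_select = 5L, config = svm_rfe_config()) {
  y <- if (inherits(y, "phenotype_labels")) y$label else as.integer(y)
  stopifnot(n_select >= 1L, n_select <= ncol(X))
  rfe <- .rfe_generic(colnames(X), function(surv, it) {
    list(scores = .svm_weights2(X[, surv, drop = FALSE], y, config$C, it))
  }, n_select = n_select, step = config$step)
  feature_ranking("svmrfe", rfe$ordered, rfe$scores, n_select = n_select,
                  raw_scores = rfe$raw_scores)
}

#' Random forest configuration
#'
#' @param n_trees trees in the forest (default 500).
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @param importance_mode `"shap"` (mean absolute TreeSHAP attribution of
#'   the predicted case probability, the default) or `"impurity"` (mean
#'   decrease in Gini impurity).
#' @param seed seed controlling bootstrap resampling and split sampling.
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_trees = 500L, mtry = NULL,
                      importance_mode = c("shap", "impurity"), seed = 1L) {
  stopifnot(n_trees >= 1L)
  list(n_trees = as.integer(n_trees), mtry = mtry,
       importance_mode = match.arg(importance_mode), seed = as.integer(seed))
}

#' Random-forest feature ranking
#'
#' Fits a classification random forest (bootstrap-resampled trees, random
#' feature subset at each split) and ranks features either by exact
#' path-dependent TreeSHAP attributions of the predicted case probability
#' (mean absolute value over the training samples) or by Gini importance.
#'
#' @inheritParams select_kbest_rank
#' @param config an [rf_config()].
#' @return A [feature_ranking].
#' @export
rf_rank <- function(X, y, k = 5L, config = rf_config()) {
  y <- if (inherits(y, "phenotype_labels")) y$label else as.integer(y)
  feats <- colnames(X)
  fit <- .with_seed(config$seed, randomForest::randomForest(
    x = X, y = factor(y, levels = c(0L, 1L)),
    ntree = config$n_trees,
    mtry = if (is.null(config$mtry)) max(1L, floor(sqrt(ncol(X)))) else config$mtry,
    importance = TRUE, keep.inbag = TRUE, keep.forest = TRUE))
  if (config$importance_mode == "impurity") {
    sc <- fit$importance[, "MeanDecreaseGini"]
  } else {
    shap <- rf_shap(fit, X)
    sc <- colMeans(abs(shap$phi))
  }
  ord <- .order_by_score(feats, sc)
  feature_ranking("rf", feats[ord], sc[ord], n_select = k)
}

#' Exact TreeSHAP attributions for a random forest
#'
#' Path-dependent TreeSHAP over every tree of a fitted
#' \code{\link[randomForest]{randomForest}} classifier, attributing the
#' predicted case probability (fraction of tree votes for the case class)
#' to the input features. Node covers are reconstructed by routing each
#' tree's in-bag training samples down the tree, so attributions satisfy
#' exact local accuracy: for every sample, `base + sum(phi)` equals the
#' forest's predicted probability.
#'
#' @param fit a `randomForest` classification fit with `keep.forest = TRUE`
#'   and (ideally) `keep.inbag = TRUE`; two classes, case class last.
#' @param X matrix of samples to explain (the training matrix for ranking).
#' @param X_train training matrix used to rebuild node covers; defaults to
#'   `X`.
#' @return List with `phi` (samples x features attribution matrix) and
#'   `base` (expected predicted probability).
#' @export
rf_shap <- function(fit, X, X_train = X) {
  stopifnot(inherits(fit, "randomForest"), fit$type == "classification",
            length(fit$classes) == 2L)
  ntree <- fit$ntree
  inbag <- fit$inbag  # samples x trees counts, NULL unless keep.inbag
  trees <- vector("list", ntree)
  for (kk in seq_len(ntree)) {
    tr <- randomForest::getTree(fit, kk, labelVar = FALSE)
    leaf <- tr[, "status"] == -1L
    w <- if (is.null(inbag)) rep(1, nrow(X_train)) else as.numeric(inbag[, kk])
    trees[[kk]] <- list(
      left = as.integer(tr[, "left daughter"]) - 1L,    # 0-based, -1 for leaf
      right = as.integer(tr[, "right daughter"]) - 1L,
      var = ifelse(leaf, -1L, as.integer(tr[, "split var"]) - 1L),
      thr = as.numeric(tr[, "split point"]),
      value = ifelse(leaf & tr[, "prediction"] == 2L, 1.0, 0.0),
      weight = w
    )
  }
  res <- treeshap_forest_cpp(trees, X, X_train)
  phi <- res$phi
  dimnames(phi) <- dimnames(X)
  list(phi = phi, base = res$base)
}
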