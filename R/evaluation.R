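#' Stratified fold assignment
#'
#' Samples are shuffled within each class and dealt round-robin, so fold
#' sizes per class differ by at most one. Called inside [.with_seed()] by
#' consumers; on its own it uses the current RNG stream.
#'
#' @param y 0/1 labels.
#' @param n_folds folds.
#' @return Integer fold id per sample.
#' @export
make_stratified_folds <- function(y, n_folds = 5L) {
  y <- as.integer(y)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Evaluate a feature panel by cross-validated logistic regression
#'
#' Stratified k-fold cross-validation of an L2-regularized logistic
#' regression on the given panel. Within each fold, imputation and
#' standardization statistics are fit on the training rows only and applied
#' to the held-out rows; accuracy uses the 0.5 probability threshold and
#' AUC is the Mann-Whitney statistic of the held-out scores. Fold means and
#' standard deviations are reported; pooled out-of-fold scores define the
#' ROC points.
#'
#' @param table an [omics_table] on the original intensity scale.
#' @param labels a [phenotype_labels].
#' @param panel feature ids to evaluate jointly.
#' @param n_folds folds (default 5); each class must have at least
#'   `n_folds` samples.
#' @param seed seed for the fold assignment.
#' @param C inverse regularization strength of the logistic model; the
#'   ridge penalty weight is `1 / (C * n_train)`.
#' @return A `panel_evaluation` with accuracy/AUC means and sds, per-fold
#'   values and pooled ROC points.
#' @export
evaluate_panel <- function(table, labels, panel, n_folds = 5L, seed = 1L,
                           C = 1) {
  stopifnot(inherits(table, "omics_table"))
  labels <- align_labels(labels, table)
  y <- labels$label
  missing <- setdiff(panel, table$feature_ids)
  if (length(missing)) {
    stop("panel feature(s) missing from table: ", paste(missing, collapse = ", "))
  }
  if (min(table(y)) < n_folds) stop("each class needs at least n_folds samples")
  sub <- omics_table(table$values[, panel, drop = FALSE],
                     sample_ids = table$sample_ids, feature_ids = panel,
                     missing_ceiling = 1)
  fold <- .with_seed(seed, make_stratified_folds(y, n_folds))
  acc <- auc <- numeric(n_folds)
  oof <- numeric(length(y))
  for (f in seq_len(n_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    Z <- impute_and_standardize(sub, fit_rows = tr)$values
    sc <- .fit_predict_logistic(Z[tr, , drop = FALSE], y[tr],
                                Z[te, , drop = FALSE], C = C)
    acc[f] <- mean((sc > 0.5) == y[te])
    auc[f] <- feature_auc(sc, y[te])$auc
    oof[te] <- sc
  }
  roc <- pROC::roc(response = y, predictor = oof, quiet = TRUE,
                   direction = "<", levels = c(0L, 1L))
  pts <- data.frame(fpr = 1 - roc$specificities, tpr = roc$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  rownames(pts) <- NULL
  structure(list(panel = panel,
                 accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
                 auc_mean = mean(auc), auc_sd = stats::sd(auc),
                 fold_accuracy = acc, fold_auc = auc,
                 roc_points = pts, oof_scores = oof,
                 n_folds = n_folds, seed = seed),
            class = "panel_evaluation")
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat(sprintf("panel_evaluation (%d features, %d-fold CV):\n",
              length(x$panel), x$n_folds))
  cat(sprintf("  accuracy %.3f +/- %.3f, AUC %.3f +/- %.3f\n",
              x$accuracy_mean, x$accuracy_sd, x$auc_mean, x$auc_sd))
  invisible(x)
}

# Ridge logistic regression via glmnet; a zero dummy column works around
# glmnet's two-column minimum for single-feature panels.
.fit_predict_logistic <- function(Xtr, ytr, Xte, C = 1) {
  pad <- ncol(Xtr) < 2L
  if (pad) {
    Xtr <- cbind(Xtr, `.dummy` = 0)
    Xte <- cbind(Xte, `.dummy` = 0)
  }
  fit <- glmnet::glmnet(Xtr, factor(ytr, levels = c(0L, 1L)),
                        family = "binomial", alpha = 0,
                        lambda = 1 / (C * nrow(Xtr)), standardize = FALSE)
  as.numeric(stats::predict(fit, Xte, type = "response"))
}

#' Cross-method consensus features
#'
#' Counts how often each feature appears among the top-`top_n` lists of the
#' supplied rankings; the consensus set is every feature selected by more
#' than one method.
#'
#' @param rankings list of [feature_ranking] objects and/or plain character
#'   vectors of ranked feature ids.
#' @param top_n list depth considered per method (default 5).
#' @return List with `counts` (named, decreasing) and `consensus_set`
#'   (features with count >= 2, ordered by count then name).
#' @export
consensus_features <- function(rankings, top_n = 5L) {
  stopifnot(length(rankings) >= 2L)
  tops <- lapply(rankings, function(r) {
    ids <- if (inherits(r, "feature_ranking")) r$ordered_features else as.character(r)
    utils::head(ids, top_n)
  })
  cnt <- table(unlist(tops, use.names = FALSE))
  cnt <- cnt[order(-cnt, names(cnt), method = "radix")]
  counts <- stats::setNames(as.integer(cnt), names(cnt))
  list(counts = counts, consensus_set = names(counts)[counts >= 2L])
}

# ---- method registry -------------------------------------------------------

.ranker_methods <- c("selectkbest", "elasticnet", "svmrfe", "rf",
                     "transformer_rfe", "mogonet_lite")

#' Rank multi-omics features by a named method
#'
#' Uniform front end over the six ranking methods. `X` must be the
#' standardized combined matrix with layer-prefixed column names.
#'
#' @param X standardized matrix (samples x features).
#' @param y 0/1 labels or [phenotype_labels].
#' @param method one of `"selectkbest"`, `"elasticnet"`, `"svmrfe"`,
#'   `"rf"`, `"transformer_rfe"`, `"mogonet_lite"`.
#' @param n_select panel size to flag as selected.
#' @param config optional method config ([elastic_net_config()],
#'   [svm_rfe_config()], [rf_config()], [transformer_config()],
#'   [graph_fusion_config()]).
#' @return A [feature_ranking].
#' @export
rank_features <- function(X, y, method = .ranker_methods, n_select = 5L,
                          config = NULL) {
  method <- match.arg(method)
  switch(method,
    selectkbest = select_kbest_rank(X, y, k = n_select),
    elasticnet = elastic_net_rank(X, y, k = n_select,
                                  config = config %||% elastic_net_config()),
    svmrfe = svm_rfe_rank(X, y, n_select = n_select,
                          config = config %||% svm_rfe_config()),
    rf = rf_rank(X, y, k = n_select, config = config %||% rf_config()),
    transformer_rfe = transformer_rfe_rank(
      X, y, n_select = n_select,
      config = config %||% transformer_config())$ranking,
    mogonet_lite = {
      cfg <- config %||% graph_fusion_config()
      Xl <- .split_by_layer(X)
      cfg$knn_k <- min(cfg$knn_k, nrow(X) - 1L)
      model <- mogonet_lite_fit(Xl, y, config = cfg)
      mogonet_lite_rank(model, k = n_select)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.split_by_layer <- function(X) {
  lys <- layer_of(colnames(X))
  present <- omics_layers()[omics_layers() %in% lys]
  stats::setNames(lapply(present, function(ly) X[, lys == ly, drop = FALSE]),
                  present)
}

#' Benchmark ranking methods as cross-validated panels
#'
#' For each method, ranks features and evaluates its top-`n_select` panel
#' with [evaluate_panel()]. The default protocol selects the panel on the
#' full data set before cross-validation (select-then-evaluate), matching
#' the common practice this workflow models; it is optimistic because the
#' held-out folds already influenced the selection. `leakage_safe = TRUE`
#' instead re-runs selection inside each training fold and evaluates the
#' fold-specific panel on that fold's held-out rows.
#'
#' @param table an [omics_table] on the intensity scale.
#' @param labels a [phenotype_labels].
#' @param methods methods to run (see [rank_features()]).
#' @param n_select panel size (default 5).
#' @param n_folds CV folds (default 5).
#' @param seed seed for fold assignment and seeded methods.
#' @param configs optional named list of per-method configs.
#' @param leakage_safe re-select inside each training fold.
#' @return A `benchmark_report`: `report` data.frame (method, panel,
#'   accuracy/AUC mean and sd), `rankings` and `evaluations` lists.
#' @export
benchmark_all <- function(table, labels, methods = .ranker_methods,
                          n_select = 5L, n_folds = 5L, seed = 1L,
                          configs = list(), leakage_safe = FALSE) {
  stopifnot(inherits(table, "omics_table"))
  labels <- align_labels(labels, table)
  y <- labels$label
  methods <- match.arg(methods, .ranker_methods, several.ok = TRUE)
  rankings <- list(); evals <- list(); rows <- list()
  for (m in methods) {
    cfg <- configs[[m]]
    if (!leakage_safe) {
      Z <- impute_and_standardize(table)$values
      rk <- rank_features(Z, y, method = m, n_select = n_select, config = cfg)
      ev <- evaluate_panel(table, labels, rk$selected, n_folds = n_folds,
                           seed = seed)
      rankings[[m]] <- rk; evals[[m]] <- ev
      rows[[m]] <- data.frame(
        method = m, panel = paste(rk$selected, collapse = ";"),
        accuracy_mean = ev$accuracy_mean, accuracy_sd = ev$accuracy_sd,
        auc_mean = ev$auc_mean, auc_sd = ev$auc_sd, stringsAsFactors = FALSE)
    } else {
      fold <- .with_seed(seed, make_stratified_folds(y, n_folds))
      acc <- auc <- numeric(n_folds)
      panels <- vector("list", n_folds)
      for (f in seq_len(n_folds)) {
        tr <- which(fold != f); te <- which(fold == f)
        Z <- impute_and_standardize(table, fit_rows = tr)$values
        rk <- rank_features(Z[tr, , drop = FALSE], y[tr], method = m,
                            n_select = n_select, config = cfg)
        panels[[f]] <- rk$selected
        sc <- .fit_predict_logistic(Z[tr, rk$selected, drop = FALSE], y[tr],
                                    Z[te, rk$selected, drop = FALSE])
        acc[f] <- mean((sc > 0.5) == y[te])
        auc[f] <- feature_auc(sc, y[te])$auc
      }
      evals[[m]] <- list(fold_accuracy = acc, fold_auc = auc, panels = panels)
      rows[[m]] <- data.frame(
        method = m, panel = paste(unique(unlist(panels)), collapse = ";"),
        accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
        auc_mean = mean(auc), auc_sd = stats::sd(auc), stringsAsFactors = FALSE)
    }
  }
  structure(list(report = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 rankings = rankings, evaluations = evals,
                 n_select = n_select, n_folds = n_folds, seed = seed,
                 leakage_safe = leakage_safe),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("benchmark_report (%s protocol, %d-fold CV, top %d):\n",
              if (x$leakage_safe) "leakage-safe" else "select-then-evaluate",
              x$n_folds, x$n_select))
  print(x$report[, c("method", "accuracy_mean", "accuracy_sd",
                     "auc_mean", "auc_sd")], row.names = FALSE)
  invisible(x)
}

#' Write a benchmark report to disk
#'
#' Emits the report table and per-method rankings as delimited text, ROC
#' point files for select-then-evaluate runs, and a JSON run manifest
#' recording the seed, fold count, panel size and protocol.
#'
#' @param x a [benchmark_all()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_benchmark_report <- function(x, dir) {
  stopifnot(inherits(x, "benchmark_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x$report, file.path(dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (m in names(x$rankings)) {
    write_ranking(x$rankings[[m]], file.path(dir, paste0("ranking_", m, ".tsv")))
  }
  for (m in names(x$evaluations)) {
    ev <- x$evaluations[[m]]
    if (inherits(ev, "panel_evaluation")) {
      utils::write.table(ev$roc_points, file.path(dir, paste0("roc_", m, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  manifest <- list(seed = x$seed, n_folds = x$n_folds, n_select = x$n_select,
                   leakage_safe = x$leakage_safe, methods = names(x$evaluations))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

# ---- shipped reference inputs ---------------------------------------------

#' Reported top-five panels of the seven ranking methods
#'
#' The method-wise top-five multi-omics feature lists reported by the
#' targeted HCC-versus-cirrhosis study this workflow models (UniProt
#' accessions, N-glycan composition codes, metabolite names). Shipped as a
#' package data file; the usual input to [consensus_features()].
#'
#' @return Named list of character vectors, one per method, most important
#'   feature first.
#' @export
reported_top5_panels <- function() {
  path <- system.file("extdata", "hcc_reported_top5_panels.tsv",
                      package = "omicspanel", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  df <- df[order(match(df$method, unique(df$method)), df$rank), ]
  split(df$feature_id, factor(df$method, levels = unique(df$method)))
}

#' Reported cohort-characteristic 2x2 tables
#'
#' Case/control positive and negative counts for the categorical cohort
#' characteristics of the HCC-versus-cirrhosis study (reconstructed from
#' the reported percentages), with the reported two-sided p-values, for use
#' with [fisher_exact_2x2()].
#'
#' @return data.frame with one 2x2 table per row.
#' @export
reported_cohort_2x2 <- function() {
  path <- system.file("extdata", "hcc_cohort_2x2.tsv",
                      package = "omicspanel", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
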