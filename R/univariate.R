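#' Pooled-variance (Student) two-sample t test for one feature
#'
#' Classical equal-variance two-sided t test comparing cases against
#' controls, as used for per-omics significance screening. Degenerate inputs
#' with zero pooled variance are handled explicitly: equal means give
#' p = 1, separated means give p = 0, both flagged.
#'
#' @param values numeric vector, one value per sample.
#' @param labels a [phenotype_labels] or a 0/1 vector aligned to `values`.
#' @return List with `t`, `p`, `df` and logical `degenerate`.
#' @export
student_t <- function(values, labels) {
  y <- if (inherits(labels, "phenotype_labels")) labels$label else as.integer(labels)
  stopifnot(length(values) == length(y))
  ok <- is.finite(values)
  if (!all(ok)) stop("non-finite values passed to student_t")
  x1 <- values[y == 1L]; x0 <- values[y == 0L]
  if (length(x1) < 2L || length(x0) < 2L) {
    stop("each class needs at least 2 samples")
  }
  df <- length(x1) + length(x0) - 2L
  pooled <- ((length(x1) - 1) * stats::var(x1) + (length(x0) - 1) * stats::var(x0)) / df
  if (pooled <= .Machine$double.eps * max(abs(c(x1, x0)), 1)^2) {
    eq <- isTRUE(all.equal(mean(x1), mean(x0)))
    return(list(t = if (eq) 0 else sign(mean(x1) - mean(x0)) * Inf,
                p = if (eq) 1 else 0, df = df, degenerate = TRUE))
  }
  res <- stats::t.test(x1, x0, var.equal = TRUE)
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter), degenerate = FALSE)
}

#' Per-feature t tests across a whole table
#'
#' @param table an [omics_table] (missing cells are dropped per feature
#'   pairwise; upstream imputation is recommended).
#' @param labels a [phenotype_labels] aligned to the table.
#' @return data.frame with feature_id, layer, t, p, df, auc.
#' @export
univariate_screen <- function(table, labels) {
  stopifnot(inherits(table, "omics_table"))
  labels <- align_labels(labels, table)
  y <- labels$label
  res <- lapply(seq_along(table$feature_ids), function(j) {
    v <- table$values[, j]
    keep <- !is.na(v)
    tt <- student_t(v[keep], y[keep])
    c(t = tt$t, p = tt$p, df = tt$df,
      auc = feature_auc(v[keep], y[keep])$auc)
  })
  res <- do.call(rbind, res)
  data.frame(feature_id = table$feature_ids,
             layer = layer_of(table$feature_ids),
             t = res[, "t"], p = res[, "p"], df = res[, "df"],
             auc = res[, "auc"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Univariate ROC AUC of a single feature
#'
#' The feature value is treated directly as a classification score for the
#' case class; the AUC is the Mann-Whitney statistic U/(n1 n2) with ties
#' counted one half. Orientation is kept raw: features lower in cases give
#' AUC below 0.5.
#'
#' @inheritParams student_t
#' @return List with `auc` and `direction` (`"up"` if cases score higher).
#' @export
feature_auc <- function(values, labels) {
  y <- if (inherits(labels, "phenotype_labels")) labels$label else as.integer(labels)
  stopifnot(length(values) == length(y))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(values)  # mid-ranks handle ties as 1/2
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(auc = auc, direction = if (auc >= 0.5) "up" else "down")
}

#' Count significant features per omics layer
#'
#' Number of features per layer with raw Student-t p at or below `alpha`
#' (no multiple-testing adjustment, matching the targeted-panel screening
#' convention).
#'
#' @param table an [omics_table].
#' @param labels a [phenotype_labels].
#' @param alpha significance threshold (default 0.05).
#' @return Named integer vector over layers present in the table.
#' @export
significant_count <- function(table, labels, alpha = 0.05) {
  scr <- univariate_screen(table, labels)
  lys <- omics_layers()[omics_layers() %in% unique(scr$layer)]
  vapply(lys, function(ly) sum(scr$p[scr$layer == ly] <= alpha), integer(1))
}

#' Top-k features within each omics layer by t-test p-value
#'
#' Features are ordered by ascending p; ties are broken by descending |t|
#' and then lexicographically by feature id, so the ordering is
#' deterministic.
#'
#' @param table an [omics_table].
#' @param labels a [phenotype_labels].
#' @param k features to select per layer.
#' @return Named list of [feature_ranking] objects, one per layer.
#' @export
top_k_per_omics <- function(table, labels, k = 5L) {
  scr <- univariate_screen(table, labels)
  lys <- omics_layers()[omics_layers() %in% unique(scr$layer)]
  out <- lapply(lys, function(ly) {
    sub <- scr[scr$layer == ly, ]
    if (k > nrow(sub)) stop("k exceeds layer size for ", ly)
    ord <- order(sub$p, -abs(sub$t), sub$feature_id, method = "radix")
    sub <- sub[ord, ]
    feature_ranking(paste0("ttest_", ly), sub$feature_id, -sub$p, n_select = k,
                    raw_scores = sub$p)
  })
  stats::setNames(out, lys)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value defined by the point-probability rule: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the probability of the observed table. Used for
#' categorical cohort-characteristics comparisons.
#'
#' @param counts 2x2 matrix (or length-4 vector, column-major) of
#'   non-negative integer counts.
#' @return Two-sided exact p-value.
#' @export
fisher_exact_2x2 <- function(counts) {
  m <- matrix(as.numeric(counts), 2L, 2L)
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  if (sum(m) < 1) stop("at least one observation required")
  stats::fisher.test(m)$p.value
}
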