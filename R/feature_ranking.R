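#' Construct a feature ranking
#'
#' The common output contract of every ranking method: features ordered from
#' most to least important with a non-increasing score vector and the
#' selected top subset flagged. For recursive-elimination methods the score
#' is a monotone ranking score (survivors keep their final-fit importance,
#' shifted above all eliminated features; eliminated features get minus their
#' elimination index); the raw importance at elimination time, which need not
#' be monotone, is preserved in `raw_scores`.
#'
#' @param method method identifier string.
#' @param ordered_features feature ids, most important first.
#' @param scores numeric, same length, non-increasing along the order.
#' @param n_select size of the selected subset.
#' @param raw_scores optional method-scale scores aligned to
#'   `ordered_features` (not necessarily monotone).
#' @return An object of class `feature_ranking`.
#' @export
feature_ranking <- function(method, ordered_features, scores,
                            n_select = length(ordered_features),
                            raw_scores = NULL) {
  ordered_features <- as.character(ordered_features)
  scores <- as.numeric(scores)
  stopifnot(length(ordered_features) == length(scores),
            !anyDuplicated(ordered_features),
            n_select >= 1L, n_select <= length(ordered_features))
  if (any(diff(scores) > 1e-12)) {
    stop("scores must be non-increasing along the ranking")
  }
  structure(list(method = method,
                 ordered_features = ordered_features,
                 scores = stats::setNames(scores, ordered_features),
                 selected = ordered_features[seq_len(n_select)],
                 raw_scores = if (!is.null(raw_scores))
                   stats::setNames(as.numeric(raw_scores), ordered_features)),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("feature_ranking [%s]: %d features, top %d selected\n",
              x$method, length(x$ordered_features), length(x$selected)))
  top <- utils::head(x$ordered_features, length(x$selected))
  cat(paste(sprintf("  %2d. %s (%.4g)", seq_along(top), top, x$scores[top]),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Write a ranking as delimited text
#' @param x a [feature_ranking].
#' @param path output path.
#' @export
write_ranking <- function(x, path) {
  stopifnot(inherits(x, "feature_ranking"))
  df <- data.frame(rank = seq_along(x$ordered_features),
                   feature_id = x$ordered_features,
                   layer = layer_of(x$ordered_features),
                   score = unname(x$scores),
                   selected = x$ordered_features %in% x$selected)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Deterministic ordering used by all rankers: primary key descending score,
# ties broken lexicographically by feature id.
.order_by_score <- function(feature_ids, scores) {
  order(-scores, feature_ids, method = "radix")
}

# Generic recursive-elimination loop shared by the RFE rankers.
# score_fun(surviving_ids, iteration) returns list(scores = named numeric,
# info = optional one-row data.frame of diagnostics). Eliminates the `step`
# lowest-scoring features per iteration (ties: lexicographically first id
# goes), stopping when n_select remain; one final scoring call orders the
# survivors. Returns the ranking ingredients plus an elimination trace.
.rfe_generic <- function(features, score_fun, n_select, step = 1L) {
  stopifnot(n_select >= 1L, n_select <= length(features), step >= 1L)
  surv <- features
  eliminated <- character(0)
  elim_score <- numeric(0)
  trace <- list()
  it <- 0L
  repeat {
    it <- it + 1L
    res <- score_fun(surv, it)
    sc <- res$scores[surv]
    if (length(surv) == n_select) {
      final_scores <- sc
      break
    }
    n_drop <- min(step, length(surv) - n_select)
    victims <- surv[order(sc, surv, method = "radix")][seq_len(n_drop)]
    row <- data.frame(iteration = it, eliminated_feature = victims,
                      score = unname(sc[victims]),
                      n_surviving = length(surv) - n_drop,
                      stringsAsFactors = FALSE)
    if (!is.null(res$info)) row <- cbind(row, res$info, row.names = NULL)
    trace[[it]] <- row
    eliminated <- c(eliminated, victims)
    elim_score <- c(elim_score, sc[victims])
    surv <- setdiff(surv, victims)
  }
  trace <- if (length(trace)) do.call(rbind, c(trace, list(make.row.names = FALSE)))
           else data.frame(iteration = integer(0), eliminated_feature = character(0),
                           score = numeric(0), n_surviving = integer(0))
  surv_ord <- surv[.order_by_score(surv, final_scores[surv])]
  list(ordered = c(surv_ord, rev(eliminated)),
       scores = c(final_scores[surv_ord] - min(final_scores, 0),
                  -seq_along(eliminated)),
       raw_scores = c(final_scores[surv_ord], rev(elim_score)),
       trace = trace)
}
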