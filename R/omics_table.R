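#' @useDynLib omicspanel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median sd
NULL

# Canonical layer encoding: feature ids carry a namespace prefix so a merged
# multi-omics matrix stays self-describing.
.LAYER_PREFIXES <- c(proteomics = "prot:", glycomics = "gly:", metabolomics = "met:")

#' Omics layer names recognized by the package
#' @return Character vector `c("proteomics", "glycomics", "metabolomics")`.
#' @export
omics_layers <- function() names(.LAYER_PREFIXES)

#' Prefix feature identifiers with their omics layer
#'
#' @param feature_ids character vector of bare feature identifiers
#'   (UniProt accessions, glycan composition codes, metabolite names).
#' @param layer one of `omics_layers()`.
#' @return Prefixed identifiers, e.g. `"met:glutamic acid"`.
#' @export
add_layer_prefix <- function(feature_ids, layer) {
  layer <- match.arg(layer, omics_layers())
  pre <- .LAYER_PREFIXES[[layer]]
  already <- startsWith(feature_ids, pre)
  feature_ids[!already] <- paste0(pre, feature_ids[!already])
  feature_ids
}

#' Map prefixed feature identifiers to their omics layer
#'
#' @param feature_ids prefixed feature identifiers.
#' @return Character vector of layer names, same length as `feature_ids`.
#' @export
layer_of <- function(feature_ids) {
  out <- rep(NA_character_, length(feature_ids))
  for (ly in omics_layers()) {
    out[startsWith(feature_ids, .LAYER_PREFIXES[[ly]])] <- ly
  }
  if (anyNA(out)) {
    bad <- feature_ids[is.na(out)]
    stop("feature id(s) without a recognized layer prefix (prot:/gly:/met:): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  out
}

#' Construct a samples x features omics abundance table
#'
#' The container every stage of the pipeline consumes: a numeric matrix with
#' samples as rows and features as columns, where each feature identifier
#' carries a layer prefix (`"prot:"`, `"gly:"`, `"met:"`). Missing abundances
#' are `NA`, never zero.
#'
#' @param values numeric matrix, samples x features. `NA` marks missing cells.
#' @param sample_ids,feature_ids optional identifiers; default to dimnames.
#' @param layer if given, all features are assigned to this single layer and
#'   prefixed accordingly; otherwise `feature_ids` must already be prefixed.
#' @param missing_ceiling maximum tolerated fraction of missing cells
#'   (default 0.01, i.e. under 1 percent missing data).
#' @return An object of class `omics_table`.
#' @export
omics_table <- function(values, sample_ids = rownames(values),
                        feature_ids = colnames(values), layer = NULL,
                        missing_ceiling = 0.01) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(feature_ids)) stop("feature identifiers are required")
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values) || length(feature_ids) != ncol(values)) {
    stop("dimensions of `values` do not match sample/feature identifiers")
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature identifier(s): ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifier(s)")
  if (!is.null(layer)) feature_ids <- add_layer_prefix(feature_ids, layer)
  layer_of(feature_ids)  # validates prefixes
  miss <- mean(is.na(values))
  if (miss > missing_ceiling) {
    stop(sprintf("missingness %.3f exceeds ceiling %.3f", miss, missing_ceiling))
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(
    list(values = values, sample_ids = sample_ids, feature_ids = feature_ids),
    class = "omics_table"
  )
}

#' @export
print.omics_table <- function(x, ...) {
  tab <- table(factor(layer_of(x$feature_ids), levels = omics_layers()))
  cat(sprintf("omics_table: %d samples x %d features (%s)\n",
              length(x$sample_ids), length(x$feature_ids),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  miss <- mean(is.na(x$values))
  if (miss > 0) cat(sprintf("  missing cells: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.omics_table <- function(x) dim(x$values)

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a delimited abundance table
#'
#' Expects a header row of feature names and sample identifiers in the first
#' column; the delimiter (comma or tab) is auto-detected. Empty cells become
#' missing values; any non-numeric cell is an error naming its position.
#'
#' @param path file path.
#' @param layer omics layer tag applied to all features in the file, or
#'   `NULL` (default) if the header already carries layer prefixes (as files
#'   written by [write_omics_table()] do).
#' @param missing_ceiling maximum tolerated missing fraction (default 0.01).
#' @return An [omics_table].
#' @export
read_omics_table <- function(path, layer = NULL, missing_ceiling = 0.01) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected sample id column plus at least one feature")
  sample_ids <- df[[1L]]
  feat <- colnames(df)[-1L]
  if (anyDuplicated(feat)) {
    stop("duplicate feature name(s) in header: ",
         paste(unique(feat[duplicated(feat)]), collapse = ", "))
  }
  mat <- matrix(NA_real_, nrow(df), length(feat))
  for (j in seq_along(feat)) {
    raw <- trimws(df[[j + 1L]])
    empty <- raw == "" | is.na(raw) | toupper(raw) == "NA"
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!empty & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric cell at row %d (sample '%s'), column '%s': '%s'",
                   bad[1L], sample_ids[bad[1L]], feat[j], raw[bad[1L]]))
    }
    mat[, j] <- num
  }
  omics_table(mat, sample_ids = sample_ids, feature_ids = feat, layer = layer,
              missing_ceiling = missing_ceiling)
}

#' Write an abundance table as delimited text
#'
#' Inverse of [read_omics_table()]; values are written at full double
#' precision so a read/write round trip is value-stable. Layer prefixes are
#' kept in the header.
#'
#' @param x an [omics_table].
#' @param path output path.
#' @param sep field delimiter, `"\t"` (default) or `","`.
#' @export
write_omics_table <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "omics_table"))
  vals <- format(x$values, digits = 17, trim = TRUE, scientific = TRUE)
  vals[is.na(x$values)] <- ""
  df <- data.frame(sample_id = x$sample_ids, vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", x$feature_ids)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct binary phenotype labels aligned to an omics table
#'
#' @param sample_ids sample identifiers.
#' @param label integer/logical vector, 1 = case (e.g. HCC), 0 = control
#'   (e.g. cirrhosis).
#' @return An object of class `phenotype_labels`.
#' @export
phenotype_labels <- function(sample_ids, label) {
  sample_ids <- as.character(sample_ids)
  label <- as.integer(label)
  if (length(sample_ids) != length(label)) stop("length mismatch")
  if (!all(label %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(unique(label)) < 2L) stop("both classes must be present")
  structure(list(sample_ids = sample_ids, label = label),
            class = "phenotype_labels")
}

#' @export
print.phenotype_labels <- function(x, ...) {
  cat(sprintf("phenotype_labels: %d samples (%d cases, %d controls)\n",
              length(x$label), sum(x$label == 1L), sum(x$label == 0L)))
  invisible(x)
}

#' Read phenotype labels from delimited text
#'
#' Two columns: sample identifier and 0/1 label; delimiter auto-detected.
#' @param path file path.
#' @return A [phenotype_labels] object.
#' @export
read_labels <- function(path) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  phenotype_labels(df[[1L]], df[[2L]])
}

#' @rdname read_labels
#' @param x a [phenotype_labels] object.
#' @param sep field delimiter.
#' @export
write_labels <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "phenotype_labels"))
  utils::write.table(
    data.frame(sample_id = x$sample_ids, label = x$label),
    path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align labels to an omics table's sample order
#'
#' @param labels a [phenotype_labels].
#' @param table an [omics_table].
#' @return Labels reordered to `table$sample_ids`.
#' @export
align_labels <- function(labels, table) {
  stopifnot(inherits(labels, "phenotype_labels"), inherits(table, "omics_table"))
  idx <- match(table$sample_ids, labels$sample_ids)
  if (anyNA(idx)) {
    stop("samples missing from labels: ",
         paste(utils::head(table$sample_ids[is.na(idx)], 5L), collapse = ", "))
  }
  phenotype_labels(labels$sample_ids[idx], labels$label[idx])
}

#' Merge per-layer tables into one multi-omics table
#'
#' Column-wise concatenation in canonical layer order (proteomics, then
#' glycomics, then metabolomics). All tables must contain the same samples;
#' later tables are re-aligned to the first table's sample order.
#'
#' @param tables list of [omics_table] objects.
#' @return A single merged [omics_table].
#' @export
merge_layers <- function(tables) {
  if (inherits(tables, "omics_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L, all(vapply(tables, inherits, TRUE, "omics_table")))
  ref <- tables[[1L]]$sample_ids
  for (i in seq_along(tables)[-1L]) {
    ids <- tables[[i]]$sample_ids
    extra <- setdiff(ids, ref); missing <- setdiff(ref, ids)
    if (length(extra) || length(missing)) {
      stop("sample sets differ between layers; offending samples: ",
           paste(utils::head(c(missing, extra), 10L), collapse = ", "))
    }
  }
  aligned <- lapply(tables, function(t) t$values[match(ref, t$sample_ids), , drop = FALSE])
  vals <- do.call(cbind, aligned)
  feats <- unlist(lapply(tables, `[[`, "feature_ids"), use.names = FALSE)
  # canonical block order: proteomics, glycomics, metabolomics
  ord <- order(match(layer_of(feats), omics_layers()))
  omics_table(vals[, ord, drop = FALSE], sample_ids = ref,
              feature_ids = feats[ord], missing_ceiling = 1)
}

#' Median-impute and z-score features using a designated fit subset
#'
#' Missing cells are replaced by the per-feature median of the `fit_rows`
#' samples; each feature is then centred and scaled by the mean and sample
#' standard deviation of `fit_rows` only. Computing the statistics on a fit
#' subset and applying them to all rows is what makes the transform safe to
#' use inside cross-validation: held-out rows never contribute to the
#' statistics that transform them.
#'
#' Features with zero variance on the fit rows are flagged and their
#' standardized values set to 0, with a warning.
#'
#' @param table an [omics_table].
#' @param fit_rows sample identifiers or indices whose statistics are used;
#'   defaults to all samples.
#' @return An [omics_table] of standardized values with attributes
#'   `center`, `scale` and `flagged` (zero-variance feature ids).
#' @export
impute_and_standardize <- function(table, fit_rows = NULL) {
  stopifnot(inherits(table, "omics_table"))
  X <- table$values
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(X))
  if (is.character(fit_rows)) fit_rows <- match(fit_rows, table$sample_ids)
  if (is.logical(fit_rows)) fit_rows <- which(fit_rows)
  if (!length(fit_rows) || anyNA(fit_rows)) stop("invalid fit_rows")
  fitX <- X[fit_rows, , drop = FALSE]
  med <- apply(fitX, 2L, median, na.rm = TRUE)
  med[is.na(med)] <- 0  # feature entirely missing on fit rows
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- med[j]
    fnas <- is.na(fitX[, j])
    if (any(fnas)) fitX[fnas, j] <- med[j]
  }
  ctr <- colMeans(fitX)
  scl <- apply(fitX, 2L, sd)
  flagged <- table$feature_ids[!is.finite(scl) | scl == 0]
  if (length(flagged)) {
    warning("zero-variance feature(s) on fit rows set to 0: ",
            paste(utils::head(flagged, 5L), collapse = ", "))
  }
  scl[!is.finite(scl) | scl == 0] <- Inf  # maps feature to all zeros
  Z <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
  out <- omics_table(Z, sample_ids = table$sample_ids,
                     feature_ids = table$feature_ids, missing_ceiling = 1)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  attr(out, "flagged") <- flagged
  out
}
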