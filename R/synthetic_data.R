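# Evaluate expr with a local, restored RNG state so generators are
# reproducible without clobbering the caller's stream.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Specification for a synthetic two-group multi-omics cohort
#'
#' Defaults mirror the targeted HCC-vs-cirrhosis study design this package
#' is built around: 40 cases vs 49 controls and 100 protein + 82 N-glycan +
#' 60 metabolite features, with log-normal-like intensities, within-layer
#' correlation blocks and under 1 percent missing cells.
#'
#' @param n_case,n_control samples per group.
#' @param layer_sizes features per layer, named after [omics_layers()].
#' @param n_informative number of planted differential features.
#' @param effect_size standardized mean shift d (log scale, in units of the
#'   within-group sd) added to cases for each informative feature. Either a
#'   scalar or a vector of length `n_informative`.
#' @param block_size features per within-layer exchangeable correlation block.
#' @param block_rho within-block correlation, in `[0, 1)`.
#' @param missing_rate fraction of cells masked completely at random.
#' @param keep_log if `TRUE` the table stays on the log scale; otherwise
#'   values are exponentiated to intensity scale.
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_case = 40L, n_control = 49L,
                           layer_sizes = c(proteomics = 100L, glycomics = 82L,
                                           metabolomics = 60L),
                           n_informative = 20L, effect_size = 1.0,
                           block_size = 10L, block_rho = 0.3,
                           missing_rate = 0.005, keep_log = FALSE,
                           seed = 1L) {
  if (is.null(names(layer_sizes))) {
    names(layer_sizes) <- omics_layers()[seq_along(layer_sizes)]
  }
  stopifnot(all(names(layer_sizes) %in% omics_layers()),
            n_case >= 2L, n_control >= 2L,
            block_rho >= 0, block_rho < 1,
            missing_rate >= 0, missing_rate <= 1,
            block_size >= 1L)
  p <- sum(layer_sizes)
  if (n_informative > p) stop("n_informative exceeds total feature count")
  if (!length(effect_size) %in% c(1L, max(1L, n_informative))) {
    stop("effect_size must be scalar or length n_informative")
  }
  structure(list(n_case = as.integer(n_case), n_control = as.integer(n_control),
                 layer_sizes = layer_sizes, n_informative = as.integer(n_informative),
                 effect_size = effect_size, block_size = as.integer(block_size),
                 block_rho = block_rho, missing_rate = missing_rate,
                 keep_log = keep_log, seed = as.integer(seed)),
            class = "synthetic_spec")
}

.synthetic_feature_ids <- function(layer_sizes) {
  tag <- c(proteomics = "P", glycomics = "G", metabolomics = "M")
  unlist(lapply(names(layer_sizes), function(ly) {
    add_layer_prefix(sprintf("%s%03d", tag[[ly]], seq_len(layer_sizes[[ly]])), ly)
  }), use.names = FALSE)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Per layer, log-scale values are drawn from a multivariate Gaussian with
#' unit marginal variance and exchangeable correlation `block_rho` inside
#' consecutive blocks of `block_size` features. Informative features (spread
#' evenly across the combined feature list) receive a location shift of
#' `effect_size` standard deviations in cases. Per-feature baseline
#' log-intensities are drawn from N(12, 1); values are exponentiated to
#' intensity scale unless `keep_log`, and cells are masked completely at
#' random at `missing_rate`.
#'
#' @param spec a [synthetic_spec].
#' @return List with elements `table` ([omics_table]), `labels`
#'   ([phenotype_labels]) and `truth` (list with `informative_features` and
#'   named vector `effect_size_of`).
#' @export
generate_cohort <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_case + spec$n_control
    feats <- .synthetic_feature_ids(spec$layer_sizes)
    p <- length(feats)
    y <- c(rep(1L, spec$n_case), rep(0L, spec$n_control))
    sample_ids <- c(sprintf("case%03d", seq_len(spec$n_case)),
                    sprintf("ctrl%03d", seq_len(spec$n_control)))

    Z <- matrix(0, n, p)
    off <- 0L
    for (ly in names(spec$layer_sizes)) {
      pl <- spec$layer_sizes[[ly]]
      blocks <- split(seq_len(pl), ceiling(seq_len(pl) / spec$block_size))
      for (b in blocks) {
        shared <- rnorm(n)
        eps <- matrix(rnorm(n * length(b)), n, length(b))
        Z[, off + b] <- sqrt(spec$block_rho) * shared +
          sqrt(1 - spec$block_rho) * eps
      }
      off <- off + pl
    }

    if (spec$n_informative > 0L) {
      idx <- unique(round(seq(1, p, length.out = spec$n_informative)))
      d <- rep_len(spec$effect_size, length(idx))
      Z[y == 1L, idx] <- sweep(Z[y == 1L, idx, drop = FALSE], 2L, d, "+")
      truth <- list(informative_features = feats[idx],
                    effect_size_of = stats::setNames(d, feats[idx]))
    } else {
      truth <- list(informative_features = character(0),
                    effect_size_of = stats::setNames(numeric(0), character(0)))
    }

    baseline <- rnorm(p, mean = 12, sd = 1)
    V <- sweep(Z, 2L, baseline, "+")
    if (!spec$keep_log) V <- exp(V)
    if (spec$missing_rate > 0) {
      mask <- runif(n * p) < spec$missing_rate
      V[matrix(mask, n, p)] <- NA_real_
    }
    list(
      table = omics_table(V, sample_ids = sample_ids, feature_ids = feats,
                          missing_ceiling = max(0.01, 2 * spec$missing_rate)),
      labels = phenotype_labels(sample_ids, y),
      truth = truth
    )
  })
}

#' Write a deterministic suite of miniature test cohorts
#'
#' Emits three small named cohorts in the package's delimited formats, used
#' by unit tests: `basic` (two planted features at d = 1.5), `separable`
#' (one feature at d = 4, separating the groups almost perfectly on its own)
#' and `null` (no informative features). Each cohort is 20 samples by
#' 30 features (10 per layer). Identical seeds produce byte-identical files.
#'
#' @param seed integer master seed.
#' @param dir output directory (created if needed).
#' @return Named list of per-cohort file paths (`table`, `labels`) plus the
#'   in-memory cohorts under `$cohorts`.
#' @export
fixture_suite <- function(seed = 1L, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- list(n_case = 10L, n_control = 10L,
               layer_sizes = c(proteomics = 10L, glycomics = 10L, metabolomics = 10L),
               block_size = 5L, block_rho = 0.2, missing_rate = 0)
  specs <- list(
    basic     = synthetic_spec(n_case = base$n_case, n_control = base$n_control,
                               layer_sizes = base$layer_sizes, n_informative = 2L,
                               effect_size = 1.5, block_size = base$block_size,
                               block_rho = base$block_rho, missing_rate = 0,
                               seed = seed),
    separable = synthetic_spec(n_case = base$n_case, n_control = base$n_control,
                               layer_sizes = base$layer_sizes, n_informative = 1L,
                               effect_size = 4.0, block_size = base$block_size,
                               block_rho = base$block_rho, missing_rate = 0,
                               seed = seed + 1L),
    null      = synthetic_spec(n_case = base$n_case, n_control = base$n_control,
                               layer_sizes = base$layer_sizes, n_informative = 0L,
                               effect_size = 0, block_size = base$block_size,
                               block_rho = base$block_rho, missing_rate = 0,
                               seed = seed + 2L)
  )
  out <- list(cohorts = list())
  for (nm in names(specs)) {
    co <- generate_cohort(specs[[nm]])
    tab_path <- file.path(dir, paste0(nm, "_table.tsv"))
    lab_path <- file.path(dir, paste0(nm, "_labels.tsv"))
    write_omics_table(co$table, tab_path)
    write_labels(co$labels, lab_path)
    out[[nm]] <- list(table = tab_path, labels = lab_path)
    out$cohorts[[nm]] <- co
  }
  out
}
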