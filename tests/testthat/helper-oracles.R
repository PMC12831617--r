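# Shared fixtures and independent oracles used across the test files.

# Small synthetic cohort; defaults keep unit tests fast.
tiny_cohort <- function(seed = 1L, n_case = 10L, n_control = 10L,
                        layers = c(proteomics = 4L, glycomics = 3L,
                                   metabolomics = 3L),
                        n_informative = 0L, effect_size = 0,
                        block_rho = 0.2, missing_rate = 0, ...) {
  generate_cohort(synthetic_spec(
    n_case = n_case, n_control = n_control, layer_sizes = layers,
    n_informative = n_informative, effect_size = effect_size,
    block_rho = block_rho, missing_rate = missing_rate, seed = seed, ...))
}

std_xy <- function(co) {
  list(X = suppressWarnings(impute_and_standardize(co$table))$values,
       y = co$labels$label)
}

# Two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins (point-probability rule).
fisher_enum_oracle <- function(m) {
  m <- matrix(m, 2L, 2L)
  r1 <- sum(m[1L, ]); c1 <- sum(m[, 1L]); n <- sum(m)
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(m[1L, 1L], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC by explicit enumeration of all case/control pairs, ties count 1/2.
auc_pair_oracle <- function(values, y) {
  cs <- values[y == 1L]; ct <- values[y == 0L]
  pairs <- outer(cs, ct, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

# Exact Shapley values of an arbitrary prediction function by subset
# enumeration, with absent features set to the background value.
shapley_brute <- function(f, x, background) {
  p <- length(x)
  v <- function(S) {
    z <- background; z[S] <- x[S]
    f(matrix(z, 1L, p))
  }
  phi <- numeric(p)
  for (j in seq_len(p)) {
    others <- setdiff(seq_len(p), j)
    for (k in 0:length(others)) {
      subs <- if (k == 0) list(integer(0)) else
        utils::combn(others, k, simplify = FALSE)
      for (S in subs) {
        w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
        phi[j] <- phi[j] + w * (v(c(S, j)) - v(S))
      }
    }
  }
  phi
}

# Reduced transformer settings shared by the slower integration tests.
fast_tf_config <- function(seed = 1L, max_epochs = 250L,
                           early_stop_patience = 40L, ...) {
  transformer_config(d_model = 16L, n_heads = 2L, n_attention_layers = 1L,
                     d_ff = 32L, max_epochs = max_epochs,
                     early_stop_patience = early_stop_patience,
                     learning_rate = 3e-2, n_permutations = 8L, seed = seed,
                     ...)
}
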