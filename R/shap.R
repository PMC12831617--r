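#' Monte-Carlo permutation Shapley attributions for any predictor
#'
#' Model-agnostic Shapley estimate: for each evaluation sample, features are
#' inserted one at a time in `n_permutations` random orders, starting from a
#' background reference vector; a feature's attribution is its average
#' marginal change in the prediction. Because each permutation's
#' contributions telescope, the attributions satisfy the efficiency axiom
#' exactly: for every sample, `sum(phi) = f(x) - f(background)` up to
#' floating-point error, at any number of permutations.
#'
#' @param predict_fun function taking a numeric matrix (rows = samples,
#'   columns = the model's features, in order) and returning a numeric
#'   prediction per row.
#' @param X_eval matrix of samples to attribute.
#' @param background reference vector (length `ncol(X_eval)`) substituted
#'   for absent features; typically the training feature means.
#' @param n_permutations Monte-Carlo permutations (default 128).
#' @param seed integer seed; attributions are deterministic given it.
#' @return List with `phi` (attribution matrix, same shape as `X_eval`),
#'   `base` (prediction at the background) and `scores`
#'   (mean absolute attribution per feature).
#' @export
permutation_shap <- function(predict_fun, X_eval, background,
                             n_permutations = 128L, seed = 1L) {
  X_eval <- as.matrix(X_eval)
  n <- nrow(X_eval); p <- ncol(X_eval)
  stopifnot(length(background) == p, n_permutations >= 1L)
  phi <- matrix(0, n, p, dimnames = dimnames(X_eval))
  .with_seed(seed, {
    for (r in seq_len(n_permutations)) {
      perm <- sample.int(p)
      # stack the p+1 insertion stages into one batched prediction
      stages <- matrix(rep(background, each = n * (p + 1L)), n * (p + 1L), p)
      for (t in seq_len(p)) {
        rows_on <- (t * n + 1L):((p + 1L) * n)  # stages t..p have feature perm[t] set
        js <- perm[t]
        stages[rows_on, js] <- rep(X_eval[, js], p + 1L - t)
      }
      f <- predict_fun(stages)
      fm <- matrix(f, n, p + 1L)  # column t = prediction after t-1 insertions
      phi[, perm] <- phi[, perm] + (fm[, -1L, drop = FALSE] - fm[, -(p + 1L), drop = FALSE])
    }
  })
  phi <- phi / n_permutations
  base <- unname(predict_fun(matrix(background, 1L, p))[1L])
  list(phi = phi, base = base, scores = colMeans(abs(phi)))
}

# Adam update for a named list of parameter arrays. state holds m/v/t.
.adam_init <- function(par) {
  list(m = lapply(par, function(x) x * 0), v = lapply(par, function(x) x * 0),
       t = 0L)
}

.adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grad[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    par[[nm]] <- par[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}
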