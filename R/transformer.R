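#' Configuration for the cross-attention tabular transformer
#'
#' Architecture: every feature becomes a token (its scalar value projected
#' to `d_model` dimensions, plus a learned per-feature embedding and a
#' learned omics-layer embedding); a single learned query token
#' cross-attends over all feature tokens through `n_attention_layers`
#' attention + feed-forward blocks with residual connections; the refined
#' query representation feeds a binary logistic head. Keeping the query as
#' the only token that updates keeps the parameter count O(p * d_model),
#' which is what makes the model trainable on cohorts of under a hundred
#' samples.
#'
#' @param d_model embedding width (divisible by `n_heads`).
#' @param n_heads attention heads.
#' @param n_attention_layers attention blocks.
#' @param d_ff feed-forward hidden width (default `2 * d_model`).
#' @param dropout dropout rate on the feed-forward hidden layer during
#'   training (0 disables it).
#' @param max_epochs full-batch Adam epochs.
#' @param learning_rate Adam learning rate.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping; the best-validation parameters are restored.
#' @param val_fraction stratified fraction held out for early stopping.
#' @param weight_decay L2 penalty on weight matrices and embeddings.
#' @param n_permutations Monte-Carlo permutations for Shapley importance.
#' @param seed integer seed; training is fully reproducible from it.
#' @return A `transformer_config` list.
#' @export
transformer_config <- function(d_model = 32L, n_heads = 4L,
                               n_attention_layers = 2L, d_ff = 2L * d_model,
                               dropout = 0, max_epochs = 300L,
                               learning_rate = 1e-2, early_stop_patience = 40L,
                               val_fraction = 0.2, weight_decay = 1e-4,
                               n_permutations = 128L, seed = 1L) {
  stopifnot(d_model %% n_heads == 0L, max_epochs >= 1L,
            dropout >= 0, dropout < 1, val_fraction >= 0, val_fraction < 0.5)
  list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
       n_attention_layers = as.integer(n_attention_layers),
       d_ff = as.integer(d_ff), dropout = dropout,
       max_epochs = as.integer(max_epochs), learning_rate = learning_rate,
       early_stop_patience = as.integer(early_stop_patience),
       val_fraction = val_fraction, weight_decay = weight_decay,
       n_permutations = as.integer(n_permutations), seed = as.integer(seed))
}

.tf_init <- function(p, n_layer_groups, cfg) {
  d <- cfg$d_model; Fh <- cfg$d_ff
  par <- list(
    w_val = stats::rnorm(d, sd = 1),
    E = matrix(stats::rnorm(p * d, sd = 0.2), p, d),
    Lyr = matrix(stats::rnorm(n_layer_groups * d, sd = 0.2), n_layer_groups, d),
    q0 = stats::rnorm(d, sd = 0.2),
    w_out = stats::rnorm(d, sd = 1 / sqrt(d)),
    b_out = 0
  )
  for (i in seq_len(cfg$n_attention_layers)) {
    par[[paste0("Wq", i)]] <- matrix(stats::rnorm(d * d, sd = 1 / sqrt(d)), d, d)
    par[[paste0("Wk", i)]] <- matrix(stats::rnorm(d * d, sd = 1 / sqrt(d)), d, d)
    par[[paste0("Wv", i)]] <- matrix(stats::rnorm(d * d, sd = 1 / sqrt(d)), d, d)
    par[[paste0("Wo", i)]] <- matrix(stats::rnorm(d * d, sd = 1 / sqrt(d)), d, d)
    par[[paste0("W1", i)]] <- matrix(stats::rnorm(d * Fh, sd = 1 / sqrt(d)), d, Fh)
    par[[paste0("b1", i)]] <- rep(0, Fh)
    par[[paste0("W2", i)]] <- matrix(stats::rnorm(Fh * d, sd = 1 / sqrt(Fh)), Fh, d)
    par[[paste0("b2", i)]] <- rep(0, d)
  }
  par
}

# Forward pass. X: n x p, lidx: per-feature layer-group index (1-based).
# Returns logits; with cache = TRUE also all intermediates for backprop.
# drop_masks: optional list of n x d_ff inverted-dropout masks per block.
.tf_forward <- function(par, X, lidx, cfg, cache = FALSE, drop_masks = NULL) {
  n <- nrow(X); p <- ncol(X)
  d <- cfg$d_model; H <- cfg$n_heads; dk <- d %/% H
  grp <- rep(seq_len(n), each = p)
  frep <- rep.int(seq_len(p), n)
  xvec <- as.vector(t(X))
  Tmat <- tcrossprod(xvec, par$w_val) + par$E[frep, , drop = FALSE] +
    par$Lyr[lidx[frep], , drop = FALSE]
  q <- matrix(par$q0, n, d, byrow = TRUE)
  layers <- if (cache) vector("list", cfg$n_attention_layers)
  for (i in seq_len(cfg$n_attention_layers)) {
    Wq <- par[[paste0("Wq", i)]]; Wk <- par[[paste0("Wk", i)]]
    Wv <- par[[paste0("Wv", i)]]; Wo <- par[[paste0("Wo", i)]]
    Q <- q %*% Wq; K <- Tmat %*% Wk; V <- Tmat %*% Wv
    A <- matrix(0, n, d)
    amats <- if (cache) vector("list", H)
    for (h in seq_len(H)) {
      hh <- ((h - 1L) * dk + 1L):(h * dk)
      Qh <- Q[, hh, drop = FALSE]; Kh <- K[, hh, drop = FALSE]
      Vh <- V[, hh, drop = FALSE]
      sc <- rowSums(Kh * Qh[grp, , drop = FALSE]) / sqrt(dk)
      S <- matrix(sc, n, p, byrow = TRUE)
      S <- S - apply(S, 1L, max)
      a <- exp(S); a <- a / rowSums(a)
      A[, hh] <- rowsum(Vh * as.vector(t(a)), grp)
      if (cache) amats[[h]] <- a
    }
    q1 <- q + A %*% Wo
    Hpre <- sweep(q1 %*% par[[paste0("W1", i)]], 2L, par[[paste0("b1", i)]], "+")
    Hid <- pmax(Hpre, 0)
    if (!is.null(drop_masks)) Hid <- Hid * drop_masks[[i]]
    q2 <- q1 + sweep(Hid %*% par[[paste0("W2", i)]], 2L, par[[paste0("b2", i)]], "+")
    if (cache) layers[[i]] <- list(q_in = q, Q = Q, K = K, V = V, a = amats,
                                   A = A, q1 = q1, Hpre = Hpre, Hid = Hid)
    q <- q2
  }
  logit <- drop(q %*% par$w_out) + par$b_out
  if (!cache) return(logit)
  list(logit = logit, q_final = q, layers = layers, Tmat = Tmat,
       xvec = xvec, grp = grp, frep = frep)
}

# Mean binary cross-entropy with logits; numerically stable.
.bce <- function(logit, y) {
  mean((1 - y) * logit + log1p(exp(-abs(logit))) + pmax(-logit, 0))
}

# Loss and analytic gradients for one full batch.
.tf_loss_grad <- function(par, X, y, lidx, cfg, drop_masks = NULL) {
  n <- nrow(X); p <- ncol(X)
  d <- cfg$d_model; H <- cfg$n_heads; dk <- d %/% H
  fw <- .tf_forward(par, X, lidx, cfg, cache = TRUE, drop_masks = drop_masks)
  prob <- stats::plogis(fw$logit)
  loss <- .bce(fw$logit, y)
  grp <- fw$grp; frep <- fw$frep
  g <- lapply(par, function(x) x * 0)
  dlogit <- (prob - y) / n
  g$w_out <- drop(crossprod(fw$q_final, dlogit))
  g$b_out <- sum(dlogit)
  dq <- tcrossprod(dlogit, par$w_out)
  dT <- matrix(0, n * p, d)
  for (i in rev(seq_len(cfg$n_attention_layers))) {
    L <- fw$layers[[i]]
    W1 <- par[[paste0("W1", i)]]; W2 <- par[[paste0("W2", i)]]
    Wo <- par[[paste0("Wo", i)]]; Wq <- par[[paste0("Wq", i)]]
    Wk <- par[[paste0("Wk", i)]]; Wv <- par[[paste0("Wv", i)]]
    dq2 <- dq
    g[[paste0("W2", i)]] <- crossprod(L$Hid, dq2)
    g[[paste0("b2", i)]] <- colSums(dq2)
    dHid <- dq2 %*% t(W2)
    if (!is.null(drop_masks)) dHid <- dHid * drop_masks[[i]]
    dHpre <- dHid * (L$Hpre > 0)
    g[[paste0("W1", i)]] <- crossprod(L$q1, dHpre)
    g[[paste0("b1", i)]] <- colSums(dHpre)
    dq1 <- dq2 + dHpre %*% t(W1)
    dA <- dq1 %*% t(Wo)
    g[[paste0("Wo", i)]] <- crossprod(L$A, dq1)
    dQ <- matrix(0, n, d); dKV <- matrix(0, n * p, d); dV <- matrix(0, n * p, d)
    for (h in seq_len(H)) {
      hh <- ((h - 1L) * dk + 1L):(h * dk)
      a <- L$a[[h]]
      aflat <- as.vector(t(a))
      Kh <- L$K[, hh, drop = FALSE]; Vh <- L$V[, hh, drop = FALSE]
      Qh <- L$Q[, hh, drop = FALSE]
      dhead <- dA[, hh, drop = FALSE]
      dhead_rep <- dhead[grp, , drop = FALSE]
      dV[, hh] <- dhead_rep * aflat
      da <- matrix(rowSums(Vh * dhead_rep), n, p, byrow = TRUE)
      ds <- a * (da - rowSums(a * da))
      dsflat <- as.vector(t(ds)) / sqrt(dk)
      dQ[, hh] <- rowsum(Kh * dsflat, grp)
      dKV[, hh] <- Qh[grp, , drop = FALSE] * dsflat
    }
    g[[paste0("Wq", i)]] <- crossprod(L$q_in, dQ)
    g[[paste0("Wk", i)]] <- crossprod(fw$Tmat, dKV)
    g[[paste0("Wv", i)]] <- crossprod(fw$Tmat, dV)
    dT <- dT + dKV %*% t(Wk) + dV %*% t(Wv)
    dq <- dq1 + dQ %*% t(Wq)
  }
  g$q0 <- colSums(dq)
  g$E <- rowsum(dT, frep)
  g$w_val <- drop(crossprod(dT, fw$xvec))
  dL <- rowsum(dT, lidx[frep])
  g$Lyr[sort(unique(lidx)), ] <- dL
  if (cfg$weight_decay > 0) {
    for (nm in names(g)) {
      if (!nm %in% c("b_out", "q0") && !startsWith(nm, "b")) {
        g[[nm]] <- g[[nm]] + cfg$weight_decay * par[[nm]]
      }
    }
  }
  list(loss = loss, grad = g)
}

#' Train the cross-attention transformer classifier
#'
#' Full-batch Adam with early stopping on a stratified validation split;
#' the parameters with the best validation loss are kept. Training is fully
#' reproducible from `config$seed`.
#'
#' @param X standardized numeric matrix (samples x features) with
#'   layer-prefixed feature ids as column names.
#' @param y 0/1 labels or [phenotype_labels].
#' @param config a [transformer_config()].
#' @return A `transformer_model` with elements `par` (trained parameters),
#'   `config`, `feature_ids`, `background` (training feature means, used as
#'   the Shapley reference), `history` (per-epoch losses) and `best_epoch`.
#' @export
fit_transformer <- function(X, y, config = transformer_config()) {
  y <- if (inherits(y, "phenotype_labels")) y$label else as.integer(y)
  stopifnot(length(y) == nrow(X), !is.null(colnames(X)))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  lys <- layer_of(colnames(X))
  lidx <- match(lys, omics_layers())
  cfg <- config
  .with_seed(cfg$seed, {
    n <- nrow(X)
    # stratified validation split for early stopping
    n_val_by_class <- vapply(c(0L, 1L), function(cl)
      floor(sum(y == cl) * cfg$val_fraction), numeric(1))
    use_val <- cfg$val_fraction > 0 && all(n_val_by_class >= 1)
    if (use_val) {
      val_idx <- unlist(lapply(c(0L, 1L), function(cl) {
        idx <- which(y == cl)
        sample(idx, n_val_by_class[[cl + 1L]])
      }))
      tr_idx <- setdiff(seq_len(n), val_idx)
    } else {
      tr_idx <- seq_len(n); val_idx <- integer(0)
    }
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]

    par <- .tf_init(ncol(X), length(omics_layers()), cfg)
    state <- .adam_init(par)
    best <- list(loss = Inf, par = par, epoch = 0L)
    wait <- 0L
    hist <- matrix(NA_real_, cfg$max_epochs, 2L,
                   dimnames = list(NULL, c("train_loss", "val_loss")))
    for (ep in seq_len(cfg$max_epochs)) {
      masks <- NULL
      if (cfg$dropout > 0) {
        masks <- lapply(seq_len(cfg$n_attention_layers), function(i) {
          matrix(stats::rbinom(nrow(Xtr) * cfg$d_ff, 1L, 1 - cfg$dropout),
                 nrow(Xtr), cfg$d_ff) / (1 - cfg$dropout)
        })
      }
      lg <- .tf_loss_grad(par, Xtr, ytr, lidx, cfg, drop_masks = masks)
      if (!is.finite(lg$loss)) stop("training loss diverged (non-finite)")
      upd <- .adam_step(par, lg$grad, state, cfg$learning_rate)
      par <- upd$par; state <- upd$state
      monitor <- if (use_val) {
        .bce(.tf_forward(par, Xval, lidx, cfg), yval)
      } else {
        .bce(.tf_forward(par, Xtr, lidx, cfg), ytr)
      }
      hist[ep, ] <- c(lg$loss, if (use_val) monitor else NA_real_)
      if (monitor < best$loss - 1e-9) {
        best <- list(loss = monitor, par = par, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$early_stop_patience) break
      }
    }
    structure(list(par = best$par, config = cfg,
                   feature_ids = colnames(X), layer_idx = lidx,
                   background = colMeans(X),
                   history = as.data.frame(hist[!is.na(hist[, 1L]), , drop = FALSE]),
                   best_epoch = best$epoch),
              class = "transformer_model")
  })
}

#' @export
print.transformer_model <- function(x, ...) {
  cat(sprintf(paste0("transformer_model: %d features, d_model=%d, %d heads, ",
                     "%d attention layers (best epoch %d)\n"),
              length(x$feature_ids), x$config$d_model, x$config$n_heads,
              x$config$n_attention_layers, x$best_epoch))
  invisible(x)
}

#' Predict case probabilities from a trained transformer
#'
#' @param object a `transformer_model`.
#' @param newdata matrix with the model's features in the model's column
#'   order (column names checked when present).
#' @param type `"response"` (probability) or `"link"` (logit).
#' @param ... unused.
#' @export
predict.transformer_model <- function(object, newdata,
                                      type = c("response", "link"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_ids)) {
    stop("newdata feature set does not match the trained model")
  }
  if (ncol(newdata) != length(object$feature_ids)) {
    stop("newdata feature set does not match the trained model")
  }
  logit <- .tf_forward(object$par, newdata, object$layer_idx, object$config)
  if (type == "link") logit else stats::plogis(logit)
}

#' Shapley feature importance of a trained transformer
#'
#' Monte-Carlo permutation Shapley attributions (see [permutation_shap()])
#' of the predicted case probability, with the training feature means as
#' background. The importance score is the mean absolute attribution over
#' the evaluation samples.
#'
#' @param model a `transformer_model`.
#' @param X_eval samples to attribute (typically the training matrix).
#' @param n_permutations Monte-Carlo permutations; defaults to the model
#'   config.
#' @param seed seed; defaults to the model config seed.
#' @return List with `phi`, `base` and per-feature `scores`
#'   (see [permutation_shap()]).
#' @export
shap_importance <- function(model, X_eval,
                            n_permutations = model$config$n_permutations,
                            seed = model$config$seed) {
  stopifnot(inherits(model, "transformer_model"))
  X_eval <- as.matrix(X_eval)
  if (!is.null(colnames(X_eval)) &&
      !identical(colnames(X_eval), model$feature_ids)) {
    stop("X_eval feature set does not match the trained model")
  }
  permutation_shap(function(M) {
    .tf_forward(model$par, M, model$layer_idx, model$config) |> stats::plogis()
  }, X_eval, model$background, n_permutations = n_permutations, seed = seed)
}

#' Recursive feature elimination with the transformer as estimator
#'
#' The transformer is trained on the current feature set, per-feature
#' Shapley importance scores are computed, and the single lowest-scoring
#' feature (ties broken lexicographically) is removed; the model is then
#' retrained from a fresh seed-derived initialization on the reduced set.
#' The loop stops when `n_select` features remain; a final fit orders the
#' survivors by their Shapley scores, and eliminated features follow in
#' reverse elimination order.
#'
#' @inheritParams fit_transformer
#' @param n_select features to retain.
#' @return List with `ranking` (a [feature_ranking]; `raw_scores` are
#'   Shapley scores frozen at elimination time) and `trace` (one row per
#'   elimination: iteration, eliminated feature, its score, surviving
#'   count, training loss).
#' @export
transformer_rfe_rank <- function(X, y, n_select = 5L,
                                 config = transformer_config()) {
  y <- if (inherits(y, "phenotype_labels")) y$label else as.integer(y)
  stopifnot(n_select >= 1L, n_select <= ncol(X), !is.null(colnames(X)))
  rfe <- .rfe_generic(colnames(X), function(surv, it) {
    cfg <- config
    cfg$seed <- config$seed + 7919L * it  # fresh re-initialization per refit
    Xs <- X[, surv, drop = FALSE]
    model <- fit_transformer(Xs, y, cfg)
    shap <- shap_importance(model, Xs, seed = cfg$seed + 1L)
    list(scores = shap$scores,
         info = data.frame(train_loss = utils::tail(model$history$train_loss, 1L),
                           best_epoch = model$best_epoch))
  }, n_select = n_select, step = 1L)
  ranking <- feature_ranking("transformer_rfe", rfe$ordered, rfe$scores,
                             n_select = n_select, raw_scores = rfe$raw_scores)
  list(ranking = ranking, trace = rfe$trace)
}
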