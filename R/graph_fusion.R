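#' Configuration for the graph-convolution fusion classifier
#'
#' @param knn_k neighbors kept per sample in each sample-similarity network.
#' @param gcn_hidden hidden width of each per-view graph convolution.
#' @param gcn_layers graph-convolution layers per view (1 or 2).
#' @param vcdn_hidden hidden width of the label-space fusion head.
#' @param max_epochs full-batch Adam epochs.
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 penalty on weight matrices.
#' @param seed integer seed.
#' @return A `graph_fusion_config` list.
#' @export
graph_fusion_config <- function(knn_k = 10L, gcn_hidden = 32L, gcn_layers = 2L,
                                vcdn_hidden = 16L, max_epochs = 300L,
                                learning_rate = 1e-2, weight_decay = 1e-4,
                                seed = 1L) {
  stopifnot(knn_k >= 1L, gcn_layers %in% c(1L, 2L), max_epochs >= 1L)
  list(knn_k = as.integer(knn_k), gcn_hidden = as.integer(gcn_hidden),
       gcn_layers = as.integer(gcn_layers), vcdn_hidden = as.integer(vcdn_hidden),
       max_epochs = as.integer(max_epochs), learning_rate = learning_rate,
       weight_decay = weight_decay, seed = as.integer(seed))
}

#' Build a sample-similarity network for one omics view
#'
#' Cosine similarity between sample profiles, sparsified by keeping each
#' sample's `knn_k` most similar neighbors, symmetrized by the elementwise
#' maximum, with unit self-loops added. Kept edges get weight
#' `max(similarity, 1e-8)`: clamping at a small positive floor guarantees
#' every selected neighbor stays connected even when standardization makes
#' a few similarities slightly negative.
#'
#' @param X_layer one view's standardized matrix (samples x features).
#' @param knn_k neighbors per sample; must be below the sample count.
#' @return An `ssn` object with the symmetric `adjacency` matrix.
#' @export
build_ssn <- function(X_layer, knn_k = 10L) {
  X_layer <- as.matrix(X_layer)
  n <- nrow(X_layer)
  stopifnot(n > knn_k)
  nrm <- sqrt(rowSums(X_layer^2))
  if (any(nrm == 0)) {
    bad <- rownames(X_layer)[nrm == 0]
    if (is.null(bad)) bad <- which(nrm == 0)
    stop("zero-norm sample profile(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  S <- tcrossprod(X_layer / nrm)
  A <- matrix(0, n, n, dimnames = dimnames(S))
  for (i in seq_len(n)) {
    ord <- order(-S[i, ], seq_len(n), method = "radix")
    nb <- setdiff(ord, i)[seq_len(knn_k)]
    A[i, nb] <- pmax(S[i, nb], 1e-8)
  }
  A <- pmax(A, t(A))  # symmetrize by max
  diag(A) <- 1
  structure(list(adjacency = A, knn_k = as.integer(knn_k)), class = "ssn")
}

#' Export a sample-similarity network as an edge list
#' @param ssn an [build_ssn()] result.
#' @return data.frame with sample_i, sample_j, weight (upper triangle).
#' @export
ssn_edges <- function(ssn) {
  A <- ssn$adjacency
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  ids <- rownames(A); if (is.null(ids)) ids <- as.character(seq_len(nrow(A)))
  data.frame(sample_i = ids[idx[, 1L]], sample_j = ids[idx[, 2L]],
             weight = A[idx], stringsAsFactors = FALSE)
}

# Symmetric degree normalization D^-1/2 (A) D^-1/2.
.ssn_normalize <- function(A) {
  dinv <- 1 / sqrt(rowSums(A))
  A * tcrossprod(dinv)
}

.softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Per-view GCN forward. Returns class logits plus caches.
.gcn_forward <- function(Ahat, X, W, layers) {
  if (layers == 1L) {
    list(logits = Ahat %*% (X %*% W$W2), H = NULL, Hpre = NULL)
  } else {
    Hpre <- Ahat %*% (X %*% W$W1)
    H <- pmax(Hpre, 0)
    list(logits = Ahat %*% (H %*% W$W2), H = H, Hpre = Hpre)
  }
}

# Cross-view correlation tensor: flattened outer product of the per-view
# class-probability vectors, per sample. P_list: list of n x 2 matrices.
.vcdn_tensor <- function(P_list) {
  V <- length(P_list)
  idx <- as.matrix(expand.grid(rep(list(1:2), V)))  # 2^V combinations
  n <- nrow(P_list[[1L]])
  C <- matrix(1, n, nrow(idx))
  for (v in seq_len(V)) C <- C * P_list[[v]][, idx[, v], drop = FALSE]
  list(C = C, idx = idx)
}

#' Fit the graph-convolution fusion classifier
#'
#' A compact multi-view graph classifier: each omics view gets a
#' sample-similarity network and a graph convolutional network producing
#' per-sample class probabilities; the flattened cross-view outer product of
#' those probability vectors (the label-space correlation tensor) feeds a
#' small dense head that outputs the final class probabilities. The loss is
#' the sum of the per-view cross-entropies plus the fusion cross-entropy,
#' evaluated on `train_mask` samples only; the model is transductive (all
#' samples participate in the graphs, labels of masked-out samples are
#' never used).
#'
#' @param X_by_layer named list of standardized per-view matrices
#'   (same rows).
#' @param y 0/1 labels or [phenotype_labels].
#' @param train_mask logical or integer subset of rows used for the loss;
#'   must cover both classes. Defaults to all samples.
#' @param config a [graph_fusion_config()].
#' @return A `graph_fusion_model`.
#' @export
mogonet_lite_fit <- function(X_by_layer, y, train_mask = NULL,
                             config = graph_fusion_config()) {
  y <- if (inherits(y, "phenotype_labels")) y$label else as.integer(y)
  stopifnot(is.list(X_by_layer), length(X_by_layer) >= 1L)
  X_by_layer <- lapply(X_by_layer, as.matrix)
  n <- nrow(X_by_layer[[1L]])
  stopifnot(all(vapply(X_by_layer, nrow, 0L) == n), length(y) == n)
  if (is.null(train_mask)) train_mask <- seq_len(n)
  if (is.logical(train_mask)) train_mask <- which(train_mask)
  if (length(unique(y[train_mask])) < 2L) stop("train_mask must cover both classes")
  V <- length(X_by_layer)
  cfg <- config
  ssns <- lapply(X_by_layer, build_ssn, knn_k = cfg$knn_k)
  Ahat <- lapply(ssns, function(s) .ssn_normalize(s$adjacency))
  Y <- cbind(1 - y, y)  # one-hot, class 2 = case
  ntr <- length(train_mask)

  .with_seed(cfg$seed, {
    par <- list()
    for (v in seq_len(V)) {
      pv <- ncol(X_by_layer[[v]])
      if (cfg$gcn_layers == 2L) {
        par[[paste0("W1_", v)]] <- matrix(stats::rnorm(pv * cfg$gcn_hidden,
                                                       sd = 1 / sqrt(pv)),
                                          pv, cfg$gcn_hidden)
        par[[paste0("W2_", v)]] <- matrix(stats::rnorm(cfg$gcn_hidden * 2L,
                                                       sd = 1 / sqrt(cfg$gcn_hidden)),
                                          cfg$gcn_hidden, 2L)
      } else {
        par[[paste0("W2_", v)]] <- matrix(stats::rnorm(pv * 2L, sd = 1 / sqrt(pv)),
                                          pv, 2L)
      }
    }
    par$Wf1 <- matrix(stats::rnorm(2^V * cfg$vcdn_hidden, sd = 1 / sqrt(2^V)),
                      2^V, cfg$vcdn_hidden)
    par$bf1 <- rep(0, cfg$vcdn_hidden)
    par$Wf2 <- matrix(stats::rnorm(cfg$vcdn_hidden * 2L,
                                   sd = 1 / sqrt(cfg$vcdn_hidden)),
                      cfg$vcdn_hidden, 2L)
    par$bf2 <- rep(0, 2L)
    state <- .adam_init(par)

    for (ep in seq_len(cfg$max_epochs)) {
      # ---- forward
      gcn <- vector("list", V); P_list <- vector("list", V)
      for (v in seq_len(V)) {
        W <- list(W1 = par[[paste0("W1_", v)]], W2 = par[[paste0("W2_", v)]])
        gcn[[v]] <- .gcn_forward(Ahat[[v]], X_by_layer[[v]], W, cfg$gcn_layers)
        P_list[[v]] <- .softmax_rows(gcn[[v]]$logits)
      }
      vc <- .vcdn_tensor(P_list)
      Fpre <- sweep(vc$C %*% par$Wf1, 2L, par$bf1, "+")
      Fh <- pmax(Fpre, 0)
      logits_f <- sweep(Fh %*% par$Wf2, 2L, par$bf2, "+")
      Pf <- .softmax_rows(logits_f)
      eps <- 1e-12
      loss <- -mean(log(rowSums(Pf[train_mask, , drop = FALSE] *
                                  Y[train_mask, , drop = FALSE]) + eps))
      for (v in seq_len(V)) {
        loss <- loss - mean(log(rowSums(P_list[[v]][train_mask, , drop = FALSE] *
                                          Y[train_mask, , drop = FALSE]) + eps))
      }
      if (!is.finite(loss)) stop("training loss diverged (non-finite)")

      # ---- backward
      g <- lapply(par, function(x) x * 0)
      dlogits_f <- matrix(0, n, 2L)
      dlogits_f[train_mask, ] <- (Pf[train_mask, , drop = FALSE] -
                                    Y[train_mask, , drop = FALSE]) / ntr
      g$Wf2 <- crossprod(Fh, dlogits_f); g$bf2 <- colSums(dlogits_f)
      dFh <- dlogits_f %*% t(par$Wf2)
      dFpre <- dFh * (Fpre > 0)
      g$Wf1 <- crossprod(vc$C, dFpre); g$bf1 <- colSums(dFpre)
      dC <- dFpre %*% t(par$Wf1)
      for (v in seq_len(V)) {
        # dP_v from the correlation tensor: product over the other views
        dPv <- matrix(0, n, 2L)
        for (r in seq_len(nrow(vc$idx))) {
          prod_others <- rep(1, n)
          for (u in seq_len(V)) {
            if (u != v) prod_others <- prod_others * P_list[[u]][, vc$idx[r, u]]
          }
          cls <- vc$idx[r, v]
          dPv[, cls] <- dPv[, cls] + dC[, r] * prod_others
        }
        # direct per-view cross-entropy on softmax probabilities:
        # d loss / d logits = (P - Y)/ntr; the tensor path adds softmax
        # backward of dPv.
        Pv <- P_list[[v]]
        dlog_v <- Pv * (dPv - rowSums(dPv * Pv))
        dlog_v[train_mask, ] <- dlog_v[train_mask, ] +
          (Pv[train_mask, , drop = FALSE] - Y[train_mask, , drop = FALSE]) / ntr
        Xv <- X_by_layer[[v]]
        if (cfg$gcn_layers == 2L) {
          H <- gcn[[v]]$H
          AdL <- Ahat[[v]] %*% dlog_v
          g[[paste0("W2_", v)]] <- crossprod(H, AdL)
          dH <- AdL %*% t(par[[paste0("W2_", v)]])
          dHpre <- dH * (gcn[[v]]$Hpre > 0)
          g[[paste0("W1_", v)]] <- crossprod(Xv, Ahat[[v]] %*% dHpre)
        } else {
          g[[paste0("W2_", v)]] <- crossprod(Xv, Ahat[[v]] %*% dlog_v)
        }
      }
      if (cfg$weight_decay > 0) {
        for (nm in names(g)) {
          if (!startsWith(nm, "b")) g[[nm]] <- g[[nm]] + cfg$weight_decay * par[[nm]]
        }
      }
      upd <- .adam_step(par, g, state, cfg$learning_rate)
      par <- upd$par; state <- upd$state
    }
    structure(list(par = par, config = cfg, ssns = ssns, Ahat = Ahat,
                   X_by_layer = X_by_layer, y = y, train_mask = train_mask,
                   final_loss = loss),
              class = "graph_fusion_model")
  })
}

# Forward pass with (possibly ablated) view matrices; Ahat recomputed when
# a view's matrix is supplied.
.gf_predict <- function(model, X_by_layer = model$X_by_layer,
                        Ahat = NULL) {
  cfg <- model$config
  V <- length(X_by_layer)
  if (is.null(Ahat)) {
    Ahat <- lapply(X_by_layer, function(X)
      .ssn_normalize(build_ssn(X, cfg$knn_k)$adjacency))
  }
  P_list <- vector("list", V)
  for (v in seq_len(V)) {
    W <- list(W1 = model$par[[paste0("W1_", v)]],
              W2 = model$par[[paste0("W2_", v)]])
    P_list[[v]] <- .softmax_rows(
      .gcn_forward(Ahat[[v]], X_by_layer[[v]], W, cfg$gcn_layers)$logits)
  }
  vc <- .vcdn_tensor(P_list)
  Fh <- pmax(sweep(vc$C %*% model$par$Wf1, 2L, model$par$bf1, "+"), 0)
  Pf <- .softmax_rows(sweep(Fh %*% model$par$Wf2, 2L, model$par$bf2, "+"))
  list(prob = Pf, views = P_list)
}

#' Predicted class probabilities from the fusion model
#' @param object a `graph_fusion_model`.
#' @param ... unused (transductive model: predictions are for its samples).
#' @return Matrix n x 2 of class probabilities (column 2 = case).
#' @export
predict.graph_fusion_model <- function(object, ...) {
  .gf_predict(object, Ahat = object$Ahat)$prob
}

.gf_train_loss <- function(model, prob) {
  Y <- cbind(1 - model$y, model$y)
  tm <- model$train_mask
  -mean(log(rowSums(prob[tm, , drop = FALSE] * Y[tm, , drop = FALSE]) + 1e-12))
}

#' Ablation feature ranking from the fusion model
#'
#' Importance of a feature = increase in the training-mask fusion loss when
#' that feature's column is replaced by its training-mean value (its view's
#' similarity network is rebuilt on the ablated matrix), clamped at zero.
#' This mean-replacement ablation is the transductive analog of post-hoc
#' attribution for the graph model.
#'
#' @param model a `graph_fusion_model`.
#' @param k features to flag as selected.
#' @return A [feature_ranking]; `raw_scores` are unclamped loss increases.
#' @export
mogonet_lite_rank <- function(model, k = 5L) {
  stopifnot(inherits(model, "graph_fusion_model"))
  base_loss <- .gf_train_loss(model, .gf_predict(model, Ahat = model$Ahat)$prob)
  feats <- unlist(lapply(model$X_by_layer, colnames), use.names = FALSE)
  scores <- numeric(0)
  for (v in seq_along(model$X_by_layer)) {
    Xv <- model$X_by_layer[[v]]
    mcol <- colMeans(Xv[model$train_mask, , drop = FALSE])
    for (j in seq_len(ncol(Xv))) {
      Xab <- Xv; Xab[, j] <- mcol[j]
      Xl <- model$X_by_layer; Xl[[v]] <- Xab
      Ah <- model$Ahat
      Ah[[v]] <- .ssn_normalize(build_ssn(Xab, model$config$knn_k)$adjacency)
      loss <- .gf_train_loss(model, .gf_predict(model, Xl, Ahat = Ah)$prob)
      scores <- c(scores, loss - base_loss)
    }
  }
  names(scores) <- feats
  clamped <- pmax(scores, 0)
  ord <- .order_by_score(feats, clamped)
  feature_ranking("mogonet_lite", feats[ord], clamped[ord], n_select = k,
                  raw_scores = scores[ord])
}
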