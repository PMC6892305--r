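# Multi-filter 1d-CNN classification head over encoder token states, the
# margin ranking loss, and the plain linear (pooled-[CLS]) head.
#
# Each filter of width w slides along the token axis over full-hidden-size
# slices (valid convolution: windows never extend past the last real
# token), adds a bias, applies ReLU, and is max-over-time pooled into one
# feature. Features from all filters are concatenated (default 3 widths x
# 100 maps = 300 values) and classified by a dropout + dense + softmax
# stage.

#' CNN head settings
#'
#' @param windows filter widths (default `c(3, 4, 5)`).
#' @param maps feature maps per width (default 100).
#' @param dropout rate applied to the pooled features during training
#'   (default 0.5).
#' @return a list of class `cnn_config`.
#' @export
cnn_config <- function(windows = c(3L, 4L, 5L), maps = 100L, dropout = 0.5) {
  stopifnot(all(windows >= 1), maps >= 1, dropout >= 0, dropout < 1)
  structure(list(windows = as.integer(windows), maps = as.integer(maps),
                 dropout = dropout),
            class = "cnn_config")
}

#' Initialize CNN head parameters
#'
#' One weight matrix per window width (`(w * H) x maps`, column-major over
#' the window's token rows) plus bias, and a dense classifier over the
#' concatenated features.
#'
#' @param cfg a [cnn_config].
#' @param H encoder hidden size.
#' @param n_classes number of output classes (>= 2).
#' @param seed integer seed.
#' @return a parameter list (class `cnn_params`).
#' @export
init_cnn_params <- function(cfg, H, n_classes, seed = 1L) {
  stopifnot(n_classes >= 2)
  with_seed(seed, {
    filt <- lapply(cfg$windows, function(w) {
      list(W = tn_mat(w * H, cfg$maps), b = numeric(cfg$maps))
    })
    names(filt) <- paste0("w", cfg$windows)
    D <- length(cfg$windows) * cfg$maps
    structure(list(filters = filt,
                   fc_W = tn_mat(D, n_classes), fc_b = numeric(n_classes)),
              class = "cnn_params")
  })
}

# stack sliding windows of X (rows t..t+w-1, vectorized column-major) into a
# (n_windows x w*H) matrix
stack_windows <- function(X, w, n) {
  nwin <- n - w + 1L
  M <- matrix(0, nwin, w * ncol(X))
  for (t in seq_len(nwin)) M[t, ] <- as.vector(X[t:(t + w - 1L), , drop = FALSE])
  M
}

#' Convolution + max-over-time pooling
#'
#' Valid 1-d convolution along the token axis over full-hidden slices,
#' bias, ReLU, then the maximum over window positions that lie entirely
#' within the unpadded part of the sequence. If fewer real tokens than a
#' filter's width remain, that filter contributes its bias through ReLU.
#'
#' @param hidden `Lseq x H` matrix of final encoder states.
#' @param mask 0/1 vector marking real tokens.
#' @param params a `cnn_params` object.
#' @param cfg the matching [cnn_config].
#' @param keep_cache retain intermediates for backprop.
#' @return list with `features` (length `sum(maps)` vector) and `cache`.
#' @export
conv_pool <- function(hidden, mask, params, cfg, keep_cache = FALSE) {
  n <- sum(mask == 1L)
  feats <- numeric(0)
  caches <- if (keep_cache) vector("list", length(cfg$windows)) else NULL
  for (k in seq_along(cfg$windows)) {
    w <- cfg$windows[k]
    fp <- params$filters[[k]]
    if (n >= w) {
      M <- stack_windows(hidden, w, n)
      Z <- add_bias(M %*% fp$W, fp$b)
      Zr <- pmax(Z, 0)
      arg <- max.col(t(Zr), ties.method = "first") # argmax row per map
      f <- Zr[cbind(arg, seq_len(ncol(Zr)))]
      if (keep_cache) caches[[k]] <- list(M = M, Z = Z, arg = arg, short = FALSE)
    } else {
      f <- pmax(fp$b, 0)
      if (keep_cache) caches[[k]] <- list(short = TRUE)
      message(sprintf(
        "conv_pool: %d real tokens shorter than window %d; filter contributes bias through ReLU",
        n, w))
    }
    feats <- c(feats, f)
  }
  cache <- if (keep_cache) list(per_window = caches, n = n, Lseq = nrow(hidden)) else NULL
  list(features = feats, cache = cache)
}

# backward of conv_pool: gradient w.r.t. hidden states and filter params
conv_pool_backward <- function(dfeat, params, cfg, cache, H) {
  dX <- matrix(0, cache$Lseq, H)
  gf <- vector("list", length(cfg$windows))
  names(gf) <- names(params$filters)
  off <- 0L
  for (k in seq_along(cfg$windows)) {
    w <- cfg$windows[k]
    fp <- params$filters[[k]]
    dW <- matrix(0, w * H, cfg$maps)
    db <- numeric(cfg$maps)
    d_k <- dfeat[(off + 1L):(off + cfg$maps)]
    ck <- cache$per_window[[k]]
    if (!ck$short) {
      for (j in seq_len(cfg$maps)) {
        t <- ck$arg[j]
        if (ck$Z[t, j] > 0 && d_k[j] != 0) {
          dW[, j] <- dW[, j] + ck$M[t, ] * d_k[j]
          db[j] <- db[j] + d_k[j]
          dX[t:(t + w - 1L), ] <- dX[t:(t + w - 1L), ] +
            matrix(fp$W[, j] * d_k[j], w, H)
        }
      }
    } else {
      act <- fp$b > 0
      db[act] <- db[act] + d_k[act]
    }
    gf[[k]] <- list(W = dW, b = db)
    off <- off + cfg$maps
  }
  list(dX = dX, grads = list(filters = gf))
}

#' Dense softmax classification of a feature vector
#'
#' Affine map plus softmax; during training, dropout is applied to the
#' features first.
#'
#' @param features numeric feature vector.
#' @param params a parameter list with `fc_W` and `fc_b`.
#' @param dropout rate applied in training mode.
#' @param training apply dropout.
#' @param keep_cache retain intermediates for backprop.
#' @return list with `probs` (sums to 1) and `cache`.
#' @export
classify <- function(features, params, dropout = 0.5, training = FALSE,
                     keep_cache = FALSE) {
  dd <- dropout(features, dropout, training)
  z <- drop(dd$out %*% params$fc_W) + params$fc_b
  e <- exp(z - max(z))
  probs <- e / sum(e)
  cache <- if (keep_cache) list(fdrop = dd$out, dmask = dd$mask, probs = probs) else NULL
  list(probs = probs, cache = cache)
}

# backward of classify given dlogits; returns dfeatures + fc grads
classify_backward <- function(dlogits, params, cache) {
  gW <- cache$fdrop %o% dlogits
  gb <- dlogits
  dfeat <- drop(params$fc_W %*% dlogits)
  dfeat <- dropout_backward(dfeat, cache$dmask)
  list(dfeat = dfeat, gW = gW, gb = gb)
}

# cross-entropy gradient at the logits for a softmax output
ce_dlogits <- function(probs, class_index) {
  d <- probs
  d[class_index] <- d[class_index] - 1
  d
}

#' Margin ranking loss over positive/negative score pairs
#'
#' `sum(max(0, 1 - g(d) + g(d')))` over paired positive scores `g(d)` and
#' negative scores `g(d')`. Zero exactly when every pair satisfies the unit
#' margin. Scores must lie in `[0, 1]` (they are softmax outputs).
#'
#' @param pos_scores,neg_scores equal-length numeric vectors.
#' @return nonnegative scalar.
#' @export
ranking_loss <- function(pos_scores, neg_scores) {
  stopifnot(length(pos_scores) == length(neg_scores))
  if (any(pos_scores < 0 | pos_scores > 1 | neg_scores < 0 | neg_scores > 1)) {
    stop("scores must lie in [0, 1]: g is a softmax output", call. = FALSE)
  }
  sum(pmax(0, 1 - pos_scores + neg_scores))
}

# pair positive and negative batch indices by shuffled index, cycling the
# shorter side; optionally all positive x negative pairs
rank_pairs <- function(pos_idx, neg_idx, all_pairs = FALSE) {
  if (!length(pos_idx) || !length(neg_idx)) return(NULL)
  if (all_pairs) {
    expand.grid(pos = pos_idx, neg = neg_idx, KEEP.OUT.ATTRS = FALSE)
  } else {
    shuf <- function(x) if (length(x) <= 1L) x else sample(x)
    np <- max(length(pos_idx), length(neg_idx))
    data.frame(pos = rep(shuf(pos_idx), length.out = np),
               neg = rep(shuf(neg_idx), length.out = np))
  }
}

#' Linear classification head over the pooled first-token state
#'
#' The plain sequence-classification head: dropout on the pooled `[CLS]`
#' vector, then an affine map and softmax. Identical in form to
#' [classify]; it differs only in consuming the pooled state rather than
#' convolutional features.
#'
#' @param pooled pooled `[CLS]` vector (length H).
#' @param params list with `fc_W` (`H x n_classes`) and `fc_b`.
#' @param dropout rate applied in training mode.
#' @param training apply dropout.
#' @param keep_cache retain intermediates.
#' @return list with `probs` and `cache`.
#' @export
linear_head <- function(pooled, params, dropout = 0.5, training = FALSE,
                        keep_cache = FALSE) {
  classify(pooled, params, dropout = dropout, training = training,
           keep_cache = keep_cache)
}

init_linear_params <- function(H, n_classes, seed = 1L) {
  stopifnot(n_classes >= 2)
  with_seed(seed, structure(list(fc_W = tn_mat(H, n_classes),
                                 fc_b = numeric(n_classes)),
                            class = "linear_params"))
}
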