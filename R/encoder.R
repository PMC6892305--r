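# The bidirectional transformer encoder stack.
#
# Input embedding: row i of the input matrix is the elementwise sum of the
# token embedding of ids[i], the segment embedding of segment_ids[i], and
# the position embedding of position i. The stack applies L identical
# layers, each a masked multi-head scaled dot-product self-attention
# sublayer and a position-wise feed-forward sublayer (GELU), both with
# residual connections and post-sublayer layer normalization. A tanh pooler
# over the first ([CLS]) token feeds sequence-level classifiers.

#' Encoder geometry
#'
#' @param L number of layers (0 allowed: the encoder is then the embedding).
#' @param H hidden size; must be divisible by `A`.
#' @param A number of attention heads.
#' @param F feed-forward inner size (default `4 * H`, the standard ratio).
#' @param V vocabulary size.
#' @param P maximum number of positions (must cover every max_len used).
#' @param dropout dropout rate applied to embeddings, attention weights and
#'   sublayer outputs during training.
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function(L, H, A, F = 4L * H, V, P = 512L, dropout = 0.1) {
  stopifnot(L >= 0, H >= 1, A >= 1, H %% A == 0, F >= 1, V >= 1, P >= 1,
            dropout >= 0, dropout < 1)
  structure(list(L = as.integer(L), H = as.integer(H), A = as.integer(A),
                 F = as.integer(F), V = as.integer(V), P = as.integer(P),
                 dropout = dropout),
            class = "encoder_config")
}

#' @export
print.encoder_config <- function(x, ...) {
  cat(sprintf("<encoder_config: L=%d H=%d A=%d F=%d V=%d P=%d dropout=%g (%s parameters)>\n",
              x$L, x$H, x$A, x$F, x$V, x$P, x$dropout,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Closed-form encoder parameter count
#'
#' Sums the embedding tables (token `V x H`, segment `2 x H`, position
#' `P x H`), per-layer attention projections (four `H x H` matrices with
#' biases), two layer normalizations (`2H` each), the feed-forward weights
#' (`H x F` and `F x H` with biases), and the pooler (`H x H` plus bias).
#' Equals the element count of an instantiated checkpoint exactly.
#'
#' @param config an [encoder_config].
#' @return numeric scalar (may exceed integer range for large geometries).
#' @export
count_parameters <- function(config) {
  H <- as.numeric(config$H); F <- as.numeric(config$F)
  emb <- (config$V + 2 + config$P) * H
  attn <- 4 * (H * H + H)
  lns <- 2 * (2 * H)
  ffn <- H * F + F + F * H + H
  layer <- attn + lns + ffn
  pool <- H * H + H
  emb + config$L * layer + pool
}

#' Initialize encoder parameters
#'
#' Weights are drawn from a truncated normal (scale 0.02, resampled beyond
#' two standard deviations); layer-normalization gains start at 1, all
#' biases at 0. Deterministic given `seed`.
#'
#' @param config an [encoder_config].
#' @param seed integer seed.
#' @return an object of class `encoder_params`.
#' @export
init_encoder_params <- function(config, seed = 1L) {
  with_seed(seed, {
    H <- config$H; F <- config$F
    layers <- lapply(seq_len(config$L), function(l) {
      list(Wq = tn_mat(H, H), bq = numeric(H),
           Wk = tn_mat(H, H), bk = numeric(H),
           Wv = tn_mat(H, H), bv = numeric(H),
           Wo = tn_mat(H, H), bo = numeric(H),
           ln1_g = rep(1, H), ln1_b = numeric(H),
           W1 = tn_mat(H, F), b1 = numeric(F),
           W2 = tn_mat(F, H), b2 = numeric(H),
           ln2_g = rep(1, H), ln2_b = numeric(H))
    })
    structure(list(tok = tn_mat(config$V, H),
                   seg = tn_mat(2L, H),
                   pos = tn_mat(config$P, H),
                   layers = layers,
                   pool_W = tn_mat(H, H), pool_b = numeric(H)),
              class = "encoder_params")
  })
}

#' Input embedding: elementwise sum of token, segment and position rows
#'
#' Row i of the result is
#' `tok[ids[i], ] + seg[segment_ids[i], ] + pos[positions[i], ]` — an exact
#' sum, no normalization or scaling.
#'
#' @param seq a `token_sequence` (see [encode_pair]).
#' @param tables a list with matrices `tok` (`V x H`), `seg` (`2 x H`) and
#'   `pos` (`P x H`) — e.g. an `encoder_params` object.
#' @return a `length(seq$ids) x H` numeric matrix.
#' @export
embed <- function(seq, tables) {
  ids <- seq$ids
  if (any(ids < 0L) || any(ids >= nrow(tables$tok))) {
    stop(sprintf("token id out of range [0, %d)", nrow(tables$tok)), call. = FALSE)
  }
  if (any(seq$positions >= nrow(tables$pos))) {
    stop(sprintf("position out of range [0, %d)", nrow(tables$pos)), call. = FALSE)
  }
  tables$tok[ids + 1L, , drop = FALSE] +
    tables$seg[seq$segment_ids + 1L, , drop = FALSE] +
    tables$pos[seq$positions + 1L, , drop = FALSE]
}

# backward of embed: scatter row gradients into the three tables
embed_backward <- function(dX, seq, config) {
  g <- list(tok = NULL, seg = NULL, pos = NULL)
  g$tok <- matrix(0, config$V, config$H)
  acc <- rowsum(dX, group = seq$ids, reorder = FALSE)
  g$tok[as.integer(rownames(acc)) + 1L, ] <- acc
  g$seg <- matrix(0, 2L, config$H)
  accs <- rowsum(dX, group = seq$segment_ids, reorder = FALSE)
  g$seg[as.integer(rownames(accs)) + 1L, ] <- accs
  g$pos <- matrix(0, config$P, config$H)
  g$pos[seq$positions + 1L, ] <- g$pos[seq$positions + 1L, ] + dX
  g
}

#' One encoder layer
#'
#' Masked multi-head scaled dot-product self-attention (padding positions
#' are excluded as attention targets), residual connection and layer
#' normalization, then a position-wise GELU feed-forward network with its
#' own residual and normalization.
#'
#' @param hidden `Lseq x H` input matrix.
#' @param mask 0/1 vector; 0 marks padding (excluded as attention keys).
#' @param lp the layer's parameter list.
#' @param config an [encoder_config].
#' @param training apply dropout.
#' @param keep_cache retain intermediates for the backward pass.
#' @return list with `out` (`Lseq x H`), `attn` (list of per-head attention
#'   probability matrices), and `cache` when requested.
#' @export
encoder_layer <- function(hidden, mask, lp, config, training = FALSE,
                          keep_cache = FALSE) {
  X <- hidden
  if (any(!is.finite(X))) stop("non-finite values entering encoder layer", call. = FALSE)
  H <- config$H; A <- config$A; d <- H %/% A
  Q <- add_bias(X %*% lp$Wq, lp$bq)
  K <- add_bias(X %*% lp$Wk, lp$bk)
  V <- add_bias(X %*% lp$Wv, lp$bv)
  pad <- which(mask == 0L)
  O <- matrix(0, nrow(X), H)
  P_list <- vector("list", A)
  S_list <- if (keep_cache) vector("list", A) else NULL
  pdrop_list <- if (keep_cache) vector("list", A) else NULL
  for (a in seq_len(A)) {
    idx <- ((a - 1L) * d + 1L):(a * d)
    S <- (Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE])) / sqrt(d)
    if (length(pad)) S[, pad] <- -1e9
    P <- softmax_rows(S)
    P_list[[a]] <- P
    dp <- dropout(P, config$dropout, training)
    if (keep_cache) pdrop_list[a] <- list(dp$mask)
    O[, idx] <- dp$out %*% V[, idx, drop = FALSE]
  }
  AOut <- add_bias(O %*% lp$Wo, lp$bo)
  da <- dropout(AOut, config$dropout, training)
  R1 <- X + da$out
  l1 <- ln_forward(R1, lp$ln1_g, lp$ln1_b)
  H1 <- l1$out
  Z1 <- add_bias(H1 %*% lp$W1, lp$b1)
  U <- gelu(Z1)
  Z2 <- add_bias(U %*% lp$W2, lp$b2)
  df <- dropout(Z2, config$dropout, training)
  R2 <- H1 + df$out
  l2 <- ln_forward(R2, lp$ln2_g, lp$ln2_b)
  out <- l2$out
  if (any(!is.finite(out))) stop("non-finite values produced by encoder layer", call. = FALSE)
  cache <- NULL
  if (keep_cache) {
    cache <- list(X = X, Q = Q, K = K, V = V, P = P_list, pdrop = pdrop_list,
                  O = O, amask = da$mask, l1 = l1, H1 = H1, Z1 = Z1, U = U,
                  fmask = df$mask, l2 = l2, mask = mask)
  }
  list(out = out, attn = P_list, cache = cache)
}

# backward through one encoder layer; returns dX and the layer grads
encoder_layer_backward <- function(dout, lp, cache, config) {
  H <- config$H; A <- config$A; d <- H %/% A
  b2l <- ln_backward(dout, cache$l2, lp$ln2_g)
  dR2 <- b2l$dx
  dH1 <- dR2
  dZ2 <- dropout_backward(dR2, cache$fmask)
  dU <- dZ2 %*% t(lp$W2)
  gW2 <- t(cache$U) %*% dZ2
  gb2 <- colSums(dZ2)
  dZ1 <- dU * gelu_grad(cache$Z1)
  dH1 <- dH1 + dZ1 %*% t(lp$W1)
  gW1 <- t(cache$H1) %*% dZ1
  gb1 <- colSums(dZ1)
  b1l <- ln_backward(dH1, cache$l1, lp$ln1_g)
  dR1 <- b1l$dx
  dX <- dR1
  dAOut <- dropout_backward(dR1, cache$amask)
  dO <- dAOut %*% t(lp$Wo)
  gWo <- t(cache$O) %*% dAOut
  gbo <- colSums(dAOut)
  dQ <- matrix(0, nrow(dout), H)
  dK <- matrix(0, nrow(dout), H)
  dV <- matrix(0, nrow(dout), H)
  for (a in seq_len(A)) {
    idx <- ((a - 1L) * d + 1L):(a * d)
    P <- cache$P[[a]]
    Pd <- if (is.null(cache$pdrop[[a]])) P else P * cache$pdrop[[a]]
    dOa <- dO[, idx, drop = FALSE]
    dPd <- dOa %*% t(cache$V[, idx, drop = FALSE])
    dV[, idx] <- t(Pd) %*% dOa
    dP <- dropout_backward(dPd, cache$pdrop[[a]])
    dS <- softmax_rows_backward(P, dP) / sqrt(d)
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE]
    dK[, idx] <- t(dS) %*% cache$Q[, idx, drop = FALSE]
  }
  dX <- dX + dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv)
  grads <- list(Wq = t(cache$X) %*% dQ, bq = colSums(dQ),
                Wk = t(cache$X) %*% dK, bk = colSums(dK),
                Wv = t(cache$X) %*% dV, bv = colSums(dV),
                Wo = gWo, bo = gbo,
                ln1_g = b1l$dg, ln1_b = b1l$db,
                W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                ln2_g = b2l$dg, ln2_b = b2l$db)
  list(dX = dX, grads = grads)
}

#' Encode a token sequence through the full stack
#'
#' Embedding sum, (training-only) dropout, then `L` encoder layers.
#' Deterministic in evaluation mode.
#'
#' @param seq a `token_sequence`.
#' @param params an `encoder_params` object.
#' @param config the matching [encoder_config].
#' @param training apply dropout.
#' @param keep_cache retain intermediates for backprop.
#' @return list with `hidden` (final `Lseq x H` matrix), `pooled`
#'   (tanh-pooled `[CLS]` vector), and `cache` when requested.
#' @export
encode <- function(seq, params, config, training = FALSE, keep_cache = FALSE) {
  X0 <- embed(seq, params)
  de <- dropout(X0, config$dropout, training)
  h <- de$out
  layer_caches <- if (keep_cache) vector("list", config$L) else NULL
  for (l in seq_len(config$L)) {
    res <- encoder_layer(h, seq$mask, params$layers[[l]], config,
                         training = training, keep_cache = keep_cache)
    if (keep_cache) layer_caches[[l]] <- res$cache
    h <- res$out
  }
  z <- drop(h[1L, ] %*% params$pool_W) + params$pool_b
  pooled <- tanh(z)
  cache <- NULL
  if (keep_cache) {
    cache <- list(seq = seq, emb_mask = de$mask, layers = layer_caches,
                  h_final = h, pooled = pooled)
  }
  list(hidden = h, pooled = pooled, cache = cache)
}

# backward through the stack. dhidden: gradient w.r.t. final hidden matrix;
# dpooled: gradient w.r.t. the pooled [CLS] vector (either may be NULL).
encode_backward <- function(dhidden, dpooled, params, config, cache) {
  H <- config$H
  g <- list(tok = NULL, seg = NULL, pos = NULL,
            layers = vector("list", config$L),
            pool_W = matrix(0, H, H), pool_b = numeric(H))
  dh <- if (is.null(dhidden)) matrix(0, nrow(cache$h_final), H) else dhidden
  if (!is.null(dpooled)) {
    dz <- dpooled * (1 - cache$pooled^2)
    g$pool_W <- cache$h_final[1L, ] %o% dz
    g$pool_b <- dz
    dh[1L, ] <- dh[1L, ] + drop(params$pool_W %*% dz)
  }
  for (l in rev(seq_len(config$L))) {
    res <- encoder_layer_backward(dh, params$layers[[l]], cache$layers[[l]], config)
    g$layers[[l]] <- res$grads
    dh <- res$dX
  }
  dh <- dropout_backward(dh, cache$emb_mask)
  emb <- embed_backward(dh, cache$seq, config)
  g$tok <- emb$tok; g$seg <- emb$seg; g$pos <- emb$pos
  g
}

# ---- checkpoints -------------------------------------------------------------

#' Save / load an encoder checkpoint
#'
#' A checkpoint is a directory holding a versioned JSON manifest of the
#' configuration plus one container of named parameter tensors. Loading
#' verifies that every tensor's shape agrees with the manifest geometry.
#'
#' @param params an `encoder_params` object.
#' @param config the matching [encoder_config].
#' @param dir checkpoint directory (created if needed).
#' @param extra optional named list of additional tensors (e.g. pretraining
#'   or classifier head parameters), stored under their own namespace.
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(params, config, dir, extra = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(format = "medrex-checkpoint", version = 1L,
                   pooler = TRUE,
                   config = unclass(config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(list(encoder = unclass(params), extra = extra),
          file.path(dir, "params.rds"))
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  if (!identical(manifest$format, "medrex-checkpoint")) {
    stop("not a medrex checkpoint: ", dir, call. = FALSE)
  }
  cfgl <- manifest$config
  config <- encoder_config(L = cfgl$L, H = cfgl$H, A = cfgl$A, F = cfgl$F,
                           V = cfgl$V, P = cfgl$P, dropout = cfgl$dropout)
  blob <- readRDS(file.path(dir, "params.rds"))
  params <- structure(blob$encoder, class = "encoder_params")
  ref <- init_encoder_params(config, seed = 1L)
  if (!tree_shapes_equal(unclass(params), unclass(ref))) {
    stop("checkpoint tensors disagree with the manifest geometry", call. = FALSE)
  }
  if (tree_count(unclass(params)) != count_parameters(config)) {
    stop("checkpoint element count disagrees with the configured geometry",
         call. = FALSE)
  }
  list(params = params, config = config, extra = blob$extra)
}
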