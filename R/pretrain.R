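# Unsupervised pretraining: masked language modelling and next-sentence
# prediction over a sentence-segmented corpus.

#' Masking policy for the masked-token objective
#'
#' Of the selected positions a fraction `mask` is replaced by `[MASK]`,
#' `random` by a random vocabulary token, and `keep` left unchanged
#' (defaults 0.8 / 0.1 / 0.1, the standard recipe).
#'
#' @param rate fraction of maskable positions selected (default 0.15,
#'   minimum one position).
#' @param mask,random,keep replacement fractions; must sum to 1.
#' @return a list of class `mask_policy`.
#' @export
mask_policy <- function(rate = 0.15, mask = 0.8, random = 0.1, keep = 0.1) {
  stopifnot(rate > 0, rate <= 1, abs(mask + random + keep - 1) < 1e-9)
  structure(list(rate = rate, mask = mask, random = random, keep = keep),
            class = "mask_policy")
}

#' Corrupt a token sequence for masked-token prediction
#'
#' Selects `max(1, floor(rate * n_maskable))` positions among the real
#' (non-`[PAD]`, non-`[CLS]`, non-`[SEP]`) tokens and applies the policy;
#' the original ids at the selected positions are recorded as the
#' prediction targets. Uses the current RNG state.
#'
#' @param seq a `token_sequence`.
#' @param vocab the [wordpiece_vocab] the sequence was encoded with.
#' @param policy a [mask_policy].
#' @return list with `ids` (corrupted), `positions` (1-based indexes of the
#'   selected tokens), and `targets` (original ids there).
#' @export
mask_tokens <- function(seq, vocab, policy = mask_policy()) {
  special_ids <- vocab_id(vocab, c("[CLS]", "[SEP]"))
  maskable <- which(seq$mask == 1L & !(seq$ids %in% special_ids))
  if (!length(maskable)) stop("sequence has no maskable token", call. = FALSE)
  n_sel <- max(1L, floor(policy$rate * length(maskable)))
  sel <- if (length(maskable) == 1L) maskable else sample(maskable, n_sel)
  ids <- seq$ids
  targets <- ids[sel]
  u <- stats::runif(length(sel))
  mask_id <- vocab_id(vocab, "[MASK]")
  for (k in seq_along(sel)) {
    if (u[k] < policy$mask) {
      ids[sel[k]] <- mask_id
    } else if (u[k] < policy$mask + policy$random) {
      ids[sel[k]] <- sample.int(vocab$size, 1L) - 1L
    } # else keep the original token
  }
  list(ids = ids, positions = sel, targets = targets)
}

#' Build next-sentence-prediction pairs from a sentence-segmented corpus
#'
#' Takes every consecutive sentence pair within each document as a
#' candidate. Half of the candidates (to within one pair) keep their true
#' continuation and are labeled `IsNext`; the other half have the second
#' sentence replaced by a sentence drawn from a different document and are
#' labeled `NotNext`. Uses the current RNG state.
#'
#' @param docs list of character vectors (the sentences of each document).
#' @param n_pairs optional cap on the number of pairs returned.
#' @return a data.frame with columns `a`, `b`, `is_next` (logical) and
#'   `doc` (source document of sentence a).
#' @export
make_nsp_pairs <- function(docs, n_pairs = NULL) {
  if (length(docs) < 2L) {
    stop("next-sentence pairs need at least two documents so a replacement can come from elsewhere",
         call. = FALSE)
  }
  cand <- do.call(rbind, lapply(seq_along(docs), function(d) {
    s <- docs[[d]]
    if (length(s) < 2L) return(NULL)
    data.frame(a = s[-length(s)], b = s[-1L], doc = d, stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || !nrow(cand)) {
    stop("no consecutive sentence pair available", call. = FALSE)
  }
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  if (!is.null(n_pairs)) cand <- cand[seq_len(min(n_pairs, nrow(cand))), , drop = FALSE]
  n <- nrow(cand)
  # alternate labels so |IsNext| - |NotNext| <= 1 regardless of n
  is_next <- rep(c(TRUE, FALSE), length.out = n)
  for (i in which(!is_next)) {
    other <- setdiff(seq_along(docs), cand$doc[i])
    other <- other[lengths(docs)[other] > 0L]
    src <- if (length(other) == 1L) other else sample(other, 1L)
    sent <- docs[[src]]
    cand$b[i] <- if (length(sent) == 1L) sent else sample(sent, 1L)
  }
  cand$is_next <- is_next
  rownames(cand) <- NULL
  cand
}

# MLM + NSP heads. The masked-token decoder applies a transform block
# (dense + GELU + layer normalization) to the masked positions' hidden
# states, then a decoder tied to the token embedding table plus a per-token
# output bias; the transform decouples the stack's output space from the
# embedding space so the same hidden states can also serve the
# next-sentence objective, whose logits come off the pooled [CLS] vector.
init_pretrain_heads <- function(config, seed = 1L) {
  with_seed(seed, list(mlm_W = tn_mat(config$H, config$H),
                       mlm_tb = numeric(config$H),
                       mlm_ln_g = rep(1, config$H),
                       mlm_ln_b = numeric(config$H),
                       mlm_b = numeric(config$V),
                       nsp_W = tn_mat(config$H, 2L),
                       nsp_b = numeric(2L)))
}

# forward + backward for one pretraining example; returns losses and grads.
# Each objective runs its own forward pass: the masked-token objective sees
# the corrupted sequence, the next-sentence objective the intact pair (the
# 15% token corruption otherwise erases much of the cross-segment evidence
# the next-sentence decision rests on at miniature scale).
pretrain_example_grads <- function(seq, masked, is_next, params, heads,
                                   config, training = TRUE, nsp_weight = 1) {
  mseq <- seq
  mseq$ids <- masked$ids
  enc <- encode(mseq, params, config, training = training, keep_cache = TRUE)
  hm <- enc$hidden[masked$positions, , drop = FALSE]
  Zt <- add_bias(hm %*% heads$mlm_W, heads$mlm_tb)
  Ut <- gelu(Zt)
  lt <- ln_forward(Ut, heads$mlm_ln_g, heads$mlm_ln_b)
  logits <- add_bias(lt$out %*% t(params$tok), heads$mlm_b)
  probs <- softmax_rows(logits)
  nm <- length(masked$positions)
  tgt <- cbind(seq_len(nm), masked$targets + 1L)
  mlm_loss <- mean(-safe_log(probs[tgt]))
  dlog <- probs
  dlog[tgt] <- dlog[tgt] - 1
  dlog <- dlog / nm
  dlt <- dlog %*% params$tok
  g_tok_head <- t(dlog) %*% lt$out
  g_mlm_b <- colSums(dlog)
  bl <- ln_backward(dlt, lt, heads$mlm_ln_g)
  dUt <- bl$dx
  dZt <- dUt * gelu_grad(Zt)
  dhm <- dZt %*% t(heads$mlm_W)
  g_mlm_W <- t(hm) %*% dZt
  g_mlm_tb <- colSums(dZt)
  dhidden <- matrix(0, nrow(enc$hidden), config$H)
  dhidden[masked$positions, ] <- dhm
  g_enc <- encode_backward(dhidden, NULL, params, config, enc$cache)
  g_enc$tok <- g_enc$tok + g_tok_head
  # NSP on the intact pair
  enc_c <- encode(seq, params, config, training = training, keep_cache = TRUE)
  zn <- drop(enc_c$pooled %*% heads$nsp_W) + heads$nsp_b
  pn <- exp(zn - max(zn)); pn <- pn / sum(pn)
  cls <- if (is_next) 1L else 2L
  nsp_loss <- -safe_log(pn[cls])
  dzn <- (pn - (seq_len(2L) == cls)) * nsp_weight
  g_nsp_W <- enc_c$pooled %o% dzn
  g_nsp_b <- dzn
  dpooled <- drop(heads$nsp_W %*% dzn)
  g_enc_nsp <- encode_backward(NULL, dpooled, params, config, enc_c$cache)
  list(mlm_loss = mlm_loss, nsp_loss = nsp_loss,
       nsp_correct = (which.max(pn) == cls),
       g_enc = g_enc, g_enc_nsp = g_enc_nsp,
       g_heads = list(mlm_W = g_mlm_W, mlm_tb = g_mlm_tb,
                      mlm_ln_g = bl$dg, mlm_ln_b = bl$db,
                      mlm_b = g_mlm_b, nsp_W = g_nsp_W, nsp_b = g_nsp_b))
}

#' Pre-train an encoder with masked-token and next-sentence objectives
#'
#' Builds next-sentence pairs fresh each epoch, encodes them, corrupts
#' tokens under the masking policy, and minimizes the summed masked-token
#' and next-sentence cross-entropies with Adam. Deterministic given `seed`.
#'
#' @param docs list of character vectors: the sentence-segmented corpus.
#' @param vocab a [wordpiece_vocab].
#' @param config an [encoder_config] with `V == vocab$size`.
#' @param epochs,batch_size,lr,max_len training schedule.
#' @param policy a [mask_policy].
#' @param nsp_weight relative weight of the next-sentence gradient in the
#'   combined objective (default 1: the plain sum of the two
#'   cross-entropies). At miniature scale the masked-token term dominates
#'   the gradient by almost an order of magnitude; a weight of a few
#'   rebalances the two tasks.
#' @param pairs_per_epoch optional cap on pairs used per epoch.
#' @param seed integer seed governing initialization, pairing, masking and
#'   dropout.
#' @param verbose print per-epoch losses.
#' @return an object of class `medrex_pretrain`: `params`, `heads`,
#'   `config`, and a `history` data.frame (per-epoch MLM, NSP and combined
#'   loss and NSP accuracy).
#' @export
pretrain <- function(docs, vocab, config, epochs = 3L, batch_size = 16L,
                     lr = 1e-3, max_len = 64L, policy = mask_policy(),
                     nsp_weight = 1, pairs_per_epoch = NULL, seed = 1L,
                     verbose = FALSE) {
  if (config$V != vocab$size) {
    stop(sprintf("config V (%d) does not match vocabulary size (%d)",
                 config$V, vocab$size), call. = FALSE)
  }
  params <- init_encoder_params(config, seed = derive_seed(seed, "init"))
  heads <- init_pretrain_heads(config, seed = derive_seed(seed, "heads"))
  # the two objectives take alternating updates with separate moment
  # estimates: the masked-token gradient is an order of magnitude larger
  # and its noise would otherwise swamp the next-sentence signal in the
  # shared parameters' second moments
  opt_p <- adam_state(params)
  opt_p_nsp <- adam_state(params)
  opt_h <- adam_state(heads)
  history <- data.frame(epoch = integer(), mlm = numeric(), nsp = numeric(),
                        loss = numeric(), nsp_accuracy = numeric())
  with_seed(derive_seed(seed, "pretrain"), {
    for (ep in seq_len(epochs)) {
      pairs <- make_nsp_pairs(docs, n_pairs = pairs_per_epoch)
      n <- nrow(pairs)
      mlm_sum <- 0; nsp_sum <- 0; nsp_ok <- 0
      for (b0 in seq(1L, n, by = batch_size)) {
        idx <- b0:min(b0 + batch_size - 1L, n)
        g_enc <- NULL; g_nsp <- NULL; g_heads <- NULL
        for (i in idx) {
          seq <- encode_pair(pairs$a[i], pairs$b[i], vocab, max_len)
          masked <- mask_tokens(seq, vocab, policy)
          r <- pretrain_example_grads(seq, masked, pairs$is_next[i],
                                      params, heads, config,
                                      nsp_weight = nsp_weight)
          if (!is.finite(r$mlm_loss) || !is.finite(r$nsp_loss)) {
            stop(sprintf("pretraining diverged (non-finite loss at epoch %d)", ep),
                 call. = FALSE)
          }
          mlm_sum <- mlm_sum + r$mlm_loss
          nsp_sum <- nsp_sum + r$nsp_loss
          nsp_ok <- nsp_ok + r$nsp_correct
          g_enc <- if (is.null(g_enc)) r$g_enc else tree_add(g_enc, r$g_enc)
          g_nsp <- if (is.null(g_nsp)) r$g_enc_nsp else tree_add(g_nsp, r$g_enc_nsp)
          g_heads <- if (is.null(g_heads)) r$g_heads else tree_add(g_heads, r$g_heads)
        }
        g_enc <- clip_global_norm(tree_scale(g_enc, 1 / length(idx)), 1.0)
        g_nsp <- clip_global_norm(tree_scale(g_nsp, 1 / length(idx)), 1.0)
        g_heads <- clip_global_norm(tree_scale(g_heads, 1 / length(idx)), 1.0)
        if (lr > 0) {
          st <- adam_step(unclass(params), g_enc, opt_p, lr)
          opt_p <- st$state
          st <- adam_step(st$params, g_nsp, opt_p_nsp, lr)
          params <- structure(st$params, class = "encoder_params")
          opt_p_nsp <- st$state
          st <- adam_step(heads, g_heads, opt_h, lr)
          heads <- st$params
          opt_h <- st$state
        }
      }
      history <- rbind(history, data.frame(
        epoch = ep, mlm = mlm_sum / n, nsp = nsp_sum / n,
        loss = (mlm_sum + nsp_sum) / n, nsp_accuracy = nsp_ok / n))
      if (verbose) {
        message(sprintf("epoch %d: mlm %.4f nsp %.4f (acc %.3f)",
                        ep, mlm_sum / n, nsp_sum / n, nsp_ok / n))
      }
    }
  })
  structure(list(params = params, heads = heads, config = config,
                 vocab = vocab, history = history),
            class = "medrex_pretrain")
}

#' @export
print.medrex_pretrain <- function(x, ...) {
  cat(sprintf("<medrex_pretrain: L=%d H=%d A=%d, %d epochs>\n",
              x$config$L, x$config$H, x$config$A, nrow(x$history)))
  print(x$history, row.names = FALSE)
  invisible(x)
}

#' Masked-token and next-sentence evaluation on held-out pairs
#'
#' Scores a pretrained encoder on fresh pairs in evaluation mode: mean
#' masked-token cross-entropy (and its exp, the perplexity) and
#' next-sentence accuracy.
#'
#' @param pt a `medrex_pretrain` object.
#' @param docs held-out sentence-segmented documents.
#' @param max_len encoding length.
#' @param n_pairs number of evaluation pairs.
#' @param seed seed for pairing and masking.
#' @return named list: `mlm_ce`, `perplexity`, `nsp_accuracy`, `n`.
#' @export
evaluate_pretrain <- function(pt, docs, max_len = 64L, n_pairs = 100L,
                              seed = 1L) {
  with_seed(derive_seed(seed, "eval-pretrain"), {
    pairs <- make_nsp_pairs(docs, n_pairs = n_pairs)
    ce <- 0; ok <- 0; ntok <- 0
    for (i in seq_len(nrow(pairs))) {
      seq <- encode_pair(pairs$a[i], pairs$b[i], pt$vocab, max_len)
      masked <- mask_tokens(seq, pt$vocab, mask_policy())
      mseq <- seq; mseq$ids <- masked$ids
      enc <- encode(mseq, pt$params, pt$config)
      hm <- enc$hidden[masked$positions, , drop = FALSE]
      Ut <- gelu(add_bias(hm %*% pt$heads$mlm_W, pt$heads$mlm_tb))
      tr <- ln_forward(Ut, pt$heads$mlm_ln_g, pt$heads$mlm_ln_b)$out
      probs <- softmax_rows(add_bias(tr %*% t(pt$params$tok), pt$heads$mlm_b))
      ce <- ce + sum(-safe_log(probs[cbind(seq_along(masked$positions),
                                           masked$targets + 1L)]))
      ntok <- ntok + length(masked$positions)
      # the next-sentence probe scores the uncorrupted pair
      enc_clean <- encode(seq, pt$params, pt$config)
      zn <- drop(enc_clean$pooled %*% pt$heads$nsp_W) + pt$heads$nsp_b
      ok <- ok + (which.max(zn) == (if (pairs$is_next[i]) 1L else 2L))
    }
    list(mlm_ce = ce / ntok, perplexity = exp(ce / ntok),
         nsp_accuracy = ok / nrow(pairs), n = nrow(pairs))
  })
}
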