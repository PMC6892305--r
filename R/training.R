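# Fine-tuning: back-propagate classification-head error into the encoder,
# predict, and cross-validate.

#' Fine-tuning settings
#'
#' @param lr learning rate (default 5e-5).
#' @param head_lr learning rate for the freshly initialized head (defaults
#'   to `lr`; the head starts from random weights while the encoder is
#'   pre-trained, so a larger head rate is often appropriate).
#' @param batch_size mini-batch size.
#' @param max_len maximum encoded sequence length.
#' @param epochs training epochs (default 3).
#' @param head `"cnn"` (multi-filter 1d-CNN over token states) or
#'   `"linear"` (dense softmax over the pooled `[CLS]` state).
#' @param loss `"ranking"` (margin ranking over positive/negative pairs;
#'   binary tasks only) or `"cross_entropy"`.
#' @param freeze_encoder keep encoder parameters fixed (feature-extraction
#'   mode); only the head trains.
#' @param cnn a [cnn_config] for the CNN head.
#' @param all_pairs pair every positive with every negative within a batch
#'   instead of shuffled index pairing.
#' @param clip global gradient-norm clip.
#' @param seed integer seed (shuffling, dropout, head initialization).
#' @return a list of class `finetune_config`.
#' @export
finetune_config <- function(lr = 5e-5, head_lr = lr, batch_size = 16L,
                            max_len = 128L,
                            epochs = 3L, head = c("cnn", "linear"),
                            loss = c("ranking", "cross_entropy"),
                            freeze_encoder = FALSE, cnn = cnn_config(),
                            all_pairs = FALSE, clip = 1.0, seed = 1L) {
  head <- match.arg(head)
  loss <- match.arg(loss)
  stopifnot(lr > 0, head_lr > 0, batch_size >= 1, epochs >= 1, max_len >= 5)
  structure(list(lr = lr, head_lr = head_lr, batch_size = as.integer(batch_size),
                 max_len = as.integer(max_len), epochs = as.integer(epochs),
                 head = head, loss = loss, freeze_encoder = freeze_encoder,
                 cnn = cnn, all_pairs = all_pairs, clip = clip,
                 seed = as.integer(seed)),
            class = "finetune_config")
}

# forward pass through encoder + head for one encoded sequence
model_forward <- function(seq, enc_params, config, head_type, head_params,
                          cnn_cfg, head_dropout, training = FALSE,
                          keep_cache = FALSE) {
  enc <- encode(seq, enc_params, config, training = training,
                keep_cache = keep_cache)
  if (head_type == "cnn") {
    cp <- conv_pool(enc$hidden, seq$mask, head_params, cnn_cfg,
                    keep_cache = keep_cache)
    cl <- classify(cp$features, head_params, dropout = head_dropout,
                   training = training, keep_cache = keep_cache)
    list(probs = cl$probs, enc = enc, cp = cp, cl = cl)
  } else {
    cl <- linear_head(enc$pooled, head_params, dropout = head_dropout,
                      training = training, keep_cache = keep_cache)
    list(probs = cl$probs, enc = enc, cl = cl)
  }
}

# backward from dlogits; returns head grads and (unless frozen) encoder grads
model_backward <- function(dlogits, fwd, enc_params, config, head_type,
                           head_params, cnn_cfg, freeze_encoder) {
  cb <- classify_backward(dlogits, head_params, fwd$cl$cache)
  if (head_type == "cnn") {
    cpb <- conv_pool_backward(cb$dfeat, head_params, cnn_cfg, fwd$cp$cache,
                              config$H)
    g_head <- list(filters = cpb$grads$filters, fc_W = cb$gW, fc_b = cb$gb)
    dhidden <- cpb$dX
    dpooled <- NULL
  } else {
    g_head <- list(fc_W = cb$gW, fc_b = cb$gb)
    dhidden <- NULL
    dpooled <- cb$dfeat
  }
  g_enc <- NULL
  if (!freeze_encoder) {
    g_enc <- encode_backward(dhidden, dpooled, enc_params, config, fwd$enc$cache)
  }
  list(g_head = g_head, g_enc = g_enc)
}

encode_samples <- function(samples, vocab, max_len) {
  lapply(seq_len(nrow(samples)), function(i) {
    encode_pair(samples$sentence_a[i], samples$sentence_b[i], vocab, max_len)
  })
}

#' Fine-tune a pre-trained encoder on labeled sentence-pair samples
#'
#' Restores the encoder from `pretrained`, attaches a freshly initialized
#' classification head, and trains with Adam. With the ranking loss,
#' positives and negatives are paired within each mini-batch by shuffled
#' index (cycling the shorter side); a single-class batch falls back to
#' cross-entropy for that step. When `freeze_encoder` is `TRUE` the encoder
#' parameters are bit-identical after training; otherwise head error
#' back-propagates through every layer into the embedding tables.
#'
#' @param pretrained a `medrex_pretrain` object, the result of
#'   [load_checkpoint], or any list with `params` (`encoder_params`),
#'   `config` ([encoder_config]) and `vocab` ([wordpiece_vocab]).
#' @param train data.frame of samples (`sentence_a`, `sentence_b`, `label`).
#' @param dev optional held-out samples evaluated each epoch.
#' @param cfg a [finetune_config].
#' @param verbose print per-epoch progress.
#' @return an object of class `medrex_model`.
#' @export
finetune <- function(pretrained, train, dev = NULL, cfg = finetune_config(),
                     verbose = FALSE) {
  enc_params <- pretrained$params
  config <- pretrained$config
  vocab <- pretrained$vocab
  if (is.null(enc_params) || is.null(config) || is.null(vocab)) {
    stop("pretrained must carry params, config and vocab", call. = FALSE)
  }
  if (config$V != vocab$size) {
    stop(sprintf("encoder vocabulary size (%d) does not match tokenizer vocabulary (%d)",
                 config$V, vocab$size), call. = FALSE)
  }
  if (config$P < cfg$max_len) {
    stop(sprintf("encoder supports %d positions but max_len is %d",
                 config$P, cfg$max_len), call. = FALSE)
  }
  label_set <- sort(unique(train$label))
  if (!is.null(dev) && nrow(dev) && !all(dev$label %in% label_set)) {
    stop("dev set contains labels unseen in training", call. = FALSE)
  }
  if (cfg$loss == "ranking" && length(label_set) != 2L) {
    stop("the ranking loss applies to binary tasks; use loss = 'cross_entropy'",
         call. = FALSE)
  }
  n_classes <- length(label_set)
  pos_class <- if ("1" %in% label_set) match("1", label_set) else n_classes
  head_dropout <- if (cfg$head == "cnn") cfg$cnn$dropout else 0.5
  head_params <- if (cfg$head == "cnn") {
    init_cnn_params(cfg$cnn, config$H, n_classes,
                    seed = derive_seed(cfg$seed, "head"))
  } else {
    init_linear_params(config$H, n_classes, seed = derive_seed(cfg$seed, "head"))
  }
  y <- match(train$label, label_set)
  seqs <- encode_samples(train, vocab, cfg$max_len)
  opt_h <- adam_state(head_params)
  opt_e <- if (!cfg$freeze_encoder) adam_state(enc_params) else NULL
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        dev_precision = numeric(), dev_recall = numeric(),
                        dev_f1 = numeric())
  model_env <- new.env(parent = emptyenv())

  with_seed(derive_seed(cfg$seed, "finetune"), {
    n <- nrow(train)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      loss_sum <- 0; loss_n <- 0
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        fwds <- lapply(idx, function(i) {
          model_forward(seqs[[i]], enc_params, config, cfg$head, head_params,
                        cfg$cnn, head_dropout, training = TRUE,
                        keep_cache = TRUE)
        })
        probs <- do.call(rbind, lapply(fwds, `[[`, "probs"))
        yb <- y[idx]
        B <- length(idx)
        dlogits_list <- vector("list", B)
        if (cfg$loss == "ranking" &&
            length(unique(yb)) == 2L) {
          gpos <- probs[, pos_class]
          pp <- which(yb == pos_class)
          nn <- which(yb != pos_class)
          pairs <- rank_pairs(pp, nn, all_pairs = cfg$all_pairs)
          margins <- 1 - gpos[pairs$pos] + gpos[pairs$neg]
          active <- margins > 0
          loss <- sum(pmax(0, margins)) / nrow(pairs)
          dg <- numeric(B)
          for (r in which(active)) {
            dg[pairs$pos[r]] <- dg[pairs$pos[r]] - 1
            dg[pairs$neg[r]] <- dg[pairs$neg[r]] + 1
          }
          dg <- dg / nrow(pairs)
          for (j in seq_len(B)) {
            if (dg[j] != 0) {
              p <- probs[j, ]
              dgdz <- p[pos_class] * ((seq_len(n_classes) == pos_class) - p)
              dlogits_list[[j]] <- dg[j] * dgdz
            } else {
              dlogits_list[[j]] <- numeric(n_classes)
            }
          }
        } else {
          # cross-entropy (multi-class, or single-class ranking batch)
          loss <- mean(-safe_log(probs[cbind(seq_len(B), yb)]))
          for (j in seq_len(B)) {
            dlogits_list[[j]] <- ce_dlogits(probs[j, ], yb[j]) / B
          }
        }
        loss_sum <- loss_sum + loss; loss_n <- loss_n + 1
        g_head <- NULL; g_enc <- NULL
        for (j in seq_len(B)) {
          bk <- model_backward(dlogits_list[[j]], fwds[[j]], enc_params,
                               config, cfg$head, head_params, cfg$cnn,
                               cfg$freeze_encoder)
          g_head <- if (is.null(g_head)) bk$g_head else tree_add(g_head, bk$g_head)
          if (!cfg$freeze_encoder) {
            g_enc <- if (is.null(g_enc)) bk$g_enc else tree_add(g_enc, bk$g_enc)
          }
        }
        g_head <- clip_global_norm(g_head, cfg$clip)
        st <- adam_step(unclass(head_params), g_head, opt_h, cfg$head_lr)
        head_params <- structure(st$params, class = class(head_params))
        opt_h <- st$state
        if (!cfg$freeze_encoder) {
          g_enc <- clip_global_norm(g_enc, cfg$clip)
          st <- adam_step(unclass(enc_params), g_enc, opt_e, cfg$lr)
          enc_params <- structure(st$params, class = "encoder_params")
          opt_e <- st$state
        }
      }
      dev_m <- c(NA_real_, NA_real_, NA_real_)
      if (!is.null(dev) && nrow(dev)) {
        model_env$model <- new_medrex_model(enc_params, config, vocab, cfg,
                                            head_params, label_set, pos_class,
                                            history)
        pr <- predict(model_env$model, dev)
        dev_m <- unlist(score_predictions(dev$label, pr$label, label_set,
                                          pos_class))
      }
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = loss_sum / loss_n,
        dev_precision = dev_m[1], dev_recall = dev_m[2], dev_f1 = dev_m[3]))
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f dev F1 %s", ep,
                        loss_sum / loss_n,
                        ifelse(is.na(dev_m[3]), "-", sprintf("%.3f", dev_m[3]))))
      }
    }
  })
  new_medrex_model(enc_params, config, vocab, cfg, head_params, label_set,
                   pos_class, history)
}

new_medrex_model <- function(enc_params, config, vocab, cfg, head_params,
                             label_set, pos_class, history) {
  structure(list(params = enc_params, config = config, vocab = vocab,
                 finetune = cfg, head_params = head_params,
                 label_set = label_set, pos_class = pos_class,
                 history = history),
            class = "medrex_model")
}

# positive-class P/R/F1 for binary label sets, micro average otherwise
score_predictions <- function(gold, pred, label_set, pos_class) {
  cc <- confusion(gold, pred, label_set)
  if (length(label_set) == 2L) {
    rep_ <- prf(cc)
    i <- match(label_set[pos_class], rep_$label)
    list(precision = rep_$precision[i], recall = rep_$recall[i], f1 = rep_$f1[i])
  } else {
    mi <- micro_average(cc)
    list(precision = mi[["precision"]], recall = mi[["recall"]],
         f1 = mi[["f1"]])
  }
}

#' @export
print.medrex_model <- function(x, ...) {
  cat(sprintf("<medrex_model: %s head, %s loss, %d classes (%s)>\n",
              x$finetune$head, x$finetune$loss, length(x$label_set),
              paste(x$label_set, collapse = ", ")))
  cat(sprintf("  encoder: L=%d H=%d A=%d%s\n", x$config$L, x$config$H,
              x$config$A, if (x$finetune$freeze_encoder) " (frozen)" else ""))
  if (nrow(x$history)) {
    cat(sprintf("  final train loss %.4f%s\n",
                utils::tail(x$history$train_loss, 1),
                if (!is.na(utils::tail(x$history$dev_f1, 1))) {
                  sprintf(", dev F1 %.3f", utils::tail(x$history$dev_f1, 1))
                } else ""))
  }
  invisible(x)
}

#' @export
summary.medrex_model <- function(object, ...) {
  print(object)
  cat("\ntraining history:\n")
  print(object$history, row.names = FALSE)
  invisible(object$history)
}

#' Predict labels and class scores for sentence-pair samples
#'
#' Evaluation-mode forward pass (no dropout): deterministic. Labels are the
#' argmax of the class distribution.
#'
#' @param object a `medrex_model`.
#' @param newdata data.frame with `sentence_a` and `sentence_b` (and
#'   optionally `instance_id`).
#' @param ... unused.
#' @return data.frame with `instance_id`, `label`, and one `score_<class>`
#'   column per class (each row's scores sum to 1).
#' @export
predict.medrex_model <- function(object, newdata, ...) {
  seqs <- encode_samples(newdata, object$vocab, object$finetune$max_len)
  head_dropout <- if (object$finetune$head == "cnn") object$finetune$cnn$dropout else 0.5
  probs <- do.call(rbind, lapply(seqs, function(s) {
    model_forward(s, object$params, object$config, object$finetune$head,
                  object$head_params, object$finetune$cnn, head_dropout,
                  training = FALSE)$probs
  }))
  colnames(probs) <- paste0("score_", object$label_set)
  out <- data.frame(
    instance_id = newdata$instance_id %||% sprintf("s%d", seq_len(nrow(newdata))),
    label = object$label_set[max.col(probs, ties.method = "first")],
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(probs))
}

#' Stratified k-fold cross-validation
#'
#' Splits samples into k folds (sizes differing by at most one,
#' stratified by label where class sizes allow; a class with fewer than k
#' members relaxes stratification with a warning), trains on k-1 folds and
#' scores the held-out fold, so every sample is tested exactly once.
#'
#' @param samples data.frame of labeled sentence-pair samples.
#' @param k number of folds (>= 2).
#' @param pretrained encoder to restore for each fold (see [finetune]).
#' @param cfg a [finetune_config].
#' @param seed fold-assignment seed.
#' @param trainer optional `function(train_samples)` returning an object
#'   with a `predict` method (defaults to [finetune] with `pretrained` and
#'   `cfg`); lets tests exercise the fold mechanics with a cheap model.
#' @return list with `folds` (per-fold data.frame of precision/recall/F1),
#'   `mean`, `variance`, and `assignment` (fold index per sample).
#' @export
cross_validate <- function(samples, k = 5L, pretrained = NULL,
                           cfg = finetune_config(), seed = 1L,
                           trainer = NULL) {
  stopifnot(k >= 2, nrow(samples) >= k)
  label_set <- sort(unique(samples$label))
  small <- names(which(table(samples$label) < k))
  if (length(small)) {
    warning(sprintf("class(es) %s have fewer than %d members; stratification relaxed",
                    paste(small, collapse = ", "), k), call. = FALSE)
  }
  fold <- integer(nrow(samples))
  with_seed(derive_seed(seed, "cv-folds"), {
    counter <- 0L
    for (lb in label_set) {
      members <- which(samples$label == lb)
      members <- members[sample.int(length(members))]
      for (m in members) {
        fold[m] <- counter %% k + 1L
        counter <- counter + 1L
      }
    }
  })
  if (is.null(trainer)) {
    if (is.null(pretrained)) stop("supply pretrained or a trainer", call. = FALSE)
    trainer <- function(tr) finetune(pretrained, tr, dev = NULL, cfg = cfg)
  }
  pos_class <- if ("1" %in% label_set) match("1", label_set) else length(label_set)
  per_fold <- lapply(seq_len(k), function(f) {
    fit <- trainer(samples[fold != f, , drop = FALSE])
    pr <- predict(fit, samples[fold == f, , drop = FALSE])
    m <- score_predictions(samples$label[fold == f], pr$label, label_set, pos_class)
    data.frame(fold = f, n = sum(fold == f), precision = m$precision,
               recall = m$recall, f1 = m$f1)
  })
  folds <- do.call(rbind, per_fold)
  mstat <- colMeans(folds[c("precision", "recall", "f1")])
  vstat <- apply(folds[c("precision", "recall", "f1")], 2, stats::var)
  list(folds = folds, mean = mstat, variance = vstat, assignment = fold)
}
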