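# The miniature end-to-end benchmark: fixed desk-scale study conditions
# under which the full pipeline (synthesis, vocabulary, pretraining,
# fine-tuning, evaluation) runs on one CPU in minutes.

#' Miniature benchmark conditions
#'
#' The fixed configuration of the package's end-to-end benchmark: a
#' synthetic relation corpus at the generator defaults, a fact-aware
#' pretraining corpus of 60 documents x 10 sentences, a 600-piece
#' vocabulary, an L=2 / H=64 / A=2 encoder (feed-forward 256, 96
#' positions), 25 pretraining epochs (batch 16, Adam 1e-3, 32-token
#' pairs), and fine-tuning of 500 labeled instances (350 train / 150 held
#' out, 80-token sequences, batch 16, 5 epochs) with the 3/4/5 x 100-map
#' CNN head, ranking loss, encoder rate 3e-4 and head rate 3e-3.
#'
#' @param seed integer seed; every stage derives its own stream from it.
#' @return a named list of the condition objects.
#' @export
miniature_conditions <- function(seed = 11L) {
  list(seed = as.integer(seed),
       synth = synth_config(seed = seed),
       pretrain_docs = 60L, pretrain_sentences = 10L,
       vocab_size = 600L,
       L = 2L, H = 64L, A = 2L, F = 256L, P = 96L, encoder_dropout = 0.1,
       pretrain_epochs = 25L, pretrain_batch = 16L, pretrain_lr = 1e-3,
       pretrain_max_len = 32L,
       n_instances = 500L, n_train = 350L,
       finetune_lr = 3e-4, finetune_head_lr = 3e-3, finetune_batch = 16L,
       finetune_max_len = 80L, finetune_epochs = 5L,
       cnn = cnn_config(c(3L, 4L, 5L), 100L, 0.5))
}

#' Materialize the benchmark corpus and instance split
#'
#' Generates the relation corpus, the balanced labeled instances, the
#' pretraining text and the vocabulary, and draws the benchmark's
#' train/held-out split.
#'
#' @param cond a [miniature_conditions] list.
#' @return list with `docs`, `samples`, `train`, `dev`, `pre_docs`,
#'   `vocab`, `config` (the [encoder_config]).
#' @export
miniature_data <- function(cond = miniature_conditions()) {
  docs <- generate_relation_corpus(cond$synth)
  samples <- suppressWarnings(
    generate_samples(docs, generation_config(seed = cond$seed)))
  pre_docs <- generate_pretrain_corpus(cond$synth, n_docs = cond$pretrain_docs,
                                       sentences_per_doc = cond$pretrain_sentences)
  vocab <- build_vocab(c(unlist(pre_docs), samples$sentence_b),
                       target_size = cond$vocab_size)
  config <- encoder_config(L = cond$L, H = cond$H, A = cond$A, F = cond$F,
                           V = vocab$size, P = cond$P,
                           dropout = cond$encoder_dropout)
  idx <- with_seed(derive_seed(cond$seed, "benchmark-split"),
                   sample(nrow(samples), min(cond$n_instances, nrow(samples))))
  list(docs = docs, samples = samples,
       train = samples[idx[seq_len(cond$n_train)], , drop = FALSE],
       dev = samples[idx[-seq_len(cond$n_train)], , drop = FALSE],
       pre_docs = pre_docs, vocab = vocab, config = config)
}

#' Pre-train the benchmark encoder
#'
#' @param data a [miniature_data] list.
#' @param cond a [miniature_conditions] list.
#' @return a `medrex_pretrain` object.
#' @export
miniature_pretrain <- function(data, cond = miniature_conditions()) {
  pretrain(data$pre_docs, data$vocab, data$config,
           epochs = cond$pretrain_epochs, batch_size = cond$pretrain_batch,
           lr = cond$pretrain_lr, max_len = cond$pretrain_max_len,
           seed = derive_seed(cond$seed, "benchmark-pretrain"))
}

#' Benchmark fine-tuning configuration
#'
#' @param cond a [miniature_conditions] list.
#' @param seed fine-tuning seed (shuffling, dropout, head init).
#' @param freeze_encoder train the head only.
#' @return a [finetune_config].
#' @export
miniature_finetune_config <- function(cond = miniature_conditions(),
                                      seed = 1L, freeze_encoder = FALSE) {
  finetune_config(lr = cond$finetune_lr, head_lr = cond$finetune_head_lr,
                  batch_size = cond$finetune_batch,
                  max_len = cond$finetune_max_len,
                  epochs = cond$finetune_epochs, head = "cnn",
                  loss = "ranking", freeze_encoder = freeze_encoder,
                  cnn = cond$cnn, seed = seed)
}
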