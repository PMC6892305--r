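# Run configuration (defaults <- config file <- overrides), the pipeline
# driver, and reproducibility manifests.

#' Default run configuration
#'
#' The documented defaults: CNN filter windows 3/4/5 with 100 maps each,
#' dropout 0.5, learning rate 5e-5, a 1:1 negative ratio, and a miniature
#' encoder geometry suitable for desk-scale pretraining.
#'
#' @return a named list.
#' @export
medrex_defaults <- function() {
  list(
    # sample generation
    neg_ratio = 1, pair_type1 = "Chemical", pair_type2 = "Disease",
    # tokenizer / vocabulary
    vocab_size = 2000, lowercase = TRUE,
    # encoder geometry
    layers = 2, hidden = 64, heads = 2, ffn = 256, max_positions = 96,
    encoder_dropout = 0.1,
    # pretraining
    pretrain_epochs = 25, pretrain_batch_size = 16, pretrain_lr = 1e-3,
    pretrain_max_len = 32,
    # fine-tuning
    lr = 5e-5, batch_size = 16, max_len = 80, epochs = 5,
    head = "cnn", loss = "ranking", freeze_encoder = FALSE,
    windows = c(3, 4, 5), maps = 100, dropout = 0.5,
    # synthesis
    synth_docs = 150, rel_prob = 0.3, preset = "easy",
    # global
    seed = 1, dev_fraction = 0.3
  )
}

#' Load a run configuration
#'
#' Precedence: package defaults, then the YAML config file, then explicit
#' overrides (e.g. command-line flags). Unknown keys are an error (no
#' silently ignored typos); values must match the type of the default.
#'
#' @param path optional YAML file of settings.
#' @param overrides named list applied last.
#' @return the fully resolved configuration list (class `run_config`).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- medrex_defaults()
  apply_layer <- function(cfg, layer, origin) {
    for (key in names(layer)) {
      if (!key %in% names(cfg)) {
        stop(sprintf("unknown configuration key '%s' (%s)", key, origin),
             call. = FALSE)
      }
      val <- layer[[key]]
      if (is.numeric(cfg[[key]]) && !is.numeric(val)) {
        stop(sprintf("configuration key '%s' must be numeric (%s)", key, origin),
             call. = FALSE)
      }
      if (is.character(cfg[[key]]) && !is.character(val)) {
        stop(sprintf("configuration key '%s' must be character (%s)", key, origin),
             call. = FALSE)
      }
      if (is.logical(cfg[[key]]) && !is.logical(val)) {
        stop(sprintf("configuration key '%s' must be logical (%s)", key, origin),
             call. = FALSE)
      }
      cfg[[key]] <- val
    }
    cfg
  }
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    if (!is.null(file_cfg)) cfg <- apply_layer(cfg, file_cfg, path)
  }
  cfg <- apply_layer(cfg, overrides, "override")
  structure(cfg, class = c("run_config", "list"))
}

run_encoder_config <- function(cfg, vocab_size) {
  encoder_config(L = cfg$layers, H = cfg$hidden, A = cfg$heads, F = cfg$ffn,
                 V = vocab_size, P = cfg$max_positions,
                 dropout = cfg$encoder_dropout)
}

run_finetune_config <- function(cfg) {
  finetune_config(lr = cfg$lr, batch_size = cfg$batch_size,
                  max_len = cfg$max_len, epochs = cfg$epochs,
                  head = cfg$head, loss = cfg$loss,
                  freeze_encoder = cfg$freeze_encoder,
                  cnn = cnn_config(cfg$windows, cfg$maps, cfg$dropout),
                  seed = derive_seed(cfg$seed, "finetune-cfg"))
}

write_manifest <- function(dir, command, cfg, inputs = character(),
                           metrics = list()) {
  lines <- c(sprintf("command: %s", command),
             sprintf("seed: %d", cfg$seed),
             sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  for (key in sort(names(cfg))) {
    lines <- c(lines, sprintf("config.%s: %s", key,
                              paste(cfg[[key]], collapse = ",")))
  }
  for (f in inputs) {
    if (file.exists(f) && !dir.exists(f)) {
      lines <- c(lines, sprintf("input.%s: md5=%s", basename(f),
                                unname(tools::md5sum(f))))
    }
  }
  for (key in names(metrics)) {
    lines <- c(lines, sprintf("metric.%s: %s", key,
                              paste(format(metrics[[key]], digits = 6),
                                    collapse = ",")))
  }
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(lines)
}

split_train_dev <- function(samples, dev_fraction, seed) {
  n <- nrow(samples)
  n_dev <- max(1L, round(dev_fraction * n))
  dev_idx <- with_seed(derive_seed(seed, "split"), sample.int(n, n_dev))
  list(train = samples[-dev_idx, , drop = FALSE],
       dev = samples[dev_idx, , drop = FALSE])
}

samples_to_instances <- function(samples) {
  relation_instances(instance_id = samples$instance_id,
                     name1 = sub(" .*$", "", samples$sentence_a),
                     id1 = samples$id1,
                     name2 = sub("^[^ ]+ ", "", samples$sentence_a),
                     id2 = samples$id2, label = samples$label,
                     context = samples$sentence_b)
}

instances_to_samples <- function(instances) {
  new_samples(instance_id = instances$instance_id,
              sentence_a = paste(instances$name1, instances$name2),
              sentence_b = instances$context, label = instances$label,
              id1 = instances$id1, id2 = instances$id2,
              doc_id = instances$instance_id)
}

#' Run one pipeline stage
#'
#' Commands: `synth` (write a synthetic PubTator corpus and pretraining
#' text), `prepare` (PubTator corpus to balanced train/dev instance TSVs),
#' `pretrain` (build a vocabulary and pretrain an encoder checkpoint),
#' `finetune` (train a classifier from a checkpoint and instance TSVs),
#' `evaluate` (gold vs predicted instance TSVs to a metric report),
#' `predict` (apply a fine-tuned model). Every stage writes its outputs plus
#' a `manifest.txt` recording the configuration, seed, input digests and
#' summary metrics into `out_dir`; outputs are staged in a temporary
#' directory and moved into place only on success, and inputs are never
#' mutated.
#'
#' @param command one of the stage names above.
#' @param cfg a [load_config] result.
#' @param inputs named character vector of input paths; stages use the names
#'   `corpus`, `pretrain_text`, `checkpoint`, `train`, `dev`, `gold`,
#'   `pred`, `model`, `instances` as applicable.
#' @param out_dir output directory for the stage.
#' @return invisibly, a named list of artifact paths and metrics.
#' @export
run <- function(command = c("synth", "prepare", "pretrain", "finetune",
                            "evaluate", "predict"),
                cfg = load_config(), inputs = character(), out_dir) {
  command <- match.arg(command)
  for (f in inputs) {
    if (!file.exists(f)) {
      stop(sprintf("%s: missing input '%s'", command, f), call. = FALSE)
    }
  }
  stage <- tempfile(paste0("medrex-", command, "-"))
  dir.create(stage, recursive = TRUE)
  ok <- FALSE
  on.exit({
    if (!ok) unlink(stage, recursive = TRUE)
  }, add = TRUE)
  result <- switch(
    command,
    synth = run_synth(cfg, stage),
    prepare = run_prepare(cfg, inputs, stage),
    pretrain = run_pretrain(cfg, inputs, stage),
    finetune = run_finetune(cfg, inputs, stage),
    evaluate = run_evaluate(cfg, inputs, stage),
    predict = run_predict(cfg, inputs, stage))
  write_manifest(stage, command, cfg, inputs, result$metrics %||% list())
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (f in list.files(stage, recursive = TRUE)) {
    dest <- file.path(out_dir, f)
    if (!dir.exists(dirname(dest))) dir.create(dirname(dest), recursive = TRUE)
    file.copy(file.path(stage, f), dest, overwrite = TRUE)
  }
  unlink(stage, recursive = TRUE)
  ok <- TRUE
  result$out_dir <- out_dir
  invisible(result)
}

run_synth <- function(cfg, stage) {
  scfg <- synth_config(
    n_docs = cfg$synth_docs, rel_prob = cfg$rel_prob,
    trigger_dropout = if (cfg$preset == "hard") 0.2 else 0,
    distractor_triggers = if (cfg$preset == "hard") c("measured", "screened") else character(),
    seed = derive_seed(cfg$seed, "synth"))
  docs <- generate_relation_corpus(scfg)
  write_pubtator(docs, file.path(stage, "corpus.pubtator"))
  pre <- generate_pretrain_corpus(scfg)
  writeLines(unlist(lapply(pre, function(d) c(d, ""))),
             file.path(stage, "pretrain.txt"))
  list(metrics = list(documents = length(docs),
                      relations = sum(vapply(docs, function(d) nrow(d$relations), numeric(1)))))
}

run_prepare <- function(cfg, inputs, stage) {
  docs <- read_pubtator(inputs[["corpus"]])
  gcfg <- generation_config(neg_per_pos = cfg$neg_ratio,
                            pair_rule = c(cfg$pair_type1, cfg$pair_type2),
                            lowercase = cfg$lowercase,
                            seed = derive_seed(cfg$seed, "samples"))
  samples <- generate_samples(docs, gcfg)
  sp <- split_train_dev(samples, cfg$dev_fraction, cfg$seed)
  write_instances_tsv(samples_to_instances(sp$train), file.path(stage, "train.tsv"))
  write_instances_tsv(samples_to_instances(sp$dev), file.path(stage, "dev.tsv"))
  balance <- table(samples$label)
  message(sprintf("prepare: %d samples (%s)", nrow(samples),
                  paste(sprintf("label %s: %d", names(balance), balance),
                        collapse = ", ")))
  list(metrics = list(n_train = nrow(sp$train), n_dev = nrow(sp$dev),
                      n_positive = sum(samples$label == "1"),
                      n_negative = sum(samples$label == "0")))
}

run_pretrain <- function(cfg, inputs, stage) {
  lines <- readLines(inputs[["pretrain_text"]], warn = FALSE)
  # blank lines separate documents
  docs <- split(lines[lines != ""], cumsum(lines == "")[lines != ""])
  docs <- unname(docs)
  vocab <- build_vocab(unlist(docs), target_size = cfg$vocab_size,
                       lowercase = cfg$lowercase)
  econf <- run_encoder_config(cfg, vocab$size)
  pt <- pretrain(docs, vocab, econf, epochs = cfg$pretrain_epochs,
                 batch_size = cfg$pretrain_batch_size, lr = cfg$pretrain_lr,
                 max_len = cfg$pretrain_max_len,
                 seed = derive_seed(cfg$seed, "pretrain"))
  ck <- file.path(stage, "checkpoint")
  save_checkpoint(pt$params, econf, ck, extra = list(heads = pt$heads))
  write_vocab(vocab, file.path(stage, "vocab.txt"))
  utils::write.table(pt$history, file.path(stage, "pretrain_history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(metrics = list(final_loss = utils::tail(pt$history$loss, 1),
                      nsp_accuracy = utils::tail(pt$history$nsp_accuracy, 1)))
}

run_finetune <- function(cfg, inputs, stage) {
  ck <- load_checkpoint(inputs[["checkpoint"]])
  vocab <- read_vocab(inputs[["vocab"]])
  train <- instances_to_samples(read_instances_tsv(inputs[["train"]]))
  dev <- if ("dev" %in% names(inputs)) {
    instances_to_samples(read_instances_tsv(inputs[["dev"]]))
  } else NULL
  pre <- list(params = ck$params, config = ck$config, vocab = vocab)
  model <- finetune(pre, train, dev, run_finetune_config(cfg))
  mdir <- file.path(stage, "model")
  save_checkpoint(model$params, model$config, mdir,
                  extra = list(head_params = model$head_params,
                               head = model$finetune$head,
                               label_set = model$label_set,
                               finetune = unclass(model$finetune)))
  write_vocab(vocab, file.path(mdir, "vocab.txt"))
  utils::write.table(model$history, file.path(stage, "history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dev_f1 <- utils::tail(model$history$dev_f1, 1)
  list(metrics = list(train_loss = utils::tail(model$history$train_loss, 1),
                      dev_f1 = if (is.na(dev_f1)) NULL else dev_f1),
       model = model)
}

run_evaluate <- function(cfg, inputs, stage) {
  gold <- read_instances_tsv(inputs[["gold"]])
  pred <- read_instances_tsv(inputs[["pred"]])
  m <- match(gold$instance_id, pred$instance_id)
  if (anyNA(m)) stop("prediction file lacks some gold instance ids", call. = FALSE)
  cc <- confusion(gold$label, pred$label[m])
  rep_ <- eval_report(cc, file.path(stage, "report.tsv"))
  mi <- micro_average(cc)
  list(metrics = as.list(mi), report = rep_)
}

run_predict <- function(cfg, inputs, stage) {
  ck <- load_checkpoint(inputs[["model"]])
  vocab <- read_vocab(file.path(inputs[["model"]], "vocab.txt"))
  fin <- ck$extra$finetune
  fcfg <- finetune_config(lr = fin$lr, batch_size = fin$batch_size,
                          max_len = fin$max_len, epochs = fin$epochs,
                          head = fin$head, loss = fin$loss,
                          freeze_encoder = fin$freeze_encoder,
                          cnn = cnn_config(fin$cnn$windows, fin$cnn$maps,
                                           fin$cnn$dropout),
                          seed = fin$seed)
  label_set <- unlist(ck$extra$label_set)
  pos_class <- if ("1" %in% label_set) match("1", label_set) else length(label_set)
  head_params <- ck$extra$head_params
  model <- new_medrex_model(ck$params, ck$config, vocab, fcfg, head_params,
                            label_set, pos_class, data.frame())
  inst <- read_instances_tsv(inputs[["instances"]])
  pr <- predict(model, instances_to_samples(inst))
  out <- inst
  out$label <- pr$label
  write_instances_tsv(out, file.path(stage, "predictions.tsv"))
  list(metrics = list(n = nrow(out)))
}
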