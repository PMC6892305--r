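# a tiny separable task: the label marks whether sentence A contains "alpha"
toy_task <- function(n = 200, seed = 3) {
  words <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta")
  vocab <- build_vocab(paste(words, collapse = " "), 60)
  cfg <- encoder_config(L = 1, H = 16, A = 2, F = 32, V = vocab$size, P = 16,
                        dropout = 0.1)
  set.seed(seed)
  a1 <- sample(words, n, TRUE)
  a2 <- sample(words, n, TRUE)
  samples <- data.frame(
    instance_id = sprintf("t%d", seq_len(n)),
    sentence_a = paste(a1, a2),
    sentence_b = replicate(n, paste(sample(words, 4, TRUE), collapse = " ")),
    label = ifelse(a1 == "alpha" | a2 == "alpha", "1", "0"),
    stringsAsFactors = FALSE)
  list(vocab = vocab, cfg = cfg, samples = samples,
       pre = list(params = init_encoder_params(cfg, 77), config = cfg,
                  vocab = vocab))
}

fast_cfg <- function(...) {
  finetune_config(lr = 1e-3, head_lr = 1e-2, batch_size = 16, max_len = 12,
                  epochs = 2, head = "cnn", loss = "cross_entropy",
                  cnn = cnn_config(c(2, 3), 8, 0.5), seed = 1, ...)
}

test_that("a frozen encoder is bit-identical after training; unfrozen moves", {
  tt <- toy_task(60)
  cfg <- fast_cfg(freeze_encoder = TRUE)
  cfg$epochs <- 1L
  m <- finetune(tt$pre, tt$samples[1:40, ], cfg = cfg)
  expect_identical(unclass(m$params), unclass(tt$pre$params))
  cfg$freeze_encoder <- FALSE
  m2 <- finetune(tt$pre, tt$samples[1:40, ], cfg = cfg)
  expect_false(identical(m2$params$tok, tt$pre$params$tok))
})

test_that("fine-tuning recovers a planted lexical signal and fits train at least as well as dev", {
  tt <- toy_task(240)
  tr <- tt$samples[1:180, ]; dv <- tt$samples[181:240, ]
  cfg <- fast_cfg()
  cfg$epochs <- 4L
  m <- finetune(tt$pre, tr, dv, cfg)
  dev_f1 <- utils::tail(m$history$dev_f1, 1)
  expect_gt(dev_f1, 0.9)
  pr_tr <- predict(m, tr)
  cc <- confusion(tr$label, pr_tr$label, m$label_set)
  train_f1 <- prf(cc)$f1[cc$label == "1"]
  expect_gte(train_f1 + 1e-9, dev_f1)
})

test_that("predictions are deterministic distributions with one label per sample", {
  tt <- toy_task(40)
  cfg <- fast_cfg(); cfg$epochs <- 1L
  m <- finetune(tt$pre, tt$samples[1:30, ], cfg = cfg)
  one <- predict(m, tt$samples[31, ])
  expect_equal(nrow(one), 1)
  expect_true(one$label %in% m$label_set)
  pr <- predict(m, tt$samples[31:40, ])
  scores <- as.matrix(pr[, grep("^score_", names(pr))])
  expect_equal(rowSums(scores), rep(1, 10), tolerance = 1e-9)
  expect_identical(pr, predict(m, tt$samples[31:40, ]))
})

test_that("a dev set with unseen labels or a non-binary ranking setup is refused", {
  tt <- toy_task(30)
  dv <- tt$samples[1:5, ]
  dv$label[1] <- "weird"
  expect_error(finetune(tt$pre, tt$samples[6:30, ], dv, fast_cfg()), "unseen")
  tr3 <- tt$samples[1:30, ]
  tr3$label <- rep(c("A", "B", "C"), 10)
  cfg <- fast_cfg(); cfg$loss <- "ranking"
  expect_error(finetune(tt$pre, tr3, cfg = cfg), "binary")
})

test_that("identical seeds give identical fine-tuned models", {
  tt <- toy_task(50)
  cfg <- fast_cfg(); cfg$epochs <- 1L
  m1 <- finetune(tt$pre, tt$samples, cfg = cfg)
  m2 <- finetune(tt$pre, tt$samples, cfg = cfg)
  expect_identical(unclass(m1$head_params), unclass(m2$head_params))
  expect_identical(m1$history, m2$history)
})

test_that("stratified folds partition the data with near-equal sizes", {
  tt <- toy_task(100)
  dummy_trainer <- function(tr) {
    maj <- names(which.max(table(tr$label)))
    structure(list(maj = maj), class = "majority_model")
  }
  assign("predict.majority_model",
         function(object, newdata, ...) {
           data.frame(instance_id = newdata$instance_id, label = object$maj,
                      stringsAsFactors = FALSE)
         }, envir = globalenv())
  on.exit(rm("predict.majority_model", envir = globalenv()), add = TRUE)
  cv <- cross_validate(tt$samples, k = 5, trainer = dummy_trainer, seed = 4)
  expect_equal(as.vector(table(cv$assignment)), rep(20L, 5))
  expect_equal(sort(unique(cv$assignment)), 1:5)
  # every sample tested exactly once, folds pairwise disjoint by construction
  expect_equal(sum(cv$folds$n), 100)
  # stratification: each fold's class mix within one of proportional
  for (f in 1:5) {
    expect_lte(abs(sum(tt$samples$label[cv$assignment == f] == "1") -
                     sum(tt$samples$label == "1") / 5), 1)
  }
  cv2 <- cross_validate(tt$samples, k = 5, trainer = dummy_trainer, seed = 4)
  expect_identical(cv$assignment, cv2$assignment)
  cv3 <- cross_validate(tt$samples, k = 5, trainer = dummy_trainer, seed = 5)
  expect_false(identical(cv$assignment, cv3$assignment))
})

test_that("classes smaller than k relax stratification with a warning", {
  tt <- toy_task(40)
  tt$samples$label[1] <- "rare"
  dummy_trainer <- function(tr) {
    structure(list(maj = "0"), class = "majority_model2")
  }
  assign("predict.majority_model2",
         function(object, newdata, ...) {
           data.frame(instance_id = newdata$instance_id, label = "0",
                      stringsAsFactors = FALSE)
         }, envir = globalenv())
  on.exit(rm("predict.majority_model2", envir = globalenv()), add = TRUE)
  expect_warning(cross_validate(tt$samples, k = 5, trainer = dummy_trainer,
                                seed = 1), "fewer than")
})
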