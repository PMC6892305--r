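# independent oracle: sliding-window convolution + ReLU + max-over-time
oracle_conv_pool <- function(X, n, windows, filters) {
  feats <- numeric(0)
  for (k in seq_along(windows)) {
    w <- windows[k]
    W <- filters[[k]]$W; b <- filters[[k]]$b
    vals <- matrix(-Inf, max(n - w + 1, 0), length(b))
    if (n >= w) {
      for (t in 1:(n - w + 1)) {
        win <- as.vector(X[t:(t + w - 1), , drop = FALSE])
        for (j in seq_along(b)) {
          vals[t, j] <- max(0, sum(win * W[, j]) + b[j])
        }
      }
      feats <- c(feats, apply(vals, 2, max))
    } else {
      feats <- c(feats, pmax(b, 0))
    }
  }
  feats
}

test_that("all-zero hidden states with zero biases pool to zero features", {
  cfg <- cnn_config(windows = c(2, 3), maps = 4, dropout = 0)
  p <- init_cnn_params(cfg, H = 4, n_classes = 2, seed = 1)
  for (k in seq_along(p$filters)) p$filters[[k]]$b[] <- 0
  out <- conv_pool(matrix(0, 6, 4), rep(1L, 6), p, cfg)
  expect_identical(out$features, rep(0, 8))
})

test_that("convolution with pooling matches the sliding-window loop oracle", {
  set.seed(14)
  cfg <- cnn_config(windows = 3, maps = 2, dropout = 0)
  p <- init_cnn_params(cfg, H = 4, n_classes = 2, seed = 2)
  X <- matrix(rnorm(24), 6, 4)
  out <- conv_pool(X, rep(1L, 6), p, cfg)
  expect_equal(out$features, oracle_conv_pool(X, 6, cfg$windows, p$filters),
               tolerance = 1e-6)
})

test_that("conv_pool equals the oracle over exhaustive small integer-weight configurations", {
  set.seed(15)
  for (L in 3:8) for (H in 2:4) for (w in 1:3) {
    cfg <- cnn_config(windows = w, maps = 2, dropout = 0)
    filters <- list(list(W = matrix(sample(-2:2, w * H * 2, TRUE), w * H, 2),
                         b = sample(-1:1, 2, TRUE)))
    names(filters) <- paste0("w", w)
    p <- structure(list(filters = filters,
                        fc_W = matrix(0, 2, 2), fc_b = numeric(2)),
                   class = "cnn_params")
    X <- matrix(sample(-3:3, L * H, TRUE), L, H)
    out <- conv_pool(X, rep(1L, L), p, cfg)
    expect_identical(out$features, oracle_conv_pool(X, L, w, filters))
  }
})

test_that("padding rows never influence pooled features", {
  set.seed(16)
  cfg <- cnn_config(windows = c(2, 3), maps = 5, dropout = 0)
  p <- init_cnn_params(cfg, H = 6, n_classes = 2, seed = 3)
  X <- matrix(rnorm(30), 5, 6)
  mask <- rep(1L, 5)
  f1 <- conv_pool(X, mask, p, cfg)$features
  Xp <- rbind(X, matrix(rnorm(18), 3, 6)) # junk past the mask
  f2 <- conv_pool(Xp, c(mask, 0L, 0L, 0L), p, cfg)$features
  expect_identical(f1, f2)
})

test_that("sequences shorter than a window fall back to bias through ReLU", {
  cfg <- cnn_config(windows = 4, maps = 3, dropout = 0)
  p <- init_cnn_params(cfg, H = 2, n_classes = 2, seed = 4)
  p$filters[[1]]$b <- c(-1, 0.5, 2)
  expect_message(
    out <- conv_pool(matrix(1, 2, 2), c(1L, 1L), p, cfg),
    "shorter than window")
  expect_identical(out$features, c(0, 0.5, 2))
})

test_that("classification distributions are valid, uniform at zero, shift-invariant", {
  p <- list(fc_W = matrix(0, 6, 3), fc_b = numeric(3))
  expect_equal(classify(rnorm(6), p)$probs, rep(1 / 3, 3))
  set.seed(17)
  p2 <- list(fc_W = matrix(rnorm(18), 6, 3), fc_b = rnorm(3))
  for (i in 1:1000) {
    pr <- classify(rnorm(6), p2)$probs
    expect_equal(sum(pr), 1, tolerance = 1e-9)
    expect_true(all(pr >= 0))
  }
  f <- rnorm(6)
  p3 <- p2; p3$fc_b <- p2$fc_b + 5 # constant logit shift
  expect_equal(classify(f, p2)$probs, classify(f, p3)$probs, tolerance = 1e-9)
})

test_that("the margin ranking loss follows its closed form", {
  expect_identical(ranking_loss(rep(1, 5), rep(0, 5)), 0)
  expect_identical(ranking_loss(rep(0.4, 7), rep(0.4, 7)), 7)
  set.seed(18)
  g1 <- runif(50); g2 <- runif(50)
  oracle <- 0
  for (i in 1:50) oracle <- oracle + max(0, 1 - g1[i] + g2[i])
  expect_equal(ranking_loss(g1, g2), oracle, tolerance = 1e-12)
  expect_error(ranking_loss(1.2, 0.1), "softmax")
  expect_error(ranking_loss(c(0.5, 0.5), 0.1), "length")
})

test_that("the ranking loss is monotone in each score", {
  grid <- seq(0, 1, by = 0.1)
  for (gn in grid) {
    vals <- vapply(grid, function(gp) ranking_loss(gp, gn), numeric(1))
    expect_true(all(diff(vals) <= 1e-12))
  }
  for (gp in grid) {
    vals <- vapply(grid, function(gn) ranking_loss(gp, gn), numeric(1))
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("the linear head agrees with classify on identical inputs", {
  set.seed(19)
  p <- list(fc_W = matrix(rnorm(16), 8, 2), fc_b = rnorm(2))
  x <- rnorm(8)
  expect_identical(linear_head(x, p)$probs, classify(x, p)$probs)
  p0 <- list(fc_W = matrix(0, 8, 2), fc_b = numeric(2))
  expect_equal(linear_head(x, p0)$probs, c(0.5, 0.5))
})

test_that("the full encoder + CNN + classifier pass is differentiable end to end", {
  v <- tiny_vocab()
  cfg <- encoder_config(L = 2, H = 8, A = 2, V = v$size, P = 16, dropout = 0)
  params <- init_encoder_params(cfg, 31)
  ccfg <- cnn_config(windows = c(2, 3), maps = 3, dropout = 0)
  hp <- init_cnn_params(ccfg, 8, 2, seed = 5)
  s <- encode_pair("ab cd", "ef gh ij", v, 14)
  loss_at <- function(params, hp) {
    enc <- encode(s, params, cfg)
    cp <- conv_pool(enc$hidden, s$mask, hp, ccfg)
    cl <- classify(cp$features, hp, dropout = 0)
    -log(cl$probs[1])
  }
  # analytic gradient via the training path
  enc <- encode(s, params, cfg, keep_cache = TRUE)
  cp <- conv_pool(enc$hidden, s$mask, hp, ccfg, keep_cache = TRUE)
  cl <- classify(cp$features, hp, dropout = 0, keep_cache = TRUE)
  dlog <- cl$probs; dlog[1] <- dlog[1] - 1
  cb <- medrex:::classify_backward(dlog, hp, cl$cache)
  cpb <- medrex:::conv_pool_backward(cb$dfeat, hp, ccfg, cp$cache, cfg$H)
  g <- medrex:::encode_backward(cpb$dX, NULL, params, cfg, enc$cache)
  set.seed(20)
  flat_checks <- list(
    list(get = function() params$tok, set = function(o) { q <- params; q$tok <- o; q },
         grad = g$tok),
    list(get = function() params$layers[[1]]$Wv,
         set = function(o) { q <- params; q$layers[[1]]$Wv <- o; q },
         grad = g$layers[[1]]$Wv),
    list(get = function() params$layers[[2]]$W2,
         set = function(o) { q <- params; q$layers[[2]]$W2 <- o; q },
         grad = g$layers[[2]]$W2))
  for (chk in flat_checks) {
    obj <- chk$get()
    for (i in sample(length(obj), 4)) {
      eps <- 1e-5
      o1 <- obj; o1[i] <- o1[i] + eps
      o2 <- obj; o2[i] <- o2[i] - eps
      num <- (loss_at(chk$set(o1), hp) - loss_at(chk$set(o2), hp)) / (2 * eps)
      expect_equal(chk$grad[i], num, tolerance = 1e-4)
    }
  }
  # repeated evaluation passes are deterministic
  expect_identical(loss_at(params, hp), loss_at(params, hp))
})
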