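# Numerical core: parameter trees, layer primitives and the Adam optimizer.
#
# Parameters are nested lists of numeric matrices/vectors; gradients mirror
# the same structure. All forward passes cache what their backward pass
# needs, so gradients are exact (hand-derived backprop, no autodiff).

LN_EPS <- 1e-6

# ---- parameter-tree utilities ----------------------------------------------

tree_map <- function(f, p) {
  if (is.list(p)) lapply(p, tree_map, f = f) else f(p)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    out
  } else {
    f(a, b)
  }
}

tree_zero <- function(p) tree_map(function(x) x * 0, p)

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_scale <- function(p, s) tree_map(function(x) x * s, p)

tree_count <- function(p) {
  if (is.list(p)) sum(vapply(p, tree_count, numeric(1))) else length(p)
}

tree_sq_norm <- function(p) {
  if (is.list(p)) sum(vapply(p, tree_sq_norm, numeric(1))) else sum(p^2)
}

# identical shapes check (names and dims)
tree_shapes_equal <- function(a, b) {
  if (is.list(a) != is.list(b)) return(FALSE)
  if (is.list(a)) {
    if (!identical(names(a), names(b)) || length(a) != length(b)) return(FALSE)
    all(mapply(tree_shapes_equal, a, b))
  } else {
    identical(dim(a) %||% length(a), dim(b) %||% length(b))
  }
}

clip_global_norm <- function(g, max_norm) {
  nrm <- sqrt(tree_sq_norm(g))
  if (is.finite(nrm) && nrm > max_norm) tree_scale(g, max_norm / nrm) else g
}

# truncated-normal initialization (resample beyond 2 sd), scale 0.02
trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

tn_mat <- function(nr, nc, sd = 0.02) matrix(trunc_normal(nr * nc, sd), nr, nc)

# ---- primitives -------------------------------------------------------------

# add a row vector b to every row of M
add_bias <- function(M, b) M + rep(b, each = nrow(M))

softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

# backward of row-wise softmax: given P = softmax(S) and dP, return dS
softmax_rows_backward <- function(P, dP) {
  P * (dP - rowSums(dP * P))
}

gelu <- function(x) x * stats::pnorm(x)

gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# row-wise layer normalization over the hidden axis
ln_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xh <- xc * inv
  list(out = add_bias(xh * rep(g, each = nrow(x)), b), xh = xh, inv = inv)
}

ln_backward <- function(dy, cache, g) {
  xh <- cache$xh
  dxh <- dy * rep(g, each = nrow(dy))
  dg <- colSums(dy * xh)
  db <- colSums(dy)
  dx <- (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh)) * cache$inv
  list(dx = dx, dg = dg, db = db)
}

# inverted dropout; returns the kept/scaled mask so backward is a product
dropout <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  m <- stats::rbinom(length(x), 1L, 1 - rate) / (1 - rate)
  if (!is.null(dim(x))) dim(m) <- dim(x)
  list(out = x * m, mask = m)
}

dropout_backward <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# ---- Adam -------------------------------------------------------------------

adam_state <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  list(params = tree_map2(`-`, params, upd), state = state)
}
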