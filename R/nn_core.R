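# Minimal neural-network engine: parameter trees, layer forward/backward
# primitives, and Adam. All randomness flows through R's RNG so a single
# set.seed() makes initialization, shuffling and dropout reproducible.

glorot <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -l, l), nr, nc)
}

dense_params <- function(d_in, d_out, bias = TRUE) {
  p <- list(W = glorot(d_in, d_out))
  if (bias) p$b <- numeric(d_out)
  p
}

dense_fwd <- function(X, p) {
  out <- X %*% p$W
  if (!is.null(p$b)) out <- sweep(out, 2L, p$b, `+`)
  out
}

# returns list(dX, grads(W,b))
dense_bwd <- function(dOut, X, p) {
  g <- list(W = crossprod(X, dOut))
  if (!is.null(p$b)) g$b <- colSums(dOut)
  list(dX = dOut %*% t(p$W), grads = g)
}

relu <- function(x) pmax(x, 0)
relu_bwd <- function(dOut, pre) dOut * (pre > 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

# --- batch normalization (over rows; per-feature) -------------------------

bn_params <- function(d) list(gamma = rep(1, d), beta = numeric(d))

bn_fwd <- function(X, p, state, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    va <- colMeans(X^2) - mu^2
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
  } else {
    mu <- state$mean
    va <- state$var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(X, 2L, mu, `-`), 2L, inv, `*`)
  out <- sweep(sweep(xhat, 2L, p$gamma, `*`), 2L, p$beta, `+`)
  list(out = out, cache = list(xhat = xhat, inv = inv), state = state)
}

bn_bwd <- function(dOut, cache, p) {
  xhat <- cache$xhat
  n <- nrow(xhat)
  dgamma <- colSums(dOut * xhat)
  dbeta <- colSums(dOut)
  dxhat <- sweep(dOut, 2L, p$gamma, `*`)
  dX <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(xhat), byrow = TRUE) -
                xhat * matrix(colMeans(dxhat * xhat), n, ncol(xhat), byrow = TRUE),
              2L, cache$inv, `*`)
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}

# --- layer normalization (per row) ----------------------------------------

ln_params <- function(d) list(gamma = rep(1, d), beta = numeric(d))

ln_fwd <- function(X, p, eps = 1e-5) {
  mu <- rowMeans(X)
  va <- rowMeans(X^2) - mu^2
  inv <- 1 / sqrt(va + eps)
  xhat <- (X - mu) * inv
  out <- sweep(sweep(xhat, 2L, p$gamma, `*`), 2L, p$beta, `+`)
  list(out = out, cache = list(xhat = xhat, inv = inv))
}

ln_bwd <- function(dOut, cache, p) {
  xhat <- cache$xhat
  d <- ncol(xhat)
  dgamma <- colSums(dOut * xhat)
  dbeta <- colSums(dOut)
  dxhat <- sweep(dOut, 2L, p$gamma, `*`)
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}

# --- dropout ---------------------------------------------------------------

dropout_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, mask = NULL))
  mask <- matrix((runif(length(X)) >= rate) / (1 - rate), nrow(X), ncol(X))
  list(out = X * mask, mask = mask)
}

dropout_bwd <- function(dOut, mask) if (is.null(mask)) dOut else dOut * mask

# --- parameter-tree utilities ---------------------------------------------

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) tree_map(f, x)) else f(tree)
}

# Walks two parameter trees in parallel; matches children by name when both
# trees are named (gradient lists are assembled in backward order).
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    by_name <- !is.null(names(a)) && !is.null(names(b)) &&
      all(nzchar(names(a))) && setequal(names(a), names(b))
    for (k in seq_along(a)) {
      bk <- if (by_name) b[[names(a)[k]]] else b[[k]]
      out[[k]] <- tree_map2(f, a[[k]], bk)
    }
    out
  } else f(a, b)
}

tree_zeros <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(a, b) tree_map2(`+`, a, b)

# Adam with bias correction; state holds first/second moments and step count.
adam_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
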