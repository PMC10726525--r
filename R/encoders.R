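# Drug-branch and cell-branch encoders: parameter construction and batched
# forward/backward passes used by the training loop. The reference
# single-graph layer implementations live in graph_layers.R; tests assert
# both paths agree.

#' Encoder configuration
#'
#' Architecture settings for the drug-branch encoder. Defaults follow the
#' reference configuration: three graph layers, 128-dimensional hidden and
#' embedding widths, ten attention heads on the first graph-attention
#' layer, an 8-dimensional Laplacian positional encoding for the hybrid
#' graph-transformer variant, rectifier activations and dropout rate 0.2
#' (applied in the cell branch only).
#'
#' @param variant One of `"GIN_TRANSFORMER"`, `"GCN"`, `"GAT"`, `"GIN"`.
#' @param n_graph_layers Number of graph layers (default 3; for the hybrid
#'   variant this is two GIN layers plus one transformer layer).
#' @param hidden_dim Hidden width of the graph layers.
#' @param gat_heads Attention heads on the first GAT layer.
#' @param gin_mu_learnable Is the GIN self-weight offset mu learnable
#'   (default: fixed at 0)?
#' @param pe_dim Laplacian positional-encoding size (hybrid variant).
#' @param embed_dim Graph embedding length (128).
#' @param dropout Dropout rate (cell branch).
#' @param transformer_position `"last"` (default: GIN, GIN, transformer) or
#'   `"first"` for the hybrid stack order.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(variant = c("GIN_TRANSFORMER", "GCN", "GAT", "GIN"),
                           n_graph_layers = 3L, hidden_dim = 128L,
                           gat_heads = 10L, gin_mu_learnable = FALSE,
                           pe_dim = 8L, embed_dim = 128L, dropout = 0.2,
                           transformer_position = c("last", "first")) {
  variant <- match.arg(variant)
  transformer_position <- match.arg(transformer_position)
  if (variant == "GIN_TRANSFORMER" && pe_dim < 1L) {
    stop("pe_dim must be >= 1 for the GIN_TRANSFORMER variant")
  }
  structure(list(variant = variant, n_graph_layers = as.integer(n_graph_layers),
                 hidden_dim = as.integer(hidden_dim),
                 gat_heads = as.integer(gat_heads),
                 gin_mu_learnable = isTRUE(gin_mu_learnable),
                 pe_dim = as.integer(pe_dim), embed_dim = as.integer(embed_dim),
                 dropout = dropout, transformer_position = transformer_position),
            class = "encoder_config")
}

gin_layer_params <- function(d_in, h, learnable_mu) {
  list(W1 = glorot(d_in, h), b1 = numeric(h),
       W2 = glorot(h, h), b2 = numeric(h),
       bn = bn_params(h), mu = 0)
}

gat_head_params <- function(d_in, dh) {
  list(W = glorot(d_in, dh),
       a1 = drop(glorot(dh, 1L)), a2 = drop(glorot(dh, 1L)))
}

init_drug_params <- function(config, d_in) {
  h <- config$hidden_dim
  p <- switch(config$variant,
    GCN = list(l1 = list(W = glorot(d_in, h)),
               l2 = list(W = glorot(h, h)),
               l3 = list(W = glorot(h, h))),
    GAT = {
      heads <- lapply(seq_len(config$gat_heads),
                      function(k) gat_head_params(d_in, h))
      names(heads) <- paste0("h", seq_along(heads))
      list(l1 = heads,
           l2 = list(h1 = gat_head_params(h * config$gat_heads, h)),
           l3 = list(h1 = gat_head_params(h, h)))
    },
    GIN = list(l1 = gin_layer_params(d_in, h, config$gin_mu_learnable),
               l2 = gin_layer_params(h, h, config$gin_mu_learnable),
               l3 = gin_layer_params(h, h, config$gin_mu_learnable)),
    GIN_TRANSFORMER = {
      d0 <- d_in  # caller's input width already includes the positional encoding
      if (config$transformer_position == "last") {
        list(l1 = gin_layer_params(d0, h, config$gin_mu_learnable),
             l2 = gin_layer_params(h, h, config$gin_mu_learnable),
             l3 = make_transformer_params(h))
      } else {
        list(l1 = make_transformer_params(h, d_in_pe = d0),
             l2 = gin_layer_params(h, h, config$gin_mu_learnable),
             l3 = gin_layer_params(h, h, config$gin_mu_learnable))
      }
    })
  p$fc <- dense_params(h, config$embed_dim)
  p
}

init_drug_state <- function(config) {
  h <- config$hidden_dim
  bn0 <- function() list(mean = numeric(h), var = rep(1, h))
  switch(config$variant,
    GIN = list(l1 = bn0(), l2 = bn0(), l3 = bn0()),
    GIN_TRANSFORMER = if (config$transformer_position == "last")
      list(l1 = bn0(), l2 = bn0()) else list(l2 = bn0(), l3 = bn0()),
    list())
}

# --- batched GCN layer -----------------------------------------------------

gcn_fwd_b <- function(H, Ahat, W) {
  AX <- as.matrix(Ahat %*% H)
  pre <- AX %*% W
  list(out = relu(pre), cache = list(AX = AX, pre = pre))
}

gcn_bwd_b <- function(dOut, cache, W, Ahat) {
  dPre <- relu_bwd(dOut, cache$pre)
  list(dH = as.matrix(Ahat %*% (dPre %*% t(W))),
       grads = list(W = crossprod(cache$AX, dPre)))
}

# --- batched GIN layer -----------------------------------------------------

gin_fwd_b <- function(H, A, p, st, training) {
  S <- (1 + p$mu) * H + as.matrix(A %*% H)
  pre1 <- sweep(S %*% p$W1, 2L, p$b1, `+`)
  h1 <- relu(pre1)
  pre2 <- sweep(h1 %*% p$W2, 2L, p$b2, `+`)
  bn <- bn_fwd(pre2, p$bn, st, training)
  list(out = relu(bn$out), state = bn$state,
       cache = list(H = H, S = S, pre1 = pre1, h1 = h1, pre2 = pre2,
                    bn_pre = bn$out, bn_cache = bn$cache))
}

gin_bwd_b <- function(dOut, cache, p, A, learnable_mu) {
  dBnOut <- relu_bwd(dOut, cache$bn_pre)
  bnb <- bn_bwd(dBnOut, cache$bn_cache, p$bn)
  d2 <- dense_bwd(bnb$dX, cache$h1, list(W = p$W2, b = p$b2))
  dPre1 <- relu_bwd(d2$dX, cache$pre1)
  d1 <- dense_bwd(dPre1, cache$S, list(W = p$W1, b = p$b1))
  dS <- d1$dX
  dH <- (1 + p$mu) * dS + as.matrix(A %*% dS)
  dmu <- if (learnable_mu) sum(dS * cache$H) else 0
  list(dH = dH,
       grads = list(W1 = d1$grads$W, b1 = d1$grads$b,
                    W2 = d2$grads$W, b2 = d2$grads$b,
                    bn = bnb$grads, mu = dmu))
}

# --- batched GAT layer -----------------------------------------------------

gat_fwd_b <- function(H, gb, heads, slope = 0.2) {
  N <- gb$N
  hc <- vector("list", length(heads))
  caches <- vector("list", length(heads))
  for (k in seq_along(heads)) {
    p <- heads[[k]]
    Z <- sweep(H %*% p$W, 2L, 0, `+`)
    s <- drop(Z %*% p$a1)
    t_ <- drop(Z %*% p$a2)
    r <- s[gb$ei] + t_[gb$ej]
    l <- leaky_relu(r, slope)
    mm <- tapply(l, gb$ei, max)
    m <- as.numeric(mm[as.character(seq_len(N))])  # align to node index
    w <- exp(l - m[gb$ei])
    den <- drop(rowsum_full(matrix(w), gb$ei, N))
    alpha <- w / den[gb$ei]
    O <- rowsum_full(alpha * Z[gb$ej, , drop = FALSE], gb$ei, N)
    hc[[k]] <- O
    caches[[k]] <- list(Z = Z, r = r, alpha = alpha)
  }
  pre <- do.call(cbind, hc)
  list(out = relu(pre), cache = list(H = H, pre = pre, heads = caches))
}

gat_bwd_b <- function(dOut, cache, gb, heads, slope = 0.2) {
  N <- gb$N
  dPre <- relu_bwd(dOut, cache$pre)
  dH <- 0
  grads <- vector("list", length(heads))
  names(grads) <- names(heads)
  dh <- ncol(cache$heads[[1]]$Z)
  for (k in seq_along(heads)) {
    p <- heads[[k]]
    ch <- cache$heads[[k]]
    dO <- dPre[, (k - 1L) * dh + seq_len(dh), drop = FALSE]
    Zj <- ch$Z[gb$ej, , drop = FALSE]
    dOi <- dO[gb$ei, , drop = FALSE]
    dalpha <- rowSums(dOi * Zj)
    dZ <- rowsum_full(ch$alpha * dOi, gb$ej, N)
    Ssum <- drop(rowsum_full(matrix(ch$alpha * dalpha), gb$ei, N))
    dl <- ch$alpha * (dalpha - Ssum[gb$ei])
    dr <- dl * ifelse(ch$r > 0, 1, slope)
    ds <- drop(rowsum_full(matrix(dr), gb$ei, N))
    dt <- drop(rowsum_full(matrix(dr), gb$ej, N))
    dZ <- dZ + outer(ds, p$a1) + outer(dt, p$a2)
    grads[[k]] <- list(W = crossprod(cache$H, dZ),
                       a1 = drop(crossprod(ch$Z, ds)),
                       a2 = drop(crossprod(ch$Z, dt)))
    dH <- dH + dZ %*% t(p$W)
  }
  list(dH = dH, grads = grads)
}

# --- batched transformer layer --------------------------------------------

transformer_fwd_b <- function(H, gb, p) {
  Hin <- H
  if (!is.null(p$Wp)) H <- H %*% p$Wp
  d <- ncol(p$Wq)
  Q <- H %*% p$Wq; K <- H %*% p$Wk; V <- H %*% p$Wv
  O <- matrix(0, nrow(H), d)
  Ps <- vector("list", gb$n_graphs)
  for (g in seq_len(gb$n_graphs)) {
    idx <- gb$node_list[[g]]
    S <- Q[idx, , drop = FALSE] %*% t(K[idx, , drop = FALSE]) / sqrt(d)
    P <- softmax_rows(S)
    O[idx, ] <- P %*% V[idx, , drop = FALSE]
    Ps[[g]] <- P
  }
  Aout <- sweep(O %*% p$Wo, 2L, p$bo, `+`)
  l1 <- ln_fwd(H + Aout, p$ln1)
  pref <- sweep(l1$out %*% p$Wf1, 2L, p$bf1, `+`)
  Fh <- relu(pref)
  F2 <- sweep(Fh %*% p$Wf2, 2L, p$bf2, `+`)
  l2 <- ln_fwd(l1$out + F2, p$ln2)
  list(out = l2$out,
       cache = list(Hin = Hin, H = H, Q = Q, K = K, V = V, O = O, Ps = Ps,
                    l1 = l1, l2 = l2, pref = pref, Fh = Fh))
}

transformer_bwd_b <- function(dOut, cache, gb, p) {
  d <- ncol(p$Wq)
  l2b <- ln_bwd(dOut, cache$l2$cache, p$ln2)
  dres2 <- l2b$dX
  dF2 <- dres2
  dWf2 <- crossprod(cache$Fh, dF2); dbf2 <- colSums(dF2)
  dFh <- dF2 %*% t(p$Wf2)
  dPref <- relu_bwd(dFh, cache$pref)
  dWf1 <- crossprod(cache$l1$out, dPref); dbf1 <- colSums(dPref)
  dL1out <- dres2 + dPref %*% t(p$Wf1)
  l1b <- ln_bwd(dL1out, cache$l1$cache, p$ln1)
  dres1 <- l1b$dX
  dAout <- dres1
  dWo <- crossprod(cache$O, dAout); dbo <- colSums(dAout)
  dO <- dAout %*% t(p$Wo)
  dQ <- matrix(0, nrow(cache$H), d)
  dK <- dQ; dV <- dQ
  for (g in seq_len(gb$n_graphs)) {
    idx <- gb$node_list[[g]]
    P <- cache$Ps[[g]]
    dOg <- dO[idx, , drop = FALSE]
    Vg <- cache$V[idx, , drop = FALSE]
    dP <- dOg %*% t(Vg)
    dV[idx, ] <- crossprod(P, dOg)
    dS <- P * (dP - rowSums(P * dP))
    dQ[idx, ] <- dS %*% cache$K[idx, , drop = FALSE] / sqrt(d)
    dK[idx, ] <- crossprod(dS, cache$Q[idx, , drop = FALSE]) / sqrt(d)
  }
  dH <- dres1 + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  grads <- list(Wq = crossprod(cache$H, dQ), Wk = crossprod(cache$H, dK),
                Wv = crossprod(cache$H, dV), Wo = dWo, bo = dbo,
                ln1 = l1b$grads, Wf1 = dWf1, bf1 = dbf1,
                Wf2 = dWf2, bf2 = dbf2, ln2 = l2b$grads)
  if (!is.null(p$Wp)) {
    grads$Wp <- crossprod(cache$Hin, dH)
    dH <- dH %*% t(p$Wp)
  }
  list(dH = dH, grads = grads)
}

# --- full drug branch ------------------------------------------------------

layer_kinds <- function(config) {
  switch(config$variant,
    GCN = c("gcn", "gcn", "gcn"),
    GAT = c("gat", "gat", "gat"),
    GIN = c("gin", "gin", "gin"),
    GIN_TRANSFORMER = if (config$transformer_position == "last")
      c("gin", "gin", "transformer") else c("transformer", "gin", "gin"))
}

drug_forward_b <- function(gb, params, config, state, training) {
  kinds <- layer_kinds(config)
  H <- gb$X
  caches <- vector("list", length(kinds))
  for (k in seq_along(kinds)) {
    lp <- params[[paste0("l", k)]]
    if (kinds[k] == "gcn") {
      f <- gcn_fwd_b(H, gb$Ahat, lp$W)
    } else if (kinds[k] == "gin") {
      f <- gin_fwd_b(H, gb$A, lp, state[[paste0("l", k)]], training)
      state[[paste0("l", k)]] <- f$state
    } else if (kinds[k] == "gat") {
      f <- gat_fwd_b(H, gb, lp)
    } else {
      f <- transformer_fwd_b(H, gb, lp)
    }
    caches[[k]] <- f$cache
    H <- f$out
  }
  pool <- pool_fwd(H, gb$node_list)
  pre_fc <- dense_fwd(pool$P, params$fc)
  emb <- relu(pre_fc)
  list(emb = emb, state = state,
       cache = list(layers = caches, pool = pool, pre_fc = pre_fc, Hlast = H))
}

drug_backward_b <- function(dEmb, cache, gb, params, config) {
  kinds <- layer_kinds(config)
  dPreFc <- relu_bwd(dEmb, cache$pre_fc)
  fcb <- dense_bwd(dPreFc, cache$pool$P, params$fc)
  grads <- list(fc = fcb$grads)
  dH <- pool_bwd(fcb$dX, cache$pool$arg, gb$N)
  for (k in rev(seq_along(kinds))) {
    lp <- params[[paste0("l", k)]]
    if (kinds[k] == "gcn") {
      b <- gcn_bwd_b(dH, cache$layers[[k]], lp$W, gb$Ahat)
    } else if (kinds[k] == "gin") {
      b <- gin_bwd_b(dH, cache$layers[[k]], lp, gb$A, config$gin_mu_learnable)
    } else if (kinds[k] == "gat") {
      b <- gat_bwd_b(dH, cache$layers[[k]], gb, lp)
    } else {
      b <- transformer_bwd_b(dH, cache$layers[[k]], gb, lp)
    }
    grads[[paste0("l", k)]] <- b$grads
    dH <- b$dH
  }
  grads
}

# --- cell branch (dense 512 -> 1024 -> dropout -> 128) ---------------------

init_cell_params <- function(n_pathways, embed_dim = 128L) {
  list(d1 = dense_params(n_pathways, 512L),
       d2 = dense_params(512L, 1024L),
       d3 = dense_params(1024L, embed_dim))
}

cell_forward_b <- function(Xc, params, dropout, training) {
  pre1 <- dense_fwd(Xc, params$d1); h1 <- relu(pre1)
  pre2 <- dense_fwd(h1, params$d2); h2 <- relu(pre2)
  dr <- dropout_fwd(h2, dropout, training)
  pre3 <- dense_fwd(dr$out, params$d3); emb <- relu(pre3)
  list(emb = emb,
       cache = list(Xc = Xc, pre1 = pre1, h1 = h1, pre2 = pre2,
                    drop_out = dr$out, mask = dr$mask, pre3 = pre3))
}

cell_backward_b <- function(dEmb, cache, params) {
  dPre3 <- relu_bwd(dEmb, cache$pre3)
  b3 <- dense_bwd(dPre3, cache$drop_out, params$d3)
  dH2 <- dropout_bwd(b3$dX, cache$mask)
  dPre2 <- relu_bwd(dH2, cache$pre2)
  b2 <- dense_bwd(dPre2, cache$h1, params$d2)
  dPre1 <- relu_bwd(b2$dX, cache$pre1)
  b1 <- dense_bwd(dPre1, cache$Xc, params$d1)
  list(grads = list(d1 = b1$grads, d2 = b2$grads, d3 = b3$grads))
}

# --- fusion head (256 -> 1024 -> 128 -> 1, sigmoid output) -----------------

init_fuse_params <- function(embed_dim = 128L, fusion_dims = c(1024L, 128L)) {
  list(f1 = dense_params(2L * embed_dim, fusion_dims[1]),
       f2 = dense_params(fusion_dims[1], fusion_dims[2]),
       f3 = dense_params(fusion_dims[2], 1L))
}

fuse_forward_b <- function(Xf, params) {
  pre1 <- dense_fwd(Xf, params$f1); h1 <- relu(pre1)
  pre2 <- dense_fwd(h1, params$f2); h2 <- relu(pre2)
  z <- dense_fwd(h2, params$f3)
  pred <- sigmoid(drop(z))
  list(pred = pred,
       cache = list(Xf = Xf, pre1 = pre1, h1 = h1, pre2 = pre2, h2 = h2,
                    z = drop(z)))
}

fuse_backward_b <- function(dPred, cache, params) {
  s <- sigmoid(cache$z)
  dz <- matrix(dPred * s * (1 - s), ncol = 1L)
  b3 <- dense_bwd(dz, cache$h2, params$f3)
  dPre2 <- relu_bwd(b3$dX, cache$pre2)
  b2 <- dense_bwd(dPre2, cache$h1, params$f2)
  dPre1 <- relu_bwd(b2$dX, cache$pre1)
  b1 <- dense_bwd(dPre1, cache$Xf, params$f1)
  list(dXf = b1$dX,
       grads = list(f1 = b1$grads, f2 = b2$grads, f3 = b3$grads))
}
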