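# Reference (single-graph, dense) implementations of the graph layers.
# The training engine uses batched sparse equivalents (graph_batch.R);
# tests assert the two paths agree.

edges_to_adjacency <- function(edges, n) {
  A <- matrix(0, n, n)
  if (NROW(edges)) {
    edges <- as.matrix(edges)
    A[edges] <- 1
    A[edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  A
}

#' Graph convolution layer (normalized propagation rule)
#'
#' One spectral graph-convolution step
#' `H' = act(D~^(-1/2) A~ D~^(-1/2) H W)` with `A~ = A + I` (self-loops) and
#' `D~` the degree matrix of `A~`. The added self-loop guarantees every
#' degree is at least one, so the normalization is always defined.
#'
#' @param H Node-feature matrix (n x d_in).
#' @param edges Two-column matrix of undirected edges (1-based indices).
#' @param W Weight matrix (d_in x d_out).
#' @param activation Activation function applied element-wise (default
#'   identity; the encoders use the rectifier).
#' @return Matrix n x d_out.
#' @export
gcn_layer <- function(H, edges, W, activation = identity) {
  H <- as.matrix(H)
  n <- nrow(H)
  At <- edges_to_adjacency(edges, n) + diag(n)
  dinv <- 1 / sqrt(rowSums(At))
  Ahat <- At * (dinv %o% dinv)
  activation(Ahat %*% H %*% W)
}

#' Graph attention layer
#'
#' Attention-weighted neighborhood aggregation: per head, node features are
#' linearly transformed (`Z = H W`), attention logits over each node's
#' first-order neighborhood (self-loop included) are
#' `leakyrelu(a_src . z_i + a_dst . z_j)`, normalized by a softmax per
#' node, and the output row is the attention-weighted sum of transformed
#' neighbors passed through `activation`. Multi-head outputs are
#' concatenated.
#'
#' @param H Node-feature matrix (n x d_in).
#' @param edges Two-column undirected edge matrix.
#' @param W Weight matrix (d_in x d_head) or list of per-head matrices.
#' @param a_src,a_dst Attention vectors of length d_head (or lists, one per
#'   head) for the attending node and its neighbor respectively.
#' @param activation Output activation (default identity).
#' @param slope Negative slope of the leaky rectifier on the logits.
#' @return Matrix n x (d_head * n_heads), with the per-head attention
#'   matrices (rows summing to one over each neighborhood) in attribute
#'   `"attention"`.
#' @export
gat_layer <- function(H, edges, W, a_src, a_dst, activation = identity,
                      slope = 0.2) {
  H <- as.matrix(H)
  n <- nrow(H)
  if (!is.list(W)) { W <- list(W); a_src <- list(a_src); a_dst <- list(a_dst) }
  A <- edges_to_adjacency(edges, n) + diag(n)  # neighborhoods include self
  outs <- vector("list", length(W))
  atts <- vector("list", length(W))
  for (h in seq_along(W)) {
    Z <- H %*% W[[h]]
    s <- drop(Z %*% a_src[[h]])
    t_ <- drop(Z %*% a_dst[[h]])
    E <- outer(s, t_, `+`)        # logit for node i attending neighbor j
    E <- ifelse(E > 0, E, slope * E)
    E[A == 0] <- -Inf
    P <- softmax_rows(E)
    outs[[h]] <- P %*% Z
    atts[[h]] <- P
  }
  out <- activation(do.call(cbind, outs))
  attr(out, "attention") <- atts
  out
}

#' Graph isomorphism layer
#'
#' GIN update `MLP((1 + mu) x_i + sum_{j in N(i)} x_j)`: the node's own
#' features (weighted by `1 + mu`) plus the plain sum of neighbor features,
#' passed through a multi-layer perceptron.
#'
#' @param H Node-feature matrix.
#' @param edges Two-column undirected edge matrix.
#' @param mlp Function applied to the aggregated matrix (rows = nodes).
#' @param mu Scalar self-weight offset (default 0).
#' @return Matrix with `mlp` applied to the aggregation.
#' @export
gin_layer <- function(H, edges, mlp = identity, mu = 0) {
  H <- as.matrix(H)
  A <- edges_to_adjacency(edges, nrow(H))
  mlp((1 + mu) * H + A %*% H)
}

#' Laplacian positional encoding
#'
#' Eigenvectors of the symmetric normalized graph Laplacian
#' `L = I - D^(-1/2) A D^(-1/2)` for the k smallest nontrivial eigenvalues,
#' used as node position features by the graph-transformer encoder. The sign
#' of each eigenvector is fixed so that its largest-magnitude entry is
#' positive (ties broken by the lowest index); graphs with fewer than k+1
#' nodes are zero-padded on the right.
#'
#' @param graph A `molecular_graph`, or a square adjacency matrix.
#' @param k Number of encoding dimensions (>= 1).
#' @return Matrix n x k.
#' @export
laplacian_pe <- function(graph, k) {
  if (k < 1L) stop("k must be >= 1")
  A <- if (inherits(graph, "molecular_graph")) mol_adjacency(graph)
       else as.matrix(graph)
  n <- nrow(A)
  if (n == 0L) stop("empty graph")
  L <- normalized_laplacian(A)
  eig <- eigen(L, symmetric = TRUE)
  ord <- order(eig$values)            # ascending; first is the trivial mode
  take <- ord[-1L]
  take <- take[seq_len(min(k, length(take)))]
  pe <- matrix(0, n, k)
  if (length(take)) {
    U <- eig$vectors[, take, drop = FALSE]
    for (c in seq_len(ncol(U))) {
      top <- which.max(abs(U[, c]))   # lowest index on ties
      if (U[top, c] < 0) U[, c] <- -U[, c]
    }
    pe[, seq_len(ncol(U))] <- U
  }
  pe
}

# Symmetric normalized Laplacian; zero-degree nodes get a zero row/column.
normalized_laplacian <- function(A) {
  n <- nrow(A)
  d <- rowSums(A)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- -A * (dinv %o% dinv)
  diag(L) <- ifelse(d > 0, 1, 0)
  L
}

#' Graph transformer layer
#'
#' Full self-attention over all nodes of one molecule followed by a
#' position-wise feed-forward block, each with a residual connection and
#' layer normalization — the standard transformer block specialized to a
#' homogeneous molecular graph (single edge type), with graph structure
#' injected through Laplacian positional encodings rather than attention
#' masking.
#'
#' @param H Node-feature matrix (n x d).
#' @param params Parameter list with elements `Wq, Wk, Wv, Wo, bo`
#'   (attention), `ln1, ln2` (each `gamma`/`beta`), and `Wf1, bf1, Wf2,
#'   bf2` (feed-forward). See [make_transformer_params()].
#' @param pe Optional positional-encoding matrix, concatenated to `H` and
#'   projected by `params$Wp` (required when `pe` is given) before
#'   attention.
#' @return Matrix n x d.
#' @export
graph_transformer_layer <- function(H, params, pe = NULL) {
  H <- as.matrix(H)
  if (!is.null(pe)) {
    if (is.null(params$Wp)) stop("params$Wp required when pe is supplied")
    H <- cbind(H, pe) %*% params$Wp
  }
  d <- ncol(params$Wq)
  Q <- H %*% params$Wq
  K <- H %*% params$Wk
  V <- H %*% params$Wv
  P <- softmax_rows(Q %*% t(K) / sqrt(d))
  O <- sweep((P %*% V) %*% params$Wo, 2L, params$bo, `+`)
  l1 <- ln_fwd(H + O, params$ln1)
  Fh <- relu(sweep(l1$out %*% params$Wf1, 2L, params$bf1, `+`))
  F2 <- sweep(Fh %*% params$Wf2, 2L, params$bf2, `+`)
  ln_fwd(l1$out + F2, params$ln2)$out
}

#' Create transformer-layer parameters
#'
#' Glorot-initialized parameters for [graph_transformer_layer()]; draws from
#' the current RNG stream.
#'
#' @param d Model width.
#' @param d_ff Feed-forward width (default `2 * d`).
#' @param d_in_pe Optional input width (features + positional encoding) for
#'   the projection `Wp`.
#' @return Named parameter list.
#' @export
make_transformer_params <- function(d, d_ff = 2L * d, d_in_pe = NULL) {
  p <- list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
            Wo = glorot(d, d), bo = numeric(d),
            ln1 = ln_params(d),
            Wf1 = glorot(d, d_ff), bf1 = numeric(d_ff),
            Wf2 = glorot(d_ff, d), bf2 = numeric(d),
            ln2 = ln_params(d))
  if (!is.null(d_in_pe)) p$Wp <- glorot(d_in_pe, d)
  p
}

#' Global max pooling
#'
#' Element-wise maximum over the node axis: collapses a node-feature matrix
#' to one graph-level feature vector. Permutation-invariant by
#' construction.
#'
#' @param H Node-feature matrix with at least one row.
#' @return Numeric vector of length `ncol(H)`.
#' @export
global_max_pool <- function(H) {
  H <- as.matrix(H)
  if (nrow(H) == 0L) stop("empty graph: cannot pool")
  apply(H, 2L, max)
}
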