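# Block-diagonal batching of molecular graphs. All molecules in a panel are
# stacked into one node-feature matrix with a sparse block-diagonal
# adjacency, so every graph layer runs as a single (sparse) matrix product
# regardless of panel size; attention is computed per molecule (no
# cross-molecule attention).

build_graph_batch <- function(graphs, pe_dim = NULL) {
  sizes <- vapply(graphs, function(g) g$n_atoms, integer(1))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  N <- sum(sizes)
  X <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  if (!is.null(pe_dim) && pe_dim > 0L) {
    PE <- do.call(rbind, lapply(graphs, function(g) laplacian_pe(g, pe_dim)))
    X <- cbind(X, PE)
  }
  src <- integer(0); dst <- integer(0)
  for (k in seq_along(graphs)) {
    e <- graphs[[k]]$edges
    if (nrow(e)) {
      src <- c(src, e[, 1L] + offsets[k], e[, 2L] + offsets[k])
      dst <- c(dst, e[, 2L] + offsets[k], e[, 1L] + offsets[k])
    }
  }
  A <- Matrix::sparseMatrix(i = dst, j = src, x = 1, dims = c(N, N))
  deg <- Matrix::rowSums(A) + 1
  dinv <- 1 / sqrt(deg)
  I <- Matrix::Diagonal(N)
  Ahat <- Matrix::Diagonal(x = dinv) %*% (A + I) %*% Matrix::Diagonal(x = dinv)
  node_list <- lapply(seq_along(graphs),
                      function(k) offsets[k] + seq_len(sizes[k]))
  graph_id <- rep.int(seq_along(graphs), sizes)
  # directed edge list including self-loops for attention layers
  ei <- c(dst, seq_len(N))   # attending node
  ej <- c(src, seq_len(N))   # attended neighbor
  list(X = X, A = A, Ahat = Ahat, N = N, n_graphs = length(graphs),
       sizes = sizes, node_list = node_list, graph_id = graph_id,
       ei = ei, ej = ej)
}

# Global max pooling over a batch: G x d matrix plus argmax bookkeeping.
pool_fwd <- function(H, node_list) {
  G <- length(node_list)
  d <- ncol(H)
  P <- matrix(0, G, d)
  arg <- matrix(0L, G, d)
  for (g in seq_len(G)) {
    idx <- node_list[[g]]
    sub <- H[idx, , drop = FALSE]
    w <- apply(sub, 2L, which.max)
    arg[g, ] <- idx[w]
    P[g, ] <- sub[cbind(w, seq_len(d))]
  }
  list(P = P, arg = arg)
}

pool_bwd <- function(dP, arg, N) {
  d <- ncol(dP)
  dH <- matrix(0, N, d)
  for (g in seq_len(nrow(dP))) {
    dH[cbind(arg[g, ], seq_len(d))] <- dH[cbind(arg[g, ], seq_len(d))] + dP[g, ]
  }
  dH
}

# rowsum aligned to 1..n groups (matrix in, matrix out)
rowsum_full <- function(x, group, n) {
  out <- matrix(0, n, ncol(x))
  agg <- rowsum(x, group)
  out[as.integer(rownames(agg)), ] <- agg
  out
}
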