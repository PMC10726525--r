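test_that("GCN layer reproduces the normalized propagation rule", {
  # single node, identity weights, linear activation: Ahat = 1
  H <- matrix(c(1, 2, 3), 1)
  expect_equal(gcn_layer(H, matrix(integer(), ncol = 2), diag(3)), H)

  # two connected nodes with identical features: symmetric normalization
  # averages identical neighbors, so the output equals the input
  H2 <- matrix(1, 2, 3)
  e2 <- rbind(c(1L, 2L))
  expect_equal(gcn_layer(H2, e2, diag(3)), H2)

  # random graphs vs the dense oracle
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    H <- matrix(rnorm(n * 4), n)
    W <- matrix(rnorm(4 * 3), 4)
    e <- random_edges(n)
    expect_equal(gcn_layer(H, e, W), oracle_gcn(H, e, W), tolerance = 1e-6)
    expect_equal(gcn_layer(H, e, W, activation = relu),
                 pmax(oracle_gcn(H, e, W), 0), tolerance = 1e-6)
  }
})

test_that("GAT attention is a per-neighborhood softmax", {
  W <- diag(3)
  a1 <- c(0.3, -0.2, 0.5); a2 <- c(0.1, 0.4, -0.3)
  # single node: softmax over one element, output = W x
  H <- matrix(c(1, -1, 2), 1)
  out <- gat_layer(H, matrix(integer(), ncol = 2), W, a1, a2)
  expect_equal(unclass(out)[1, ], drop(H %*% W), ignore_attr = TRUE)
  expect_equal(attr(out, "attention")[[1]][1, 1], 1)

  # two nodes with identical features: equal logits, alpha = 1/2
  H2 <- rbind(c(1, 0, 2), c(1, 0, 2))
  out2 <- gat_layer(H2, rbind(c(1L, 2L)), W, a1, a2)
  expect_equal(as.vector(attr(out2, "attention")[[1]]), rep(0.5, 4))

  # random graph: attention rows sum to one over each neighborhood
  set.seed(11)
  n <- 7
  H3 <- matrix(rnorm(n * 3), n)
  out3 <- gat_layer(H3, random_edges(n), W, a1, a2)
  expect_equal(unname(rowSums(attr(out3, "attention")[[1]])), rep(1, n),
               tolerance = 1e-6)

  # multi-head output concatenates
  out4 <- gat_layer(H3, random_edges(n), list(W, W), list(a1, a1), list(a2, a2))
  expect_identical(dim(unclass(out4)), c(7L, 6L))
})

test_that("GIN layer aggregates (1+mu) self plus neighbor sum", {
  # isolated node, mu = 0, identity MLP
  H <- matrix(c(2, -1), 1)
  expect_equal(gin_layer(H, matrix(integer(), ncol = 2)), H)

  # node with two neighbors: x + u + v
  H3 <- rbind(c(1, 0), c(0, 1), c(2, 2))
  e3 <- rbind(c(1L, 2L), c(1L, 3L))
  out <- gin_layer(H3, e3)
  expect_equal(out[1, ], H3[1, ] + H3[2, ] + H3[3, ])

  # random graphs vs the explicit-loop oracle, with mu and an MLP
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    H <- matrix(rnorm(n * 3), n)
    e <- random_edges(n)
    mu <- runif(1, -0.5, 0.5)
    Wm <- matrix(rnorm(9), 3)
    mlp <- function(x) pmax(x %*% Wm, 0)
    expect_equal(gin_layer(H, e, mlp, mu), mlp(oracle_gin_agg(H, e, mu)),
                 tolerance = 1e-6)
  }
})

test_that("Laplacian PE has the expected eigenstructure", {
  # 2-node path: L = [[1,-1],[-1,1]], eigenvalues {0, 2}
  A <- rbind(c(0, 1), c(1, 0))
  L <- gpdrp:::normalized_laplacian(A)
  expect_equal(L, rbind(c(1, -1), c(-1, 1)))
  expect_equal(eigen(L, symmetric = TRUE)$values, c(2, 0))
  pe <- laplacian_pe(A, 1)
  expect_equal(abs(pe[, 1]), rep(1 / sqrt(2), 2))
  expect_true(pe[which.max(abs(pe[, 1]))[1], 1] > 0)  # sign convention

  # eigenvalues of molecular graphs lie in [0, 2], smallest is 0
  for (s in c("CC", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O")) {
    g <- smiles_to_graph(s)
    ev <- eigen(gpdrp:::normalized_laplacian(gpdrp:::mol_adjacency(g)),
                symmetric = TRUE)$values
    expect_true(all(ev >= -1e-10 & ev <= 2 + 1e-10), label = s)
    expect_equal(min(ev), 0, tolerance = 1e-10)
  }

  # two disconnected components: eigenvalue 0 with multiplicity 2
  A2 <- matrix(0, 4, 4)
  A2[1, 2] <- A2[2, 1] <- 1
  A2[3, 4] <- A2[4, 3] <- 1
  ev <- eigen(gpdrp:::normalized_laplacian(A2), symmetric = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-10), 2L)

  # zero-padding for graphs with fewer than k+1 nodes
  pe2 <- laplacian_pe(A, 5)
  expect_identical(dim(pe2), c(2L, 5L))
  expect_true(all(pe2[, 2:5] == 0))
  expect_error(laplacian_pe(matrix(0, 0, 0), 2), "empty")
})

test_that("graph transformer layer attends over all nodes of one molecule", {
  set.seed(21)
  d <- 6
  p <- make_transformer_params(d)

  # single node: output is the feed-forward transform of its own features
  H1 <- matrix(rnorm(d), 1)
  expect_length(graph_transformer_layer(H1, p), d)

  # zeroed query/key forces uniform attention: equals a hand-built oracle
  p0 <- p
  p0$Wq[] <- 0; p0$Wk[] <- 0
  n <- 5
  H <- matrix(rnorm(n * d), n)
  Vp <- H %*% p0$Wv
  O <- matrix(colMeans(Vp), n, d, byrow = TRUE)   # mean-pooled value projection
  manual <- {
    Aout <- sweep(O %*% p0$Wo, 2L, p0$bo, `+`)
    l1 <- gpdrp:::ln_fwd(H + Aout, p0$ln1)$out
    F2 <- sweep(pmax(sweep(l1 %*% p0$Wf1, 2L, p0$bf1, `+`), 0) %*% p0$Wf2,
                2L, p0$bf2, `+`)
    gpdrp:::ln_fwd(l1 + F2, p0$ln2)$out
  }
  expect_equal(graph_transformer_layer(H, p0), manual, tolerance = 1e-10)

  # permutation equivariance
  perm <- sample(n)
  expect_equal(graph_transformer_layer(H, p)[perm, ],
               graph_transformer_layer(H[perm, ], p), tolerance = 1e-10)
})

test_that("global max pooling is an element-wise node maximum", {
  expect_equal(global_max_pool(rbind(c(1, 5), c(3, 2))), c(3, 5))
  expect_equal(global_max_pool(matrix(c(4, -1), 1)), c(4, -1))
  set.seed(2)
  H <- matrix(rnorm(24), 6)
  expect_equal(global_max_pool(H), global_max_pool(H[sample(6), ]))
  expect_error(global_max_pool(matrix(numeric(), 0, 3)), "empty")
})
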