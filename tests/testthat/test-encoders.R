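test_that("every encoder variant embeds drugs into 128 dimensions", {
  g <- smiles_to_graph("CC(=O)Oc1ccccc1C(=O)O")
  for (v in c("GCN", "GAT", "GIN", "GIN_TRANSFORMER")) {
    m <- gpdrp_init(50, variant = v)
    emb <- drug_encoder_forward(g, m)
    expect_length(emb, 128L)
    expect_true(all(is.finite(emb)), label = v)
  }
})

test_that("embeddings are invariant to atom relabeling", {
  relabel <- function(g, perm) {
    inv <- order(perm)
    gp <- g
    gp$node_features <- g$node_features[perm, , drop = FALSE]
    gp$edges <- cbind(inv[g$edges[, 1]], inv[g$edges[, 2]])
    gp$atoms <- g$atoms[perm, , drop = FALSE]
    gp
  }
  set.seed(77)
  g <- smiles_to_graph("CC(=O)Nc1ccccc1")
  gp <- relabel(g, sample(g$n_atoms))
  for (v in c("GCN", "GAT", "GIN")) {
    m <- gpdrp_init(30, variant = v)
    expect_equal(drug_encoder_forward(g, m), drug_encoder_forward(gp, m),
                 tolerance = 1e-5, label = v)
  }
  # the hybrid encoder's positional encoding fixes eigenvector signs, which
  # pins the embedding only when the Laplacian spectrum is non-degenerate;
  # use a molecule with distinct eigenvalues
  g2 <- smiles_to_graph("CC(=O)NCCO")
  gp2 <- relabel(g2, sample(g2$n_atoms))
  m <- gpdrp_init(30, variant = "GIN_TRANSFORMER")
  expect_equal(drug_encoder_forward(g2, m), drug_encoder_forward(gp2, m),
               tolerance = 1e-5)
})

test_that("different molecules give different embeddings", {
  m <- gpdrp_init(30, variant = "GIN_TRANSFORMER")
  e1 <- drug_encoder_forward(smiles_to_graph("CCO"), m)
  e2 <- drug_encoder_forward(smiles_to_graph("c1ccccc1Cl"), m)
  expect_gt(max(abs(e1 - e2)), 1e-4)
})

test_that("batched encoder agrees with the reference layer implementations", {
  set.seed(12)
  graphs <- lapply(c("CCO", "c1ccncc1", "CC(C)O"), smiles_to_graph)

  # GCN: relu(gcn_layer) x3 -> max pool -> relu(fc)
  m <- gpdrp_init(10, variant = "GCN")
  p <- m$params$drug
  for (k in seq_along(graphs)) {
    g <- graphs[[k]]
    H <- g$node_features
    for (l in 1:3) H <- gcn_layer(H, g$edges, p[[paste0("l", l)]]$W, relu)
    ref <- pmax(drop(global_max_pool(H) %*% p$fc$W) + p$fc$b, 0)
    expect_equal(drug_encoder_forward(g, m), ref, tolerance = 1e-8)
  }

  # GAT: three attention layers with self-loops and relu
  m2 <- gpdrp_init(10, variant = "GAT")
  p2 <- m2$params$drug
  g <- graphs[[2]]
  H <- g$node_features
  for (l in 1:3) {
    lp <- p2[[paste0("l", l)]]
    H <- gat_layer(H, g$edges, lapply(lp, `[[`, "W"),
                   lapply(lp, `[[`, "a1"), lapply(lp, `[[`, "a2"),
                   activation = relu)
    attr(H, "attention") <- NULL
  }
  ref2 <- pmax(drop(global_max_pool(H) %*% p2$fc$W) + p2$fc$b, 0)
  expect_equal(drug_encoder_forward(g, m2), ref2, tolerance = 1e-8)

  # GIN: gin_layer with the layer's MLP + inference-mode batch norm + relu
  m3 <- gpdrp_init(10, variant = "GIN")
  p3 <- m3$params$drug
  H <- g$node_features
  for (l in 1:3) {
    lp <- p3[[paste0("l", l)]]
    st <- m3$state[[paste0("l", l)]]
    mlp <- function(x) {
      h <- pmax(sweep(x %*% lp$W1, 2, lp$b1, `+`), 0)
      pre <- sweep(h %*% lp$W2, 2, lp$b2, `+`)
      xh <- sweep(sweep(pre, 2, st$mean, `-`), 2, 1 / sqrt(st$var + 1e-5), `*`)
      pmax(sweep(sweep(xh, 2, lp$bn$gamma, `*`), 2, lp$bn$beta, `+`), 0)
    }
    H <- gin_layer(H, g$edges, mlp, lp$mu)
  }
  ref3 <- pmax(drop(global_max_pool(H) %*% p3$fc$W) + p3$fc$b, 0)
  expect_equal(drug_encoder_forward(g, m3), ref3, tolerance = 1e-8)
})

test_that("cell-line encoder maps pathway vectors to 128 dimensions deterministically", {
  m <- gpdrp_init(40)
  x <- runif(40)
  e1 <- cellline_encoder_forward(x, m)
  e2 <- cellline_encoder_forward(x, m)
  expect_length(e1, 128L)
  expect_identical(e1, e2)   # inference mode has no dropout
  expect_error(cellline_encoder_forward(runif(39), m), "expected 40.*got 39")
  # architecture widths: 512 -> 1024 -> 128
  expect_identical(dim(m$params$cell$d1$W), c(40L, 512L))
  expect_identical(dim(m$params$cell$d2$W), c(512L, 1024L))
  expect_identical(dim(m$params$cell$d3$W), c(1024L, 128L))
})

test_that("training-mode dropout is seeded and reproducible", {
  m <- gpdrp_init(20)
  x <- matrix(runif(20), 1)
  set.seed(123)
  a <- gpdrp:::cell_forward_b(x, m$params$cell, 0.2, training = TRUE)$emb
  set.seed(123)
  b <- gpdrp:::cell_forward_b(x, m$params$cell, 0.2, training = TRUE)$emb
  set.seed(124)
  c_ <- gpdrp:::cell_forward_b(x, m$params$cell, 0.2, training = TRUE)$emb
  expect_identical(a, b)
  expect_false(identical(a, c_))
})

test_that("analytic gradients match numerical gradients on a small hybrid model", {
  set.seed(42)
  graphs <- lapply(c("CCO", "c1ccccc1C", "C"), smiles_to_graph)
  ctrl <- gpdrp_control(hidden_dim = 6L, embed_dim = 4L, fusion_dims = c(8L, 4L),
                        pe_dim = 2L, dropout = 0, gin_mu_learnable = TRUE)
  config <- gpdrp:::config_from_control("GIN_TRANSFORMER", ctrl)
  gb <- gpdrp:::build_graph_batch(graphs, pe_dim = ctrl$pe_dim)
  n_pw <- 5L
  params <- list(drug = gpdrp:::init_drug_params(config, ncol(gb$X)),
                 cell = list(d1 = gpdrp:::dense_params(n_pw, 7L),
                             d2 = gpdrp:::dense_params(7L, 9L),
                             d3 = gpdrp:::dense_params(9L, 4L)),
                 fuse = list(f1 = gpdrp:::dense_params(8L, 8L),
                             f2 = gpdrp:::dense_params(8L, 4L),
                             f3 = gpdrp:::dense_params(4L, 1L)))
  state <- gpdrp:::init_drug_state(config)
  Xc <- matrix(rnorm(2 * n_pw), 2)
  di <- c(1L, 2L, 3L); ci <- c(1L, 2L, 1L)
  y <- runif(3)
  loss_fn <- function(pp) {
    df <- gpdrp:::drug_forward_b(gb, pp$drug, config, state, TRUE)
    cf <- gpdrp:::cell_forward_b(Xc, pp$cell, 0, TRUE)
    Xf <- cbind(df$emb[di, , drop = FALSE], cf$emb[ci, , drop = FALSE])
    mean((gpdrp:::fuse_forward_b(Xf, pp$fuse)$pred - y)^2)
  }
  df <- gpdrp:::drug_forward_b(gb, params$drug, config, state, TRUE)
  cf <- gpdrp:::cell_forward_b(Xc, params$cell, 0, TRUE)
  Xf <- cbind(df$emb[di, , drop = FALSE], cf$emb[ci, , drop = FALSE])
  fu <- gpdrp:::fuse_forward_b(Xf, params$fuse)
  fb <- gpdrp:::fuse_backward_b(2 * (fu$pred - y) / 3, fu$cache, params$fuse)
  dEd <- gpdrp:::rowsum_full(fb$dXf[, 1:4, drop = FALSE], di, 3L)
  dEc <- gpdrp:::rowsum_full(fb$dXf[, 5:8, drop = FALSE], ci, 2L)
  grads <- list(drug = gpdrp:::drug_backward_b(dEd, df$cache, gb, params$drug, config),
                cell = gpdrp:::cell_backward_b(dEc, cf$cache, params$cell)$grads,
                fuse = fb$grads)

  probe <- list(c("drug", "l1", "W1"), c("drug", "l2", "W2"),
                c("drug", "l3", "Wq"), c("drug", "l3", "Wf1"),
                c("drug", "l1", "mu"), c("drug", "fc", "W"),
                c("cell", "d2", "W"), c("fuse", "f1", "W"))
  eps <- 1e-5
  for (path in probe) {
    leaf <- params[[path[1]]][[path[2]]][[path[3]]]
    gleaf <- grads[[path[1]]][[path[2]]][[path[3]]]
    for (i in sample(length(leaf), min(2L, length(leaf)))) {
      pp <- params
      pp[[path[1]]][[path[2]]][[path[3]]][i] <- leaf[i] + eps
      fp <- loss_fn(pp)
      pp[[path[1]]][[path[2]]][[path[3]]][i] <- leaf[i] - eps
      fm <- loss_fn(pp)
      num <- (fp - fm) / (2 * eps)
      expect_equal(gleaf[i], num, tolerance = 1e-3,
                   label = paste(path, collapse = "$"))
    }
  }
})
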