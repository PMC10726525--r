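# Shared fixtures, built in code. Expensive objects are memoized so several
# test files can share one instance.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# A small synthetic study for fast model-level tests.
tiny_dataset <- function() {
  memo("tiny_dataset", function() {
    generate_synthetic_dataset(synthetic_spec(
      n_drugs = 12L, n_cell_lines = 18L, n_pathways = 40L,
      latent_rank = 5L, seed = 101L))
  })
}

# A fast, low-capacity control for smoke-level fits.
tiny_control <- function(...) {
  defaults <- list(hidden_dim = 16L, embed_dim = 16L, fusion_dims = c(32L, 16L),
                   pe_dim = 4L, gat_heads = 3L, batch_size = 256L,
                   max_epochs = 8L, patience = 8L, seed = 5L)
  do.call(gpdrp_control, utils::modifyList(defaults, list(...)))
}

# The reference-conditions fit used by the acceptance suite: default
# synthetic spec, default control, hybrid encoder. Trained once.
reference_fit <- function() {
  memo("reference_fit", function() {
    ds <- generate_synthetic_dataset(synthetic_spec())
    fit <- gpdrp(ds$responses, ds$drugs, ds$pathways,
                 variant = "GIN_TRANSFORMER", control = gpdrp_control(seed = 1))
    list(data = ds, fit = fit)
  })
}

# Dense brute-force oracle for the normalized GCN propagation rule.
oracle_gcn <- function(H, edges, W) {
  n <- nrow(H)
  A <- matrix(0, n, n)
  if (NROW(edges)) {
    for (r in seq_len(nrow(edges))) {
      A[edges[r, 1], edges[r, 2]] <- 1
      A[edges[r, 2], edges[r, 1]] <- 1
    }
  }
  At <- A + diag(n)
  Dt <- diag(rowSums(At))
  out <- solve(sqrt(Dt)) %*% At %*% solve(sqrt(Dt)) %*% H %*% W
  out
}

# Brute-force GIN aggregation oracle (explicit loops).
oracle_gin_agg <- function(H, edges, mu) {
  n <- nrow(H)
  out <- (1 + mu) * H
  if (NROW(edges)) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      out[i, ] <- out[i, ] + H[j, ]
      out[j, ] <- out[j, ] + H[i, ]
    }
  }
  out
}

# Random connected-ish small graph edge list.
random_edges <- function(n, p = 0.4) {
  e <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(e)) < p
  out <- rbind(e[keep, , drop = FALSE],
               cbind(seq_len(n - 1), 2:n))  # spanning path keeps it connected
  unique(out)
}
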