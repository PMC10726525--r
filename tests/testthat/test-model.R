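test_that("cell-line split has exact rounded sizes and is seed-deterministic", {
  ids <- paste0("CL", 1:10)
  s <- split_by_cellline(ids, seed = 4)
  expect_identical(sort(unique(s$partition)), c("test", "train", "validation"))
  expect_identical(as.integer(table(s$partition)[c("train", "validation", "test")]),
                   c(8L, 1L, 1L))
  expect_identical(split_by_cellline(ids, seed = 4), s)
  expect_false(identical(split_by_cellline(ids, seed = 5)$partition, s$partition))
  expect_setequal(s$cell_line_id, ids)
  expect_error(split_by_cellline(paste0("c", 1:2)), "at least 3")
  expect_error(split_by_cellline(ids, fractions = c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("pairs inherit their cell line's partition with no leakage", {
  ids <- paste0("CL", 1:20)
  s <- split_by_cellline(ids, seed = 9)
  pairs <- expand.grid(drug_id = paste0("D", 1:7), cell_line_id = ids,
                       stringsAsFactors = FALSE)
  pairs$partition <- s$partition[match(pairs$cell_line_id, s$cell_line_id)]
  per_cell <- tapply(pairs$partition, pairs$cell_line_id,
                     function(p) length(unique(p)))
  expect_true(all(per_cell == 1L))
  parts <- split(pairs$cell_line_id, pairs$partition)
  expect_length(Reduce(intersect, parts), 0L)
})

test_that("rmse and pearson match brute-force oracles", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(rmse(c(0, 0), c(1, 1)), 1)
  x <- rnorm(50); y <- rnorm(50)
  brute_rmse <- { s <- 0; for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
                  sqrt(s / length(x)) }
  expect_equal(rmse(x, y), brute_rmse, tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "mismatch")

  expect_equal(pearson(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson(1:10, -(1:10)), -1)
  mx <- mean(x); my <- mean(y)
  brute_pcc <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  expect_equal(pearson(x, y), brute_pcc, tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), "constant")
  expect_error(pearson(1, 1), "at least two")
})

test_that("fusion head concatenates drug-first and squashes into (0,1)", {
  m <- gpdrp_init(25)
  expect_identical(nrow(m$params$fuse$f1$W), 256L)  # fused vector length
  d <- runif(128); c_ <- runif(128)
  p1 <- fuse_and_predict(d, c_, m)
  expect_true(p1 > 0 && p1 < 1)
  expect_identical(fuse_and_predict(d, c_, m), p1)  # deterministic
  expect_error(fuse_and_predict(runif(64), c_, m), "length 128")

  # zeroed final layer gives squash(0) = 0.5
  m0 <- m
  m0$params$fuse$f3$W[] <- 0
  m0$params$fuse$f3$b[] <- 0
  expect_identical(fuse_and_predict(d, c_, m0), 0.5)
})

test_that("a fitted model predicts finite scaled values, order-invariantly", {
  ds <- tiny_dataset()
  fit <- gpdrp(ds$responses, ds$drugs, ds$pathways, variant = "GCN",
               control = tiny_control())
  pred <- predict(fit)
  expect_true(all(pred$pred_scaled > 0 & pred$pred_scaled < 1))
  expect_true(all(is.finite(pred$pred_ln)))
  expect_equal(unscale_response(pred$pred_scaled), pred$pred_ln)

  pairs <- fit$fitted[, c("drug_id", "cell_line_id")]
  perm <- sample(nrow(pairs))
  pred2 <- predict(fit, pairs = pairs[perm, ])
  expect_equal(pred2$pred_scaled, pred$pred_scaled[perm])

  # unknown ids are reported
  expect_error(predict(fit, pairs = data.frame(drug_id = "NOPE",
                                               cell_line_id = "CL001")),
               "NOPE")
})

test_that("unlabeled cross-product prediction counts n_drugs*n_cells - n_labeled", {
  ds <- tiny_dataset()
  fit <- gpdrp(ds$responses, ds$drugs, ds$pathways, variant = "GCN",
               control = tiny_control())
  lab <- ds$responses[!is.na(ds$responses$ln_ic50), ]
  grid <- expand.grid(drug_id = ds$drugs$drug_id,
                      cell_line_id = ds$pathways$cell_line_ids,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$drug_id, d$cell_line_id)
  unl <- grid[!key(grid) %in% key(lab), ]
  expect_identical(nrow(unl),
                   nrow(ds$drugs) * length(ds$pathways$cell_line_ids) - nrow(lab))
  pu <- predict(fit, pairs = unl)
  expect_identical(nrow(pu), nrow(unl))
  expect_true(all(is.finite(pu$pred_ln)))
})

test_that("training is deterministic for a fixed seed", {
  ds <- tiny_dataset()
  f1 <- gpdrp(ds$responses, ds$drugs, ds$pathways, variant = "GIN",
              control = tiny_control(max_epochs = 4L))
  f2 <- gpdrp(ds$responses, ds$drugs, ds$pathways, variant = "GIN",
              control = tiny_control(max_epochs = 4L))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$split, f2$split)
  expect_equal(coef(f1), coef(f2))
})

test_that("no cell line spans two partitions in a fitted model", {
  ds <- tiny_dataset()
  fit <- gpdrp(ds$responses, ds$drugs, ds$pathways, variant = "GCN",
               control = tiny_control(max_epochs = 2L))
  parts <- split(fit$split$cell_line_id, fit$split$partition)
  expect_length(intersect(parts$train, parts$validation), 0L)
  expect_length(intersect(parts$train, parts$test), 0L)
  expect_length(intersect(parts$validation, parts$test), 0L)
  expect_setequal(unlist(parts), fit$split$cell_line_id)
  # and the per-pair table agrees
  per_cell <- tapply(fit$fitted$partition, fit$fitted$cell_line_id,
                     function(p) length(unique(p)))
  expect_true(all(per_cell == 1L))
})

test_that("one optimizer step on a single example decreases its loss", {
  set.seed(8)
  graphs <- list(smiles_to_graph("CC(=O)Nc1ccccc1"))
  ctrl <- gpdrp_control(hidden_dim = 8L, embed_dim = 8L,
                        fusion_dims = c(16L, 8L), dropout = 0)
  config <- gpdrp:::config_from_control("GIN", ctrl)
  gb <- gpdrp:::build_graph_batch(graphs)
  params <- list(drug = gpdrp:::init_drug_params(config, ncol(gb$X)),
                 cell = list(d1 = gpdrp:::dense_params(6L, 8L),
                             d2 = gpdrp:::dense_params(8L, 8L),
                             d3 = gpdrp:::dense_params(8L, 8L)),
                 fuse = list(f1 = gpdrp:::dense_params(16L, 16L),
                             f2 = gpdrp:::dense_params(16L, 8L),
                             f3 = gpdrp:::dense_params(8L, 1L)))
  state <- gpdrp:::init_drug_state(config)
  Xc <- matrix(runif(6), 1)
  y <- 0.8
  loss_of <- function(pp) {
    df <- gpdrp:::drug_forward_b(gb, pp$drug, config, state, TRUE)
    cf <- gpdrp:::cell_forward_b(Xc, pp$cell, 0, TRUE)
    fu <- gpdrp:::fuse_forward_b(cbind(df$emb, cf$emb), pp$fuse)
    (fu$pred - y)^2
  }
  df <- gpdrp:::drug_forward_b(gb, params$drug, config, state, TRUE)
  cf <- gpdrp:::cell_forward_b(Xc, params$cell, 0, TRUE)
  fu <- gpdrp:::fuse_forward_b(cbind(df$emb, cf$emb), params$fuse)
  loss0 <- (fu$pred - y)^2
  fb <- gpdrp:::fuse_backward_b(2 * (fu$pred - y), fu$cache, params$fuse)
  grads <- list(
    drug = gpdrp:::drug_backward_b(fb$dXf[, 1:8, drop = FALSE], df$cache, gb,
                                   params$drug, config),
    cell = gpdrp:::cell_backward_b(fb$dXf[, 9:16, drop = FALSE], cf$cache,
                                   params$cell)$grads,
    fuse = fb$grads)
  stp <- gpdrp:::adam_step(params, grads, gpdrp:::adam_init(params), lr = 0.05)
  expect_lt(loss_of(stp$params), loss0)
})

test_that("training loss decreases over epochs on learnable signal", {
  ds <- tiny_dataset()
  fit <- gpdrp(ds$responses, ds$drugs, ds$pathways, variant = "GIN_TRANSFORMER",
               control = tiny_control(max_epochs = 8L))
  h <- fit$history
  expect_lt(mean(tail(h$train_loss, 2)), mean(head(h$train_loss, 2)))
  expect_true(all(c("epoch", "train_loss", "val_rmse", "val_pcc") %in% names(h)))
  # metric bookkeeping
  expect_identical(fit$metrics$validation$scale, "scaled")
  expect_true(fit$metrics$train$rmse >= 0 && fit$metrics$train$rmse <= 1)
})

test_that("model methods behave", {
  ds <- tiny_dataset()
  fit <- gpdrp(ds$responses, ds$drugs, ds$pathways, variant = "GCN",
               control = tiny_control(max_epochs = 3L))
  expect_output(print(fit), "drug-response model")
  expect_output(print(summary(fit)), "Trainable parameters")
  expect_type(coef(fit), "list")
  r <- residuals(fit)
  expect_equal(r, fit$fitted$observed_scaled - fit$fitted$fitted_scaled)
  r_ln <- residuals(fit, scale = "ln")
  expect_length(r_ln, nrow(fit$fitted))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(dim(sims), c(nrow(fit$fitted), 2L))
  expect_true(all(sims > 0 & sims < 1))
  f <- withr::local_tempfile(fileext = ".pdf")
  pdf(f); plot(fit); dev.off()
  expect_true(file.exists(f))
})
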