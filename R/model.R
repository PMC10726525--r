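# Model fitting: cell-line-grouped splitting, the training loop, metrics,
# and prediction.

#' Cell-line-grouped train/validation/test split
#'
#' Partitions cell lines (not pairs) into train/validation/test so that no
#' cell line ever spans two partitions — every drug/cell-line pair inherits
#' the partition of its cell line, ruling out cell-line leakage. Group
#' sizes are the rounded fractions with the remainder assigned to train;
#' the assignment is deterministic for a fixed seed.
#'
#' @param cell_line_ids Character vector of cell line ids (>= 3).
#' @param fractions Train/validation/test fractions, positive, summing to 1.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return Object of class `split_assignment`: a data frame with columns
#'   `cell_line_id` and `partition` plus attributes `fractions` and `seed`.
#' @export
#' @examples
#' s <- split_by_cellline(paste0("CL", 1:10), seed = 1)
#' table(s$partition)  # 8 train, 1 validation, 1 test
split_by_cellline <- function(cell_line_ids, fractions = c(0.8, 0.1, 0.1),
                              seed = NULL) {
  cell_line_ids <- unique(as.character(cell_line_ids))
  n <- length(cell_line_ids)
  if (n < 3L) stop("need at least 3 cell lines to form 3 groups")
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be 3 positive numbers summing to 1")
  }
  if (!is.null(seed)) set.seed(seed)
  n_val <- round(fractions[2] * n)
  n_test <- round(fractions[3] * n)
  perm <- sample(cell_line_ids)
  partition <- rep("train", n)
  if (n_val > 0L) partition[seq_len(n_val)] <- "validation"
  if (n_test > 0L) partition[n_val + seq_len(n_test)] <- "test"
  out <- data.frame(cell_line_id = perm, partition = partition,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$cell_line_id, cell_line_ids)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, fractions = fractions, seed = seed,
            class = c("split_assignment", "data.frame"))
}

#' Root mean squared error
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return `sqrt(mean((actual - predicted)^2))`.
#' @export
rmse <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (length(actual) < 1L) stop("need at least one observation")
  sqrt(mean((actual - predicted)^2))
}

#' Pearson correlation coefficient
#'
#' Standard Pearson correlation (covariance over the product of standard
#' deviations) between observed and predicted responses.
#'
#' @param actual,predicted Equal-length numeric vectors (length >= 2,
#'   neither constant).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (length(actual) < 2L) stop("need at least two observations")
  if (sd(actual) == 0 || sd(predicted) == 0) {
    stop("constant input: correlation undefined")
  }
  cor(actual, predicted)
}

eval_report <- function(actual, predicted, scale) {
  pcc <- if (length(actual) >= 2L && sd(actual) > 0 && sd(predicted) > 0) {
    cor(actual, predicted)
  } else NA_real_
  structure(list(rmse = rmse(actual, predicted), pccs = pcc,
                 n_pairs = length(actual), scale = scale),
            class = "eval_report")
}

#' @method print eval_report
#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("RMSE %.4f, PCC %s on %d pairs (%s scale)\n", x$rmse,
              ifelse(is.na(x$pccs), "NA", sprintf("%.4f", x$pccs)),
              x$n_pairs, x$scale))
  invisible(x)
}

#' Training control parameters
#'
#' Hyperparameters and architecture settings for [gpdrp()]. Optimizer,
#' learning rate, dropout, activation and layer counts follow the reference
#' configuration (Adam, 1e-4, 0.2, rectifier, three graph layers); batch
#' size, epoch budget and early-stopping patience are implementation
#' defaults, all recorded on the fitted object.
#'
#' @param hidden_dim,gat_heads,gin_mu_learnable,pe_dim,embed_dim,dropout,
#'   transformer_position Encoder settings; see [encoder_config()].
#' @param fusion_dims Widths of the two fusion layers (1024, 128).
#' @param learning_rate Adam learning rate (> 0).
#' @param batch_size Pairs per optimizer step.
#' @param max_epochs Epoch budget.
#' @param patience Early-stopping patience on validation RMSE, in epochs.
#' @param seed Integer seed covering initialization, the split, shuffling
#'   and dropout.
#' @param normalize `"train"` (min-max statistics from training cell lines
#'   only, leakage-free; default) or `"global"` (statistics across all cell
#'   lines).
#' @param fractions Cell-line split fractions.
#' @param verbose Print one line per epoch?
#' @return Object of class `gpdrp_control`.
#' @export
gpdrp_control <- function(hidden_dim = 128L, gat_heads = 10L,
                          gin_mu_learnable = FALSE, pe_dim = 8L,
                          embed_dim = 128L, dropout = 0.2,
                          transformer_position = c("last", "first"),
                          fusion_dims = c(1024L, 128L),
                          learning_rate = 1e-4, batch_size = 512L,
                          max_epochs = 200L, patience = 20L, seed = 1L,
                          normalize = c("train", "global"),
                          fractions = c(0.8, 0.1, 0.1), verbose = FALSE) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (max_epochs < 1L) stop("max_epochs must be >= 1")
  structure(list(hidden_dim = as.integer(hidden_dim),
                 gat_heads = as.integer(gat_heads),
                 gin_mu_learnable = isTRUE(gin_mu_learnable),
                 pe_dim = as.integer(pe_dim),
                 embed_dim = as.integer(embed_dim), dropout = dropout,
                 transformer_position = match.arg(transformer_position),
                 fusion_dims = as.integer(fusion_dims),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 normalize = match.arg(normalize), fractions = fractions,
                 verbose = isTRUE(verbose)),
            class = "gpdrp_control")
}

config_from_control <- function(variant, control) {
  encoder_config(variant = variant, hidden_dim = control$hidden_dim,
                 gat_heads = control$gat_heads,
                 gin_mu_learnable = control$gin_mu_learnable,
                 pe_dim = control$pe_dim, embed_dim = control$embed_dim,
                 dropout = control$dropout,
                 transformer_position = control$transformer_position)
}

#' Fit the multimodal drug-response model
#'
#' Trains the two-branch regressor: a graph neural network encodes each
#' drug's molecular graph into a 128-dimensional embedding, a dense network
#' encodes each cell line's (min-max normalized) pathway-score vector into
#' another 128-dimensional embedding, and a fully connected head maps the
#' concatenated 256-dimensional representation to the response on the (0,1)
#' scale of [scale_response()]. Training minimizes mean squared error on
#' the scaled response with Adam, early-stopping on validation RMSE; the
#' validation and test cell lines never overlap the training cell lines
#' (see [split_by_cellline()]).
#'
#' @param responses Data frame with columns `drug_id`, `cell_line_id`,
#'   `ln_ic50` (LN IC50; `NA` marks unlabeled pairs, which are excluded
#'   from training).
#' @param drugs Data frame with columns `drug_id`, `smiles` covering every
#'   drug in `responses`.
#' @param pathways A [pathway_matrix()] (pathways x cell lines) covering
#'   every cell line in `responses`. Raw scores are min-max normalized
#'   internally per `control$normalize`; pre-normalized matrices are used
#'   as-is.
#' @param variant Drug-encoder variant; the hybrid
#'   graph-transformer/GIN stack is the default.
#' @param control A [gpdrp_control()] object.
#' @param schema Atom featurization schema.
#' @param split Optional pre-computed [split_by_cellline()] assignment.
#' @return An object of class `gpdrp` with `print`, `summary`, `coef`,
#'   `predict`, `plot`, `residuals` and `simulate` methods.
#' @export
gpdrp <- function(responses, drugs, pathways,
                  variant = c("GIN_TRANSFORMER", "GCN", "GAT", "GIN"),
                  control = gpdrp_control(), schema = build_atom_schema(),
                  split = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(control, "gpdrp_control"))
  if (!inherits(pathways, "pathway_matrix")) pathways <- pathway_matrix(pathways)
  need <- c("drug_id", "cell_line_id", "ln_ic50")
  if (!all(need %in% names(responses))) {
    stop("responses must have columns ", paste(need, collapse = ", "))
  }
  responses$drug_id <- as.character(responses$drug_id)
  responses$cell_line_id <- as.character(responses$cell_line_id)
  bad_drug <- setdiff(responses$drug_id, drugs$drug_id)
  if (length(bad_drug)) stop("drugs missing from drug table: ",
                             paste(head(bad_drug, 5L), collapse = ", "))
  bad_cell <- setdiff(responses$cell_line_id, pathways$cell_line_ids)
  if (length(bad_cell)) stop("cell lines missing from pathway matrix: ",
                             paste(head(bad_cell, 5L), collapse = ", "))

  cl <- match.call()
  set.seed(control$seed)
  config <- config_from_control(variant, control)

  labeled <- responses[!is.na(responses$ln_ic50), , drop = FALSE]
  if (!nrow(labeled)) stop("no labeled pairs to train on")
  cells <- sort(unique(labeled$cell_line_id))
  if (is.null(split)) {
    split <- split_by_cellline(cells, control$fractions, seed = NULL)
  } else {
    missing_cells <- setdiff(cells, split$cell_line_id)
    if (length(missing_cells)) stop("split does not cover all cell lines")
  }

  # normalization: statistics from training cells (leak-free) or global
  norm_stats <- NULL
  if (!pathways$normalized) {
    stat_cells <- if (control$normalize == "train") {
      split$cell_line_id[split$partition == "train"]
    } else NULL
    pathways <- minmax_normalize(pathways, stat_cells = stat_cells)
    norm_stats <- attr(pathways, "stats")
  }
  Xc <- t(pathways$values)          # cell lines x pathways
  cell_ids <- pathways$cell_line_ids

  graphs <- lapply(drugs$smiles, smiles_to_graph, schema = schema)
  names(graphs) <- drugs$drug_id
  pe_dim <- if (variant == "GIN_TRANSFORMER") control$pe_dim else NULL
  gb <- build_graph_batch(graphs, pe_dim = pe_dim)
  d_in <- ncol(gb$X)

  params <- list(drug = init_drug_params(config, d_in),
                 cell = init_cell_params(nrow(pathways$values),
                                         control$embed_dim),
                 fuse = init_fuse_params(control$embed_dim,
                                         control$fusion_dims))
  state <- init_drug_state(config)

  di <- match(labeled$drug_id, drugs$drug_id)
  ci <- match(labeled$cell_line_id, cell_ids)
  part <- split$partition[match(labeled$cell_line_id, split$cell_line_id)]
  y <- scale_response(labeled$ln_ic50)
  idx_train <- which(part == "train")
  idx_val <- which(part == "validation")
  idx_test <- which(part == "test")
  if (!length(idx_train)) stop("empty training partition")
  if (!length(idx_val)) stop("empty validation partition")

  G <- length(graphs); C <- length(cell_ids); ed <- control$embed_dim
  opt <- adam_init(params)
  history <- data.frame()
  best <- list(val_rmse = Inf, params = params, state = state, epoch = 0L)
  stall <- 0L

  infer_preds <- function(params, state, idx) {
    df <- drug_forward_b(gb, params$drug, config, state, training = FALSE)
    cf <- cell_forward_b(Xc, params$cell, control$dropout, training = FALSE)
    Xf <- cbind(df$emb[di[idx], , drop = FALSE], cf$emb[ci[idx], , drop = FALSE])
    fuse_forward_b(Xf, params$fuse)$pred
  }

  for (epoch in seq_len(control$max_epochs)) {
    perm <- sample(idx_train)
    batches <- split(perm, ceiling(seq_along(perm) / control$batch_size))
    ep_loss <- 0
    for (b in batches) {
      df <- drug_forward_b(gb, params$drug, config, state, training = TRUE)
      state <- df$state
      cf <- cell_forward_b(Xc, params$cell, control$dropout, training = TRUE)
      Xf <- cbind(df$emb[di[b], , drop = FALSE], cf$emb[ci[b], , drop = FALSE])
      fu <- fuse_forward_b(Xf, params$fuse)
      err <- fu$pred - y[b]
      loss <- mean(err^2)
      if (!is.finite(loss)) stop("non-finite loss at epoch ", epoch,
                                 "; check inputs and learning rate")
      ep_loss <- ep_loss + loss * length(b)
      fb <- fuse_backward_b(2 * err / length(b), fu$cache, params$fuse)
      dEd <- rowsum_full(fb$dXf[, seq_len(ed), drop = FALSE], di[b], G)
      dEc <- rowsum_full(fb$dXf[, ed + seq_len(ed), drop = FALSE], ci[b], C)
      grads <- list(drug = drug_backward_b(dEd, df$cache, gb, params$drug, config),
                    cell = cell_backward_b(dEc, cf$cache, params$cell)$grads,
                    fuse = fb$grads)
      stp <- adam_step(params, grads, opt, control$learning_rate)
      params <- stp$params
      opt <- stp$state
    }
    pv <- infer_preds(params, state, idx_val)
    val_rmse <- rmse(y[idx_val], pv)
    val_pcc <- if (sd(pv) > 0) cor(y[idx_val], pv) else NA_real_
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / length(idx_train),
      val_rmse = val_rmse, val_pcc = val_pcc))
    if (control$verbose) {
      message(sprintf("epoch %3d  train MSE %.6f  val RMSE %.6f  val PCC %s",
                      epoch, ep_loss / length(idx_train), val_rmse,
                      ifelse(is.na(val_pcc), "NA", sprintf("%.4f", val_pcc))))
    }
    if (val_rmse < best$val_rmse) {
      best <- list(val_rmse = val_rmse, params = params, state = state,
                   epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= control$patience) break
    }
  }

  params <- best$params
  state <- best$state

  all_pred <- infer_preds(params, state, seq_len(nrow(labeled)))
  fitted <- data.frame(drug_id = labeled$drug_id,
                       cell_line_id = labeled$cell_line_id,
                       partition = part,
                       observed_ln = labeled$ln_ic50,
                       observed_scaled = y,
                       fitted_scaled = all_pred,
                       fitted_ln = unscale_response(pmin(pmax(all_pred, 1e-12),
                                                         1 - 1e-12)),
                       stringsAsFactors = FALSE)
  metrics <- list(
    train = eval_report(y[idx_train], all_pred[idx_train], "scaled"),
    validation = eval_report(y[idx_val], all_pred[idx_val], "scaled"),
    test = if (length(idx_test)) {
      eval_report(y[idx_test], all_pred[idx_test], "scaled")
    } else NULL)

  structure(list(call = cl, variant = variant, config = config,
                 control = control, schema = schema,
                 params = params, state = state,
                 drugs = drugs[, c("drug_id", "smiles")], graphs = graphs,
                 graph_batch = gb,
                 pathway_ids = pathways$pathway_ids,
                 cell_features = Xc, cell_ids = cell_ids,
                 norm_stats = norm_stats,
                 split = split, history = history,
                 best_epoch = best$epoch, metrics = metrics,
                 fitted = fitted,
                 sigma_scaled = sd(fitted$fitted_scaled[idx_train] -
                                     y[idx_train])),
            class = "gpdrp")
}

#' Initialize an untrained model
#'
#' Builds a `gpdrp` object with freshly initialized (untrained) parameters,
#' useful for inspecting architecture shapes (embedding and fusion
#' dimensions) and as a starting point for encoder forward passes.
#'
#' @param n_pathways Length of the cell-line feature vector.
#' @param variant Drug encoder variant.
#' @param control A [gpdrp_control()].
#' @param schema Atom featurization schema.
#' @return An untrained object of class `gpdrp` (no history or metrics).
#' @export
gpdrp_init <- function(n_pathways,
                       variant = c("GIN_TRANSFORMER", "GCN", "GAT", "GIN"),
                       control = gpdrp_control(),
                       schema = build_atom_schema()) {
  variant <- match.arg(variant)
  set.seed(control$seed)
  config <- config_from_control(variant, control)
  d_in <- schema$total_dim +
    if (variant == "GIN_TRANSFORMER") control$pe_dim else 0L
  params <- list(drug = init_drug_params(config, d_in),
                 cell = init_cell_params(n_pathways, control$embed_dim),
                 fuse = init_fuse_params(control$embed_dim,
                                         control$fusion_dims))
  structure(list(call = match.call(), variant = variant, config = config,
                 control = control, schema = schema, params = params,
                 state = init_drug_state(config),
                 pathway_ids = paste0("PW", seq_len(n_pathways)),
                 history = data.frame(), metrics = list()),
            class = "gpdrp")
}

#' Embed one drug with a model's graph encoder
#'
#' Runs the drug branch on a single molecular graph: graph layers, global
#' max pooling, and the final fully connected layer, returning the
#' 128-dimensional embedding (inference mode).
#'
#' @param graph A `molecular_graph` (or a SMILES string).
#' @param model A fitted or [gpdrp_init()]-ialized `gpdrp` object.
#' @return Numeric vector of length `model$control$embed_dim`.
#' @export
drug_encoder_forward <- function(graph, model) {
  stopifnot(inherits(model, "gpdrp"))
  if (is.character(graph)) graph <- smiles_to_graph(graph, model$schema)
  pe_dim <- if (model$variant == "GIN_TRANSFORMER") model$control$pe_dim else NULL
  gb <- build_graph_batch(list(graph), pe_dim = pe_dim)
  drop(drug_forward_b(gb, model$params$drug, model$config, model$state,
                      training = FALSE)$emb)
}

#' Embed one cell line with a model's dense encoder
#'
#' Runs the cell branch (dense 512 -> 1024 -> 128, rectifier activations,
#' dropout disabled at inference) on a pathway-score feature vector.
#'
#' @param features Numeric vector of normalized pathway scores, in the
#'   model's pathway order.
#' @param model A `gpdrp` object.
#' @return Numeric vector of length `model$control$embed_dim`.
#' @export
cellline_encoder_forward <- function(features, model) {
  stopifnot(inherits(model, "gpdrp"))
  expected <- length(model$pathway_ids)
  if (length(features) != expected) {
    stop("pathway feature axis mismatch: expected ", expected, " features, got ",
         length(features))
  }
  cf <- cell_forward_b(matrix(features, nrow = 1L), model$params$cell,
                       model$config$dropout, training = FALSE)
  drop(cf$emb)
}

#' Fuse two embeddings and predict a scaled response
#'
#' Concatenates the drug and cell-line embeddings (drug first) into the
#' 256-dimensional fused vector and applies the fully connected head
#' (1024 -> 128 -> 1) with a sigmoid output, so the prediction lies on the
#' (0,1) scaled-response range.
#'
#' @param drug_embedding,cell_embedding Numeric vectors of length 128.
#' @param model A `gpdrp` object.
#' @return Scalar predicted scaled response in (0,1).
#' @export
fuse_and_predict <- function(drug_embedding, cell_embedding, model) {
  stopifnot(inherits(model, "gpdrp"))
  ed <- model$control$embed_dim
  if (length(drug_embedding) != ed || length(cell_embedding) != ed) {
    stop("embeddings must both have length ", ed)
  }
  Xf <- matrix(c(drug_embedding, cell_embedding), nrow = 1L)
  fuse_forward_b(Xf, model$params$fuse)$pred
}

#' Predict responses for drug / cell-line pairs
#'
#' @param object A fitted `gpdrp` model.
#' @param pairs Data frame with columns `drug_id`, `cell_line_id`; defaults
#'   to the model's labeled training universe.
#' @param drugs Optional drug table (`drug_id`, `smiles`) supplying drugs
#'   not seen at fit time.
#' @param pathways Optional [pathway_matrix()] supplying additional cell
#'   lines/samples; its pathway axis must match the model's (same ids). Raw
#'   matrices are normalized with the statistics stored at fit time.
#' @param ... Unused.
#' @return Data frame with columns `drug_id`, `cell_line_id`,
#'   `pred_scaled` (on (0,1)) and `pred_ln` (LN IC50 via
#'   [unscale_response()]). Row order follows `pairs`.
#' @export
predict.gpdrp <- function(object, pairs = NULL, drugs = NULL,
                          pathways = NULL, ...) {
  if (is.null(object$graphs)) stop("model has no fitted data; supply pairs, drugs and pathways to predict_pairs()")
  if (is.null(pairs)) {
    pairs <- object$fitted[, c("drug_id", "cell_line_id")]
  }
  pairs$drug_id <- as.character(pairs$drug_id)
  pairs$cell_line_id <- as.character(pairs$cell_line_id)

  graphs <- object$graphs
  if (!is.null(drugs)) {
    extra <- drugs[!drugs$drug_id %in% names(graphs), , drop = FALSE]
    if (nrow(extra)) {
      newg <- lapply(extra$smiles, smiles_to_graph, schema = object$schema)
      names(newg) <- extra$drug_id
      graphs <- c(graphs, newg)
    }
  }
  Xc <- object$cell_features
  cell_ids <- object$cell_ids
  if (!is.null(pathways)) {
    if (!inherits(pathways, "pathway_matrix")) pathways <- pathway_matrix(pathways)
    if (!identical(pathways$pathway_ids, object$pathway_ids)) {
      if (setequal(pathways$pathway_ids, object$pathway_ids)) {
        pathways <- pathway_matrix(
          pathways$values[match(object$pathway_ids, pathways$pathway_ids), ,
                          drop = FALSE],
          object$pathway_ids, pathways$cell_line_ids,
          normalized = pathways$normalized)
      } else {
        stop("pathway axis mismatch: model was trained on ",
             length(object$pathway_ids), " pathways")
      }
    }
    if (!pathways$normalized) {
      if (is.null(object$norm_stats)) {
        stop("model was fitted on pre-normalized scores; supply a normalized matrix")
      }
      v <- (pathways$values - object$norm_stats$min) /
        ifelse(object$norm_stats$max > object$norm_stats$min,
               object$norm_stats$max - object$norm_stats$min, 1)
      v[object$norm_stats$constant, ] <- 0
      v <- pmin(pmax(v, 0), 1)
      pathways <- pathway_matrix(v, pathways$pathway_ids,
                                 pathways$cell_line_ids, normalized = TRUE)
    }
    keep_new <- !pathways$cell_line_ids %in% cell_ids
    Xc <- rbind(Xc, t(pathways$values[, keep_new, drop = FALSE]))
    cell_ids <- c(cell_ids, pathways$cell_line_ids[keep_new])
  }

  bad_d <- setdiff(unique(pairs$drug_id), names(graphs))
  bad_c <- setdiff(unique(pairs$cell_line_id), cell_ids)
  if (length(bad_d) || length(bad_c)) {
    stop("unknown ids in pairs: ",
         paste(c(if (length(bad_d)) paste0("drugs [", paste(bad_d, collapse = ", "), "]"),
                 if (length(bad_c)) paste0("cells [", paste(bad_c, collapse = ", "), "]")),
               collapse = "; "))
  }

  used_drugs <- unique(pairs$drug_id)
  pe_dim <- if (object$variant == "GIN_TRANSFORMER") object$control$pe_dim else NULL
  gb <- build_graph_batch(graphs[used_drugs], pe_dim = pe_dim)
  demb <- drug_forward_b(gb, object$params$drug, object$config, object$state,
                         training = FALSE)$emb
  cemb <- cell_forward_b(Xc, object$params$cell, object$config$dropout,
                         training = FALSE)$emb
  di <- match(pairs$drug_id, used_drugs)
  ci <- match(pairs$cell_line_id, cell_ids)
  Xf <- cbind(demb[di, , drop = FALSE], cemb[ci, , drop = FALSE])
  pred <- fuse_forward_b(Xf, object$params$fuse)$pred
  data.frame(drug_id = pairs$drug_id, cell_line_id = pairs$cell_line_id,
             pred_scaled = pred,
             pred_ln = unscale_response(pmin(pmax(pred, 1e-12), 1 - 1e-12)),
             stringsAsFactors = FALSE)
}

#' @rdname predict.gpdrp
#' @param model A fitted `gpdrp` model (alias of `object`).
#' @export
predict_pairs <- function(model, pairs = NULL, drugs = NULL, pathways = NULL) {
  predict(model, pairs = pairs, drugs = drugs, pathways = pathways)
}

#' Pivot pair predictions into a samples x drugs matrix
#'
#' @param pred Data frame from [predict.gpdrp()].
#' @param value `"ln"` (default) or `"scaled"`.
#' @return Numeric matrix, rows = cell lines/samples, columns = drugs.
#' @export
prediction_matrix <- function(pred, value = c("ln", "scaled")) {
  value <- match.arg(value)
  col <- if (value == "ln") "pred_ln" else "pred_scaled"
  cells <- unique(pred$cell_line_id)
  drugs <- unique(pred$drug_id)
  M <- matrix(NA_real_, length(cells), length(drugs),
              dimnames = list(cells, drugs))
  M[cbind(match(pred$cell_line_id, cells), match(pred$drug_id, drugs))] <-
    pred[[col]]
  if (anyNA(M)) stop("pairs do not form a complete cell x drug grid")
  M
}
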