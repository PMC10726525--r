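# S3 methods for fitted gpdrp models.

#' @method print gpdrp
#' @export
print.gpdrp <- function(x, ...) {
  cat("Multimodal drug-response model (", x$variant, " drug encoder)\n", sep = "")
  if (!is.null(x$drugs)) {
    cat("  ", nrow(x$drugs), " drugs, ", length(x$cell_ids), " cell lines, ",
        length(x$pathway_ids), " pathway features\n", sep = "")
  } else {
    cat("  untrained (", length(x$pathway_ids), " pathway features)\n", sep = "")
  }
  if (nrow(x$history)) {
    cat("  trained ", nrow(x$history), " epochs (best epoch ", x$best_epoch,
        ")\n", sep = "")
    if (!is.null(x$metrics$test)) {
      cat("  test: ")
      print(x$metrics$test)
    }
  }
  invisible(x)
}

#' @method summary gpdrp
#' @export
summary.gpdrp <- function(object, ...) {
  structure(list(variant = object$variant, control = object$control,
                 split = if (!is.null(object$split))
                   table(object$split$partition) else NULL,
                 history = object$history, best_epoch = object$best_epoch,
                 metrics = object$metrics,
                 n_params = sum(unlist(tree_map(length, object$params)))),
            class = "summary.gpdrp")
}

#' @method print summary.gpdrp
#' @export
print.summary.gpdrp <- function(x, ...) {
  cat("Drug-response model, drug encoder:", x$variant, "\n")
  cat("Trainable parameters:", format(x$n_params, big.mark = ","), "\n")
  if (!is.null(x$split)) {
    cat("Cell-line split:",
        paste(names(x$split), as.integer(x$split), collapse = ", "), "\n")
  }
  if (nrow(x$history)) {
    cat("Epochs run:", nrow(x$history), " (best:", x$best_epoch, ")\n")
    for (nm in names(x$metrics)) {
      if (!is.null(x$metrics[[nm]])) {
        cat(sprintf("  %-10s ", nm)); print(x$metrics[[nm]])
      }
    }
  }
  invisible(x)
}

#' @export
coef.gpdrp <- function(object, ...) object$params

#' @export
fitted.gpdrp <- function(object, ...) object$fitted$fitted_scaled

#' Residuals of a fitted drug-response model
#'
#' @param object A fitted `gpdrp` model.
#' @param scale `"scaled"` (observed minus fitted on the (0,1) training
#'   scale, default) or `"ln"` (LN IC50 scale).
#' @param ... Unused.
#' @return Numeric vector over the labeled pairs, in `object$fitted` order.
#' @export
residuals.gpdrp <- function(object, scale = c("scaled", "ln"), ...) {
  scale <- match.arg(scale)
  if (scale == "scaled") {
    object$fitted$observed_scaled - object$fitted$fitted_scaled
  } else {
    object$fitted$observed_ln - object$fitted$fitted_ln
  }
}

#' Plot training history
#'
#' Training mean-squared error and validation RMSE per epoch, with the
#' early-stopping epoch marked.
#'
#' @param x A fitted `gpdrp` model.
#' @param ... Passed to [plot()].
#' @export
plot.gpdrp <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("no training history to plot")
  plot(h$epoch, sqrt(h$train_loss), type = "l", col = "grey40",
       xlab = "epoch", ylab = "RMSE (scaled response)",
       ylim = range(c(sqrt(h$train_loss), h$val_rmse)), ...)
  lines(h$epoch, h$val_rmse, col = "firebrick")
  abline(v = x$best_epoch, lty = 3)
  legend("topright", legend = c("train", "validation"),
         col = c("grey40", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Simulate responses from a fitted model
#'
#' Draws scaled responses as the fitted mean plus Gaussian noise with the
#' training residual standard deviation, truncated to (0,1).
#'
#' @param object A fitted `gpdrp` model.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns, one row per labeled pair.
#' @export
simulate.gpdrp <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted$fitted_scaled
  out <- as.data.frame(replicate(nsim, {
    pmin(pmax(mu + rnorm(length(mu), sd = object$sigma_scaled), 1e-6),
         1 - 1e-6)
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
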