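# Response transform: LN IC50 <-> (0,1).
#
# The raw response x is the natural-log IC50. With y = exp(x), the model
# target is yhat = 1 / (1 + y^(-0.1)) = 1 / (1 + exp(-0.1 x)) — a gentle
# sigmoid that spreads the response evenly over (0,1) and keeps the
# regression target bounded.

#' Scale LN IC50 to the (0,1) training range
#'
#' Applies `1 / (1 + exp(-0.1 x))`, the sigmoid (in base e) of a tenth of
#' the log response. Strictly increasing; `scale_response(0) == 0.5` and
#' `scale_response(-x) == 1 - scale_response(x)`.
#'
#' @param x Numeric vector of LN IC50 values (finite).
#' @return Values in (0,1).
#' @seealso [unscale_response()] for the inverse.
#' @export
#' @examples
#' scale_response(0)    # 0.5
#' scale_response(10)   # 1/(1+exp(-1)) = 0.7310586
scale_response <- function(x) {
  if (!is.numeric(x)) stop("x must be numeric")
  if (any(!is.finite(x))) stop("x must be finite")
  1 / (1 + exp(-0.1 * x))
}

#' Invert the response scaling
#'
#' Closed-form inverse of [scale_response()]: `10 * log(y / (1 - y))`.
#'
#' @param yhat Numeric vector strictly inside (0,1).
#' @return LN IC50 values; `unscale_response(scale_response(x)) == x` to
#'   numerical precision.
#' @export
#' @examples
#' unscale_response(0.5)  # 0
unscale_response <- function(yhat) {
  if (!is.numeric(yhat)) stop("yhat must be numeric")
  if (any(!is.finite(yhat)) || any(yhat <= 0) || any(yhat >= 1)) {
    stop("yhat must lie strictly inside (0,1)")
  }
  10 * log(yhat / (1 - yhat))
}

#' Z-score a matrix along rows, columns, or overall
#'
#' Centers each slice to mean 0 and scales to standard deviation 1. The
#' population standard deviation (divisor n) is the default, matching
#' Z-scoring of prediction matrices ahead of Euclidean clustering;
#' `sample_sd = TRUE` switches to the n-1 divisor.
#'
#' @param x Numeric matrix.
#' @param axis `"rows"`, `"columns"`, or `"all"`.
#' @param sample_sd Use the sample (n-1) standard deviation instead of the
#'   population one.
#' @return Matrix of the same shape, each slice with mean 0 and sd 1.
#'   Constant slices are an error naming the offending slice.
#' @export
zscore <- function(x, axis = c("rows", "columns", "all"), sample_sd = FALSE) {
  axis <- match.arg(axis)
  x <- as.matrix(x)
  pop_sd <- function(v) {
    m <- mean(v)
    s2 <- mean((v - m)^2)
    if (sample_sd) s2 <- s2 * length(v) / (length(v) - 1)
    sqrt(s2)
  }
  scale_slice <- function(v, label) {
    s <- pop_sd(v)
    if (s == 0) stop("constant slice: ", label)
    (v - mean(v)) / s
  }
  if (axis == "all") {
    out <- matrix(scale_slice(as.vector(x), "whole matrix"),
                  nrow(x), ncol(x), dimnames = dimnames(x))
  } else if (axis == "rows") {
    out <- x
    for (k in seq_len(nrow(x))) {
      out[k, ] <- scale_slice(x[k, ], paste0("row ", rownames(x)[k] %||% k))
    }
  } else {
    out <- x
    for (k in seq_len(ncol(x))) {
      out[, k] <- scale_slice(x[, k], paste0("column ", colnames(x)[k] %||% k))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a response table
#'
#' CSV/TSV with header columns `drug_id`, `cell_line_id`, `ln_ic50`; blank
#' `ln_ic50` entries denote pairs without a measured response. Duplicate
#' (drug, cell line) pairs are an error.
#'
#' @param path File path.
#' @return Data frame with the three columns; `ln_ic50` is numeric with NA
#'   for missing responses.
#' @export
read_response_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  d <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                  na.strings = c("", "NA"))
  need <- c("drug_id", "cell_line_id", "ln_ic50")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("response table missing column(s): ",
                         paste(miss, collapse = ", "))
  d$drug_id <- as.character(d$drug_id)
  d$cell_line_id <- as.character(d$cell_line_id)
  d$ln_ic50 <- as.numeric(d$ln_ic50)
  key <- paste(d$drug_id, d$cell_line_id, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (drug, cell line) pair(s) in ", path)
  d[, need]
}
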