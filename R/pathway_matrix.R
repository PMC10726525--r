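# Pathway-score matrices: pathways x cell lines, real-valued (GSVA-like
# enrichment scores), consumed as the cell-line feature modality.

#' Construct a pathway score matrix
#'
#' Wraps a numeric matrix (pathways in rows, cell lines in columns) with id
#' bookkeeping and a normalization flag. Values must be complete (no NA).
#'
#' @param values Numeric matrix, `n_pathways x n_cell_lines`.
#' @param pathway_ids,cell_line_ids Optional axis names; defaults taken from
#'   `dimnames(values)`.
#' @param normalized Logical: have rows already been min-max scaled?
#' @return An object of class `pathway_matrix`.
#' @export
pathway_matrix <- function(values, pathway_ids = rownames(values),
                           cell_line_ids = colnames(values),
                           normalized = FALSE) {
  values <- as.matrix(values)
  if (is.null(pathway_ids)) pathway_ids <- paste0("PW", seq_len(nrow(values)))
  if (is.null(cell_line_ids)) cell_line_ids <- paste0("CL", seq_len(ncol(values)))
  if (length(pathway_ids) != nrow(values) ||
      length(cell_line_ids) != ncol(values)) {
    stop("axis id lengths do not match matrix dimensions")
  }
  if (anyDuplicated(pathway_ids)) stop("duplicate pathway ids")
  if (anyDuplicated(cell_line_ids)) stop("duplicate cell line ids")
  if (anyNA(values)) stop("pathway score matrix contains missing values")
  dimnames(values) <- list(pathway_ids, cell_line_ids)
  structure(list(values = values, pathway_ids = as.character(pathway_ids),
                 cell_line_ids = as.character(cell_line_ids),
                 normalized = isTRUE(normalized)),
            class = "pathway_matrix")
}

#' @method print pathway_matrix
#' @export
print.pathway_matrix <- function(x, ...) {
  cat("Pathway score matrix: ", length(x$pathway_ids), " pathways x ",
      length(x$cell_line_ids), " cell lines",
      if (x$normalized) " (min-max normalized)" else "", "\n", sep = "")
  invisible(x)
}

#' Min-max normalize a pathway score matrix
#'
#' Scales each pathway (row) to `[0, 1]` across cell lines:
#' `x_hat = (x - min(x)) / (max(x) - min(x))`, with the row minimum and
#' maximum taken over the columns named in `stat_cells` (all columns by
#' default). Restricting `stat_cells` to the training cell lines gives a
#' leakage-free variant: statistics estimated on training columns are
#' applied to every column and the output clipped to `[0, 1]`. Constant
#' rows, for which the transform is undefined, become all zeros with a
#' warning, keeping the feature inert.
#'
#' @param x A `pathway_matrix` with `normalized = FALSE`.
#' @param stat_cells Optional character vector of cell line ids on which to
#'   compute the row statistics (default: all cell lines, the global
#'   normalization described for this model family).
#' @return Normalized `pathway_matrix`; the row statistics used are stored
#'   in attribute `stats`.
#' @export
#' @examples
#' m <- pathway_matrix(matrix(c(2, 4, 6), 1, 3))
#' minmax_normalize(m)$values  # 0, 0.5, 1
minmax_normalize <- function(x, stat_cells = NULL) {
  stopifnot(inherits(x, "pathway_matrix"))
  if (x$normalized) stop("matrix is already normalized")
  if (ncol(x$values) < 1L) stop("need at least one cell line")
  v <- x$values
  cols <- if (is.null(stat_cells)) seq_len(ncol(v)) else {
    idx <- match(stat_cells, x$cell_line_ids)
    if (anyNA(idx)) stop("unknown cell line id(s) in stat_cells")
    idx
  }
  lo <- apply(v[, cols, drop = FALSE], 1L, min)
  hi <- apply(v[, cols, drop = FALSE], 1L, max)
  rng <- hi - lo
  const <- rng == 0
  if (any(const)) {
    warning(sum(const), " constant pathway row(s) mapped to all zeros")
    rng[const] <- 1
  }
  out <- (v - lo) / rng
  out[const, ] <- 0
  out <- pmin(pmax(out, 0), 1)
  res <- pathway_matrix(out, x$pathway_ids, x$cell_line_ids, normalized = TRUE)
  attr(res, "stats") <- data.frame(pathway_id = x$pathway_ids, min = lo,
                                   max = hi, constant = const,
                                   row.names = NULL)
  res
}

#' Read / write pathway score matrices
#'
#' CSV/TSV with the pathway id in the first column and cell line ids in the
#' header. `read_score_matrix()` errors on ragged rows, duplicated pathway
#' ids and missing cells; `write_score_matrix()` writes full precision so a
#' round trip reproduces the values exactly as printed.
#'
#' @param path File path.
#' @param normalized Passed through to the constructed matrix.
#' @return `read_score_matrix()` a `pathway_matrix`; `write_score_matrix()`
#'   the path, invisibly.
#' @export
read_score_matrix <- function(path, normalized = FALSE) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  lines <- readLines(path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop("ragged score matrix: line ", bad, " has ", widths[bad],
         " fields, expected ", widths[1])
  }
  header <- fields[[1]]
  cells <- header[-1]
  body <- fields[-1]
  pw <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(pw)) {
    stop("duplicated pathway id(s): ", paste(unique(pw[duplicated(pw)]), collapse = ", "))
  }
  vals <- matrix(NA_real_, length(body), length(cells))
  for (k in seq_along(body)) {
    row <- suppressWarnings(as.numeric(body[[k]][-1]))
    if (anyNA(row)) {
      stop("missing or non-numeric entry at row '", pw[k], "', column '",
           cells[which(is.na(row))[1]], "'")
    }
    vals[k, ] <- row
  }
  pathway_matrix(vals, pw, cells, normalized = normalized)
}

#' @rdname read_score_matrix
#' @param x A `pathway_matrix`.
#' @export
write_score_matrix <- function(x, path) {
  stopifnot(inherits(x, "pathway_matrix"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("pathway_id", x$cell_line_ids), collapse = sep), con)
  for (k in seq_len(nrow(x$values))) {
    writeLines(paste(c(x$pathway_ids[k],
                       format(x$values[k, ], digits = 17, trim = TRUE,
                              scientific = FALSE)),
                     collapse = sep), con)
  }
  invisible(path)
}
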