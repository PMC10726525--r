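# Gene-set collections in the MSigDB GMT dialect.

#' Read a GMT gene-set file
#'
#' One set per line: tab-separated set name, description, then member gene
#' symbols. Duplicate genes within a set are dropped with a warning; a line
#' with fewer than three fields is a format error naming the line number.
#'
#' @param path GMT file path.
#' @return An object of class `gene_set_collection`: a named list of
#'   character vectors with attribute `source` (the file path).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3L) {
      stop("GMT format error at line ", k, ": expected name, description, ",
           "and at least one gene")
    }
    nm[k] <- f[1]
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", f[1], "' (line ", k, "); de-duplicated")
      genes <- unique(genes)
    }
    sets[[k]] <- genes
  }
  if (anyDuplicated(nm)) {
    stop("duplicate set names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  names(sets) <- nm
  structure(sets, source = path, class = "gene_set_collection")
}

#' @method print gene_set_collection
#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection:", length(x), "sets")
  if (length(x)) {
    cat(" (sizes ", min(lengths(x)), "-", max(lengths(x)), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Filter gene sets against a gene universe
#'
#' Intersects every set with the measured gene universe and keeps sets with
#' at least `min_size` surviving members — the conventional minimum-size
#' filter applied before pathway scoring (default 5). Genes outside the
#' universe are removed from the surviving sets. The result does not depend
#' on the order of sets or of genes within a set.
#'
#' @param collection A `gene_set_collection` (or plain named list).
#' @param universe Character vector of measured gene symbols.
#' @param min_size Minimum post-intersection set size (default 5).
#' @return Filtered `gene_set_collection`.
#' @export
filter_gene_sets <- function(collection, universe, min_size = 5L) {
  if (length(universe) == 0L) stop("gene universe must be non-empty")
  if (min_size < 1L) stop("min_size must be >= 1")
  universe <- unique(as.character(universe))
  kept <- lapply(collection, function(g) g[g %in% universe])
  keep <- lengths(kept) >= min_size
  structure(kept[keep],
            source = attr(collection, "source"),
            class = "gene_set_collection")
}
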