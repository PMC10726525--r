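#' Default atom symbol vocabulary
#'
#' The 44-entry element vocabulary used by the default featurizer: the
#' 43-element list popularized by DeepChem-style molecular featurizers plus
#' a terminal `"other"` bucket that absorbs any symbol outside the list.
#'
#' @return Character vector of length 44 ending in `"other"`.
#' @export
#' @examples
#' length(default_symbol_vocabulary())
default_symbol_vocabulary <- function() {
  c("C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg",
    "Na", "Ca", "Fe", "As", "Al", "I", "B", "V", "K", "Tl",
    "Yb", "Sb", "Sn", "Ag", "Pd", "Co", "Se", "Ti", "Zn", "H",
    "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn", "Zr", "Cr",
    "Pt", "Hg", "Pb", "other")
}

#' Build an atom featurization schema
#'
#' Defines the five-block binary atom feature layout used throughout the
#' package: a one-hot element-symbol block, one-hot blocks for heavy-atom
#' degree, number of attached hydrogens and implicit valence (each with
#' values above the cap clamped to the cap position), and a single aromatic
#' flag. The total feature dimension is
#' `|vocabulary| + (max_degree+1) + (max_num_hs+1) + (max_implicit_valence+1) + 1`.
#'
#' The default schema (44 symbols, caps of 10) has dimension 78 and is fixed
#' so that featurization is reproducible bit-for-bit across sessions.
#'
#' @param symbols Ordered element vocabulary. A terminal `"other"` bucket is
#'   appended when absent. Duplicates are an error.
#' @param max_degree,max_num_hs,max_implicit_valence Non-negative caps for
#'   the three count blocks; counts above a cap map to the cap position.
#' @return An object of class `atom_schema`.
#' @export
#' @examples
#' sch <- build_atom_schema()
#' sch$total_dim  # 78
build_atom_schema <- function(symbols = default_symbol_vocabulary(),
                              max_degree = 10L,
                              max_num_hs = 10L,
                              max_implicit_valence = 10L) {
  if (length(symbols) == 0L) stop("symbol vocabulary must be non-empty")
  if (anyDuplicated(symbols)) {
    stop("duplicate symbols in vocabulary: ",
         paste(unique(symbols[duplicated(symbols)]), collapse = ", "))
  }
  if (max_degree < 0L || max_num_hs < 0L || max_implicit_valence < 0L) {
    stop("feature caps must be >= 0")
  }
  if (symbols[length(symbols)] != "other") {
    if ("other" %in% symbols) stop("'other' must be the terminal vocabulary entry")
    symbols <- c(symbols, "other")
  }
  schema <- list(
    symbols = symbols,
    max_degree = as.integer(max_degree),
    max_num_hs = as.integer(max_num_hs),
    max_implicit_valence = as.integer(max_implicit_valence),
    total_dim = length(symbols) + (as.integer(max_degree) + 1L) +
      (as.integer(max_num_hs) + 1L) + (as.integer(max_implicit_valence) + 1L) + 1L
  )
  class(schema) <- "atom_schema"
  schema
}

#' @method print atom_schema
#' @export
print.atom_schema <- function(x, ...) {
  cat("Atom featurization schema:", length(x$symbols), "symbols;",
      "caps (degree, numHs, implicit valence) =",
      paste(c(x$max_degree, x$max_num_hs, x$max_implicit_valence), collapse = ", "),
      "; total dim", x$total_dim, "\n")
  invisible(x)
}

one_hot_clamped <- function(value, cap) {
  v <- numeric(cap + 1L)
  v[min(value, cap) + 1L] <- 1
  v
}

#' Featurize one atom
#'
#' Encodes a single atom as the binary vector defined by an
#' [build_atom_schema()] layout: one-hot element symbol (unknown symbols map
#' to `"other"`), one-hot heavy-atom degree, attached-hydrogen count and
#' implicit valence (clamped at the schema caps), and a trailing aromatic
#' flag. Clamping and bucketing make the encoding total: no atom fails.
#'
#' @param symbol Element symbol, e.g. `"C"`.
#' @param degree Number of neighboring heavy atoms (>= 0).
#' @param num_hs Number of attached hydrogens, implicit plus explicit (>= 0).
#' @param implicit_valence Implicit valence of the atom (>= 0).
#' @param aromatic Logical aromaticity flag.
#' @param schema An `atom_schema`.
#' @return Binary numeric vector of length `schema$total_dim` with exactly
#'   one 1 in each of the four categorical blocks.
#' @export
#' @examples
#' sch <- build_atom_schema()
#' sum(featurize_atom("C", 0, 4, 4, FALSE, sch))  # 4
featurize_atom <- function(symbol, degree, num_hs, implicit_valence,
                           aromatic, schema) {
  stopifnot(inherits(schema, "atom_schema"))
  if (degree < 0 || num_hs < 0 || implicit_valence < 0) {
    stop("atom counts must be >= 0")
  }
  sym <- numeric(length(schema$symbols))
  idx <- match(symbol, schema$symbols)
  if (is.na(idx)) idx <- length(schema$symbols)  # "other" bucket
  sym[idx] <- 1
  c(sym,
    one_hot_clamped(as.integer(degree), schema$max_degree),
    one_hot_clamped(as.integer(num_hs), schema$max_num_hs),
    one_hot_clamped(as.integer(implicit_valence), schema$max_implicit_valence),
    as.numeric(isTRUE(as.logical(aromatic))))
}
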