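# SMILES -> attributed molecular graph.
#
# Open Babel (via ChemmineOB) parses the SMILES and kekulizes; ChemmineR
# supplies ring perception and ring aromaticity. The V2000 atom/bond block
# is read directly here because ChemmineR's SDF container rejects
# single-atom molecules and hides formal-charge codes.

# Minimal default-valence model (matches the usual cheminformatics tables)
# used to derive implicit hydrogen counts from the kekulized structure.
.default_valences <- list(
  H = 1, Li = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Na = 1, Mg = 2,
  Al = 3, Si = 4, P = c(3, 5), S = c(2, 4, 6), Cl = 1, K = 1, Ca = 2,
  Zn = 2, As = c(3, 5), Se = c(2, 4, 6), Br = 1, I = 1
)

.old_charge_codes <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0,
                       `5` = -1, `6` = -2, `7` = -3)

# Parse the V2000 connection table of a single-molecule SDF string into
# atoms (symbol, charge) and bonds (i, j, order).
parse_v2000 <- function(sdf_text) {
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  counts_at <- grep("V2000", lines, fixed = TRUE)
  if (length(counts_at) == 0L) return(NULL)
  counts_at <- counts_at[1]
  counts <- lines[counts_at]
  n_atoms <- as.integer(substr(counts, 1L, 3L))
  n_bonds <- as.integer(substr(counts, 4L, 6L))
  if (is.na(n_atoms) || n_atoms < 1L) return(NULL)
  atom_lines <- lines[counts_at + seq_len(n_atoms)]
  symbol <- trimws(substr(atom_lines, 32L, 34L))
  charge_code <- suppressWarnings(as.integer(substr(atom_lines, 37L, 39L)))
  charge_code[is.na(charge_code)] <- 0L
  charge <- unname(.old_charge_codes[as.character(charge_code)])
  charge[is.na(charge)] <- 0
  if (n_bonds > 0L) {
    bond_lines <- lines[counts_at + n_atoms + seq_len(n_bonds)]
    bonds <- data.frame(
      i = as.integer(substr(bond_lines, 1L, 3L)),
      j = as.integer(substr(bond_lines, 4L, 6L)),
      order = as.integer(substr(bond_lines, 7L, 9L))
    )
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  }
  # M CHG properties supersede the atom-block charge codes
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    charge[] <- 0
    for (ln in chg_lines) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      n <- f[1]
      for (k in seq_len(n)) charge[f[2 * k]] <- f[2 * k + 1]
    }
  }
  list(symbol = symbol, charge = charge, bonds = bonds)
}

# Per-atom implicit hydrogen count under the default-valence model.
implicit_h_count <- function(symbol, charge, explicit_valence) {
  allowed <- .default_valences[[symbol]]
  if (is.null(allowed)) return(0L)
  if (charge != 0) {
    allowed <- if (symbol == "C") 4 - abs(charge) else allowed + charge
    allowed <- allowed[allowed >= 0]
    if (!length(allowed)) return(0L)
  }
  ok <- allowed[allowed >= explicit_valence]
  if (!length(ok)) return(0L)
  as.integer(min(ok) - explicit_valence)
}

# Indices (into the SDF atom order) of atoms in at least one aromatic ring.
perceive_aromatic_atoms <- function(sdf_text, n_bonds) {
  if (n_bonds < 3L) return(integer())
  out <- tryCatch({
    sdfset <- suppressWarnings(
      ChemmineR::read.SDFset(strsplit(sdf_text, "\n", fixed = TRUE)[[1]])
    )
    r <- ChemmineR::rings(sdfset[[1]], type = "all", arom = TRUE)
    atoms <- unique(unlist(r$RINGS[r$AROMATIC], use.names = FALSE))
    as.integer(sub(".*_", "", atoms))
  }, error = function(e) integer())
  out
}

#' Convert a SMILES string to an attributed molecular graph
#'
#' Parses a SMILES string into the heavy-atom graph used by the drug
#' encoders: one node per non-hydrogen atom, one undirected, featureless
#' edge per bond, and per-node binary feature vectors from
#' [featurize_atom()] (element symbol, heavy-atom degree, attached
#' hydrogens, implicit valence, aromaticity). Hydrogens are implicit: they
#' contribute to the hydrogen-count feature but are not nodes. For
#' multi-fragment input (salts, `"."`-separated components) the largest
#' fragment is kept with a warning. The result is deterministic for a fixed
#' SMILES and schema.
#'
#' @param smiles A single SMILES string.
#' @param schema An [build_atom_schema()] object; the default 78-dimensional
#'   schema when omitted.
#' @return An object of class `molecular_graph` with elements
#'   `node_features` (n_atoms x total_dim binary matrix), `edges` (two-column
#'   integer matrix, each row an unordered bond with `i < j`), `n_atoms`,
#'   `smiles`, and `atoms` (per-atom attribute data frame).
#' @export
#' @examples
#' g <- smiles_to_graph("c1ccccc1")
#' g$n_atoms        # 6
#' nrow(g$edges)    # 6
smiles_to_graph <- function(smiles, schema = build_atom_schema()) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.na(smiles) || !nzchar(trimws(smiles))) {
    stop("cannot parse empty SMILES")
  }
  sdf_text <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, " mol")),
    error = function(e) ""
  )
  ct <- parse_v2000(sdf_text)
  if (is.null(ct)) stop("cannot parse SMILES: '", smiles, "'")

  aromatic_idx <- perceive_aromatic_atoms(sdf_text, nrow(ct$bonds))
  n_all <- length(ct$symbol)
  heavy <- which(ct$symbol != "H")
  if (!length(heavy)) stop("molecule has no heavy atoms: '", smiles, "'")

  b <- ct$bonds
  heavy_bond <- b$i %in% heavy & b$j %in% heavy
  # explicit hydrogens: count them onto their heavy neighbor
  explicit_h <- integer(n_all)
  h_bond <- !heavy_bond & nrow(b) > 0
  if (any(h_bond)) {
    for (r in which(h_bond)) {
      hi <- b$i[r]; hj <- b$j[r]
      if (ct$symbol[hi] == "H" && ct$symbol[hj] != "H") {
        explicit_h[hj] <- explicit_h[hj] + 1L
      } else if (ct$symbol[hj] == "H" && ct$symbol[hi] != "H") {
        explicit_h[hi] <- explicit_h[hi] + 1L
      }
    }
  }

  # largest connected fragment of the heavy-atom graph
  bb <- b[heavy_bond, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = if (nrow(bb)) data.frame(from = bb$i, to = bb$j) else
      data.frame(from = integer(), to = integer()),
    directed = FALSE,
    vertices = data.frame(name = heavy)
  )
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    warning("multi-fragment SMILES '", smiles, "': keeping largest fragment")
    keep_comp <- which.max(comp$csize)
    keep <- heavy[comp$membership == keep_comp]
  } else {
    keep <- heavy
  }
  keep <- sort(keep)
  remap <- integer(n_all)
  remap[keep] <- seq_along(keep)

  bk <- bb[bb$i %in% keep & bb$j %in% keep, , drop = FALSE]
  edges <- cbind(remap[bk$i], remap[bk$j])
  if (nrow(edges)) {
    edges <- t(apply(edges, 1L, sort))
    edges <- unique(edges)
    storage.mode(edges) <- "integer"
  } else {
    edges <- matrix(integer(), ncol = 2L)
  }
  colnames(edges) <- c("i", "j")

  n <- length(keep)
  deg <- integer(n)
  if (nrow(edges)) {
    tab <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = n)
    deg <- tab
  }
  sym <- ct$symbol[keep]
  chg <- ct$charge[keep]
  arom <- keep %in% aromatic_idx

  # explicit valence = kekulized bond-order sum + explicit hydrogens
  expl_val <- numeric(n)
  if (nrow(bk)) {
    ends <- c(remap[bk$i], remap[bk$j])
    ords <- c(bk$order, bk$order)
    expl_val <- as.numeric(tapply(ords, factor(ends, levels = seq_len(n)), sum))
    expl_val[is.na(expl_val)] <- 0
  }
  expl_val <- expl_val + explicit_h[keep]

  impl_h <- mapply(implicit_h_count, sym, chg, expl_val)
  num_hs <- impl_h + explicit_h[keep]

  atoms <- data.frame(
    symbol = sym,
    degree = deg,
    num_hs = as.integer(num_hs),
    implicit_valence = as.integer(impl_h),
    aromatic = arom,
    formal_charge = chg,
    stringsAsFactors = FALSE
  )

  node_features <- t(vapply(
    seq_len(n),
    function(a) featurize_atom(atoms$symbol[a], atoms$degree[a],
                               atoms$num_hs[a], atoms$implicit_valence[a],
                               atoms$aromatic[a], schema),
    numeric(schema$total_dim)
  ))

  structure(
    list(node_features = node_features, edges = edges, n_atoms = n,
         smiles = smiles, atoms = atoms, feature_dim = schema$total_dim),
    class = "molecular_graph"
  )
}

#' @method print molecular_graph
#' @export
print.molecular_graph <- function(x, ...) {
  cat("Molecular graph of '", x$smiles, "': ", x$n_atoms, " heavy atoms, ",
      nrow(x$edges), " bonds, ", sum(x$atoms$aromatic), " aromatic atoms\n",
      sep = "")
  invisible(x)
}

# Dense adjacency matrix of a molecular graph (used by the reference layer
# implementations and the positional encoding).
mol_adjacency <- function(graph) {
  n <- graph$n_atoms
  A <- matrix(0, n, n)
  if (nrow(graph$edges)) {
    A[graph$edges] <- 1
    A[graph$edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  A
}

#' Read a drug table (id + SMILES)
#'
#' Reads a CSV or TSV file with header columns `drug_id` and `smiles`.
#' The separator is inferred from the header line. Row order is preserved.
#'
#' @param path File path.
#' @return Data frame with columns `drug_id` (character, unique) and
#'   `smiles`.
#' @export
read_drug_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  d <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                  quote = "\"", comment.char = "")
  need <- c("drug_id", "smiles")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("drug table missing column(s): ", paste(miss, collapse = ", "))
  d$drug_id <- as.character(d$drug_id)
  if (anyDuplicated(d$drug_id)) {
    stop("duplicate drug_id in ", path, ": ",
         paste(unique(d$drug_id[duplicated(d$drug_id)]), collapse = ", "))
  }
  d[, need]
}

#' Dump molecular graphs as JSON
#'
#' Writes one JSON object per molecule (`smiles`, `n_atoms`, `edges`,
#' `feature_dim`) for debugging and external inspection.
#'
#' @param graphs List of `molecular_graph` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graphs, path) {
  objs <- lapply(graphs, function(g) {
    list(smiles = g$smiles, n_atoms = g$n_atoms,
         edges = if (nrow(g$edges)) unname(apply(g$edges, 1L, as.list)) else list(),
         feature_dim = g$feature_dim)
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE)
  invisible(path)
}
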