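# Synthetic benchmark generator: drug panels (scaffold decoration),
# GSVA-like low-rank pathway-score matrices, planted-signal responses, and
# xenograft-style clustered fixtures. Everything is reproducible from
# (spec, seed).

.scaffolds <- list(
  c("c1ccc(", ")cc1"),          # benzene
  c("c1ccnc(", ")c1"),          # pyridine
  c("C1CCC(", ")CC1"),          # cyclohexane
  c("C1CCN(", ")CC1"),          # piperidine (N-substituted)
  c("c1ccc(", ")o1"),           # furan
  c("c1ccc(", ")s1"),           # thiophene
  c("c1ccn(", ")c1"),           # pyrrole (N-substituted)
  c("c1ccc2cc(", ")ccc2c1"),    # naphthalene
  c("O=C(", ")Nc1ccccc1"),      # anilide
  c("N#Cc1ccc(", ")cc1"),       # benzonitrile
  c("COc1ccc(", ")cc1")         # anisole
)

.substituents <- c("C", "CC", "CCC", "C(C)C", "CCO", "CO", "OC", "OCC",
                   "N", "NC(C)=O", "F", "Cl", "Br", "C#N", "C(=O)O",
                   "C(=O)OC", "C(F)(F)F", "S(N)(=O)=O")

#' Synthetic study specification
#'
#' Bundles the sizes, signal and noise settings of a synthetic drug-response
#' study. The defaults define the package's reference benchmark: 60 drugs,
#' 80 cell lines, 200 pathway features with rank-10 latent structure,
#' planted signal coefficients (1, 1, 0.5) for the drug, cell and
#' interaction terms, Gaussian noise of sd 0.5 on the LN IC50 scale, and
#' 10\% of pairs masked as unlabeled.
#'
#' @param n_drugs,n_cell_lines,n_pathways Panel sizes (>= 1).
#' @param latent_rank Rank of the pathway-matrix latent structure.
#' @param noise_sd Response noise standard deviation (LN scale, >= 0).
#' @param signal_coefficients Numeric triple `(a, b, c)` weighting the drug
#'   descriptor, cell-line pathway signal, and their interaction.
#' @param missing_fraction Fraction of pairs masked as unlabeled, in
#'   `[0, 1)`.
#' @param seed Integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_drugs = 60L, n_cell_lines = 80L,
                           n_pathways = 200L, latent_rank = 10L,
                           noise_sd = 0.5, signal_coefficients = c(1, 1, 0.5),
                           missing_fraction = 0.1, seed = 1L) {
  stopifnot(n_drugs >= 1L, n_cell_lines >= 1L, n_pathways >= 1L,
            latent_rank >= 0L, noise_sd >= 0,
            length(signal_coefficients) == 3L,
            missing_fraction >= 0, missing_fraction < 1)
  structure(list(n_drugs = as.integer(n_drugs),
                 n_cell_lines = as.integer(n_cell_lines),
                 n_pathways = as.integer(n_pathways),
                 latent_rank = as.integer(latent_rank),
                 noise_sd = noise_sd,
                 signal_coefficients = signal_coefficients,
                 missing_fraction = missing_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a drug panel of valid SMILES
#'
#' Decorates a built-in library of drug-like ring scaffolds (benzene,
#' pyridine, piperidine, naphthalene, anilide, ...) with substituent
#' fragments (alkyl, hydroxyl, halogen, nitrile, ester, trifluoromethyl,
#' sulfonamide, ...), guaranteeing chemical validity without a rejection
#' loop. Every generated molecule is verified to featurize through
#' [smiles_to_graph()]. Deterministic per seed.
#'
#' @param n Number of drugs (at most the scaffold x substituent capacity).
#' @param seed Integer seed.
#' @return Data frame with columns `drug_id`, `smiles`.
#' @export
generate_drug_panel <- function(n, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  capacity <- length(.scaffolds) * length(.substituents)
  if (n > capacity) {
    stop("n exceeds the distinct combinatorial capacity of ", capacity,
         " scaffold/substituent combinations")
  }
  grid <- expand.grid(s = seq_along(.scaffolds),
                      r = seq_along(.substituents))
  smiles <- vapply(seq_len(nrow(grid)), function(k) {
    sc <- .scaffolds[[grid$s[k]]]
    paste0(sc[1], .substituents[grid$r[k]], sc[2])
  }, character(1))
  set.seed(seed)
  pick <- sample(seq_along(smiles), n)
  out <- data.frame(drug_id = sprintf("DRUG%03d", seq_len(n)),
                    smiles = smiles[pick], stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    ok <- tryCatch({smiles_to_graph(out$smiles[k]); TRUE},
                   error = function(e) FALSE)
    if (!ok) stop("generated SMILES failed featurization: ", out$smiles[k])
  }
  out
}

#' Generate a GSVA-like pathway score matrix
#'
#' Low-rank latent structure (rank-`latent_rank` factor product, rescaled
#' to lie inside the unit interval in magnitude) plus Gaussian noise,
#' clipped to `[-1, 1]` to mimic the bounded range of sample-wise
#' enrichment scores. Deterministic per seed.
#'
#' @param n_pathways,n_cell_lines Matrix dimensions.
#' @param latent_rank Rank of the noiseless structure
#'   (`<= min(n_pathways, n_cell_lines)`; 0 gives an all-zero matrix).
#' @param noise_sd Entrywise Gaussian noise sd (default 0.1).
#' @param seed Integer seed.
#' @return Unnormalized [pathway_matrix()].
#' @export
generate_pathway_matrix <- function(n_pathways, n_cell_lines, latent_rank,
                                    noise_sd = 0.1, seed = 1L) {
  if (latent_rank < 0L || latent_rank > min(n_pathways, n_cell_lines)) {
    stop("latent_rank must lie in [0, min(n_pathways, n_cell_lines)]")
  }
  set.seed(seed)
  M <- matrix(0, n_pathways, n_cell_lines)
  if (latent_rank > 0L) {
    U <- matrix(rnorm(n_pathways * latent_rank), n_pathways)
    V <- matrix(rnorm(latent_rank * n_cell_lines), latent_rank)
    R <- U %*% V
    M <- 0.9 * R / max(abs(R))
  }
  if (noise_sd > 0) {
    M <- M + matrix(rnorm(length(M), sd = noise_sd), nrow(M))
    M <- pmin(pmax(M, -1), 1)
  }
  pathway_matrix(M, sprintf("PW%04d", seq_len(n_pathways)),
                 sprintf("CL%03d", seq_len(n_cell_lines)))
}

standardize0 <- function(v) {
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) return(v * 0)
  (v - mean(v)) / s
}

#' Generate planted-signal responses for a drug panel and cell-line panel
#'
#' LN IC50 for pair (d, c) is `a * delta(d) + b * pi(c) +
#' c * delta(d) * pi(c) + eps`, where `delta(d)` is a standardized graph
#' descriptor of the drug (aromatic-atom fraction plus scaled heavy-atom
#' count, both computable from the molecular graph the model sees),
#' `pi(c)` is a standardized weighted sum of a sparse subset of pathway
#' rows, and `eps ~ N(0, noise_sd^2)`. A `missing_fraction` of the pairs is
#' masked as unlabeled. The planted ground truth (descriptors, weights,
#' mask) is returned for recovery tests.
#'
#' @param drug_panel Data frame (`drug_id`, `smiles`).
#' @param pathway_mat A [pathway_matrix()] (raw scores).
#' @param spec A [synthetic_spec()]; its coefficients, noise, missing
#'   fraction and seed drive the generation.
#' @param n_signal_pathways Size of the sparse pathway subset carrying the
#'   cell-line signal (default 10).
#' @return List with `responses` (data frame `drug_id`, `cell_line_id`,
#'   `ln_ic50`, NA where masked) and `truth` (list: `delta`, `pi`,
#'   `coefficients`, `signal_pathways`, `weights`, `masked`).
#' @export
generate_responses <- function(drug_panel, pathway_mat, spec,
                               n_signal_pathways = 10L) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(pathway_mat, "pathway_matrix"))
  if (!nrow(drug_panel)) stop("empty drug panel")
  set.seed(spec$seed)
  graphs <- lapply(drug_panel$smiles, smiles_to_graph)
  delta_raw <- vapply(graphs, function(g) {
    mean(g$atoms$aromatic) + g$n_atoms / 20
  }, numeric(1))
  delta <- standardize0(delta_raw)
  names(delta) <- drug_panel$drug_id

  n_pw <- length(pathway_mat$pathway_ids)
  n_sig <- min(n_signal_pathways, n_pw)
  sig <- sort(sample(n_pw, n_sig))
  w <- rnorm(n_sig)
  pi_raw <- drop(w %*% pathway_mat$values[sig, , drop = FALSE])
  pi_c <- standardize0(pi_raw)
  names(pi_c) <- pathway_mat$cell_line_ids

  a <- spec$signal_coefficients[1]
  b <- spec$signal_coefficients[2]
  cc <- spec$signal_coefficients[3]
  D <- nrow(drug_panel); C <- length(pi_c)
  dd <- rep(seq_len(D), each = C)
  cid <- rep(seq_len(C), D)
  mu <- a * delta[dd] + b * pi_c[cid] + cc * delta[dd] * pi_c[cid]
  ln <- mu + rnorm(length(mu), sd = spec$noise_sd)
  n_miss <- round(spec$missing_fraction * length(ln))
  masked <- if (n_miss > 0L) sort(sample(length(ln), n_miss)) else integer()
  ln[masked] <- NA_real_
  responses <- data.frame(
    drug_id = drug_panel$drug_id[dd],
    cell_line_id = pathway_mat$cell_line_ids[cid],
    ln_ic50 = unname(ln), stringsAsFactors = FALSE)
  list(responses = responses,
       truth = list(delta = delta, pi = pi_c,
                    coefficients = c(a = a, b = b, interaction = cc),
                    signal_pathways = pathway_mat$pathway_ids[sig],
                    weights = w, masked = masked))
}

#' Generate a full synthetic study
#'
#' Convenience wrapper: drug panel, pathway matrix and planted-signal
#' responses from one [synthetic_spec()].
#'
#' @param spec A [synthetic_spec()].
#' @return List with `drugs`, `pathways`, `responses`, `truth`.
#' @export
generate_synthetic_dataset <- function(spec = synthetic_spec()) {
  drugs <- generate_drug_panel(spec$n_drugs, seed = spec$seed)
  pathways <- generate_pathway_matrix(spec$n_pathways, spec$n_cell_lines,
                                      spec$latent_rank, seed = spec$seed)
  resp <- generate_responses(drugs, pathways, spec)
  list(drugs = drugs, pathways = pathways, responses = resp$responses,
       truth = resp$truth)
}

#' Held-out correlation of the planted linear oracle
#'
#' Closed-form least-squares fit of the response on the planted drug and
#' cell-line descriptors (`delta`, `pi`) over the training pairs, evaluated
#' as the Pearson correlation on a held-out partition. Serves as the
#' signal-recovery ceiling against which the trained network is compared.
#'
#' @param responses Response data frame from [generate_responses()].
#' @param truth The matching `truth` list.
#' @param split A [split_by_cellline()] assignment.
#' @param partition Held-out partition to score (default `"test"`).
#' @return Pearson correlation of oracle predictions with the held-out
#'   responses.
#' @export
oracle_linear_pcc <- function(responses, truth, split, partition = "test") {
  lab <- responses[!is.na(responses$ln_ic50), , drop = FALSE]
  part <- split$partition[match(lab$cell_line_id, split$cell_line_id)]
  d <- data.frame(y = lab$ln_ic50,
                  delta = truth$delta[lab$drug_id],
                  pi = truth$pi[lab$cell_line_id])
  fit <- stats::lm(y ~ delta + pi, data = d[part == "train", , drop = FALSE])
  pred <- predict(fit, newdata = d[part == partition, , drop = FALSE])
  pearson(d$y[part == partition], pred)
}

#' Generate a xenograft-style clustered fixture
#'
#' Emulates a xenograft study: samples in named condition/treatment groups,
#' a planted three-cluster structure, a predicted LN IC50 matrix whose
#' cluster means are separated by `cluster_sep` (cluster 1 most resistant),
#' and a pathway-score matrix in which a 12-pathway proliferation set is
#' shifted by cluster (`prolif_shift` between adjacent clusters, cluster 1
#' lowest). The default group sizes (9, 8, 10, 12, 15) total 54 samples.
#'
#' @param group_sizes Named integer vector of group sizes (all >= 1).
#' @param n_drugs Number of drugs in the prediction matrix.
#' @param n_pathways Number of pathway rows (>= 12).
#' @param cluster_sep Separation of cluster means in the prediction matrix.
#' @param prolif_shift Per-cluster shift of the proliferation pathway set.
#' @param noise_sd Noise sd for predictions and scores.
#' @param seed Integer seed.
#' @return List with `samples` (data frame `sample_id`, `group`,
#'   `cluster`), `predictions` (samples x drugs LN IC50 matrix), `scores`
#'   (a [pathway_matrix()], pathways x samples), and `prolif_pathways`.
#' @export
generate_xenograft_fixture <- function(group_sizes = c(`PRE-CX` = 9L,
                                                       `POST-CX` = 8L,
                                                       CRPC = 10L,
                                                       ENZS = 12L,
                                                       ENZR = 15L),
                                       n_drugs = 30L, n_pathways = 60L,
                                       cluster_sep = 3, prolif_shift = 2,
                                       noise_sd = 0.5, seed = 1L) {
  if (!length(group_sizes)) stop("group_sizes must be non-empty")
  if (any(group_sizes < 1L)) stop("all group sizes must be >= 1")
  if (n_pathways < 12L) stop("n_pathways must be >= 12")
  set.seed(seed)
  n <- sum(group_sizes)
  if (is.null(names(group_sizes))) {
    names(group_sizes) <- paste0("GROUP", seq_along(group_sizes))
  }
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    group = rep(names(group_sizes), group_sizes),
    cluster = sample(rep_len(1:3, n)),
    stringsAsFactors = FALSE)

  shift <- c(1, 0, -1) * cluster_sep          # cluster 1 most resistant
  pred <- matrix(rnorm(n * n_drugs, sd = noise_sd), n, n_drugs,
                 dimnames = list(samples$sample_id,
                                 sprintf("DRUG%03d", seq_len(n_drugs))))
  pred <- pred + shift[samples$cluster]

  prolif <- sprintf("PROLIF_%02d", 1:12)
  other <- sprintf("PW%04d", seq_len(n_pathways - 12L))
  sc <- matrix(rnorm(n_pathways * n, sd = 0.3), n_pathways, n)
  pshift <- c(-1, 0, 1) * prolif_shift        # cluster 1 lowest proliferation
  sc[1:12, ] <- sc[1:12, ] +
    matrix(pshift[samples$cluster], 12L, n, byrow = TRUE)
  scores <- pathway_matrix(sc, c(prolif, other), samples$sample_id)

  list(samples = samples, predictions = pred, scores = scores,
       prolif_pathways = prolif)
}
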