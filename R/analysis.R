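# Downstream analyses of prediction matrices: drug ranking by median
# predicted LN IC50, Euclidean hierarchical clustering of samples, and
# per-cluster pathway-score summaries.

#' Rank drugs by median predicted response
#'
#' Orders drugs by the median of their predicted LN IC50 over samples,
#' ascending (most effective first: low LN IC50 means high sensitivity);
#' ties are broken by drug id.
#'
#' @param pred Numeric matrix, samples x drugs (LN IC50 scale), with drug
#'   ids as column names.
#' @return Data frame with columns `drug_id`, `median_ln`, sorted
#'   ascending.
#' @seealso [rank_extremes()] for the head/tail selection.
#' @export
rank_drugs_by_median <- function(pred) {
  pred <- as.matrix(pred)
  if (nrow(pred) < 1L || ncol(pred) < 1L) stop("empty prediction matrix")
  ids <- colnames(pred) %||% paste0("drug", seq_len(ncol(pred)))
  med <- apply(pred, 2L, median)
  ord <- order(med, ids)
  data.frame(drug_id = ids[ord], median_ln = unname(med[ord]),
             stringsAsFactors = FALSE)
}

#' Most and least effective drugs from a ranking
#'
#' @param ranking Output of [rank_drugs_by_median()].
#' @param n How many drugs at each extreme (default 6).
#' @return List with `lowest` (smallest medians: most effective) and
#'   `highest` data frames.
#' @export
rank_extremes <- function(ranking, n = 6L) {
  list(lowest = head(ranking, n), highest = tail(ranking, n))
}

#' Hierarchical clustering of a prediction matrix
#'
#' Agglomerative clustering of sample rows on pairwise Euclidean distances,
#' optionally after per-drug (column) Z-scoring so all drugs contribute on
#' a common scale. The tree is cut into `k` clusters and cluster indices
#' are relabeled in order of decreasing cluster-mean prediction, so
#' cluster 1 is always the most drug-resistant group.
#'
#' @param pred Numeric matrix, samples x drugs (rows named by sample).
#' @param k Number of clusters (1 <= k <= n_samples).
#' @param zscore_first Z-score each drug column before distances (default
#'   TRUE).
#' @param linkage Agglomeration method (default `"complete"`).
#' @return Object of class `gpdrp_clusters`: `labels` (named integer
#'   vector in 1..k), `k`, `metric`, `linkage`, `merge_heights`, and the
#'   underlying `hclust` tree.
#' @export
hierarchical_cluster <- function(pred, k, zscore_first = TRUE,
                                 linkage = c("complete", "ward.D2", "average")) {
  linkage <- match.arg(linkage)
  pred <- as.matrix(pred)
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(pred)) stop("k cannot exceed the number of samples")
  if (is.null(rownames(pred))) rownames(pred) <- paste0("sample", seq_len(nrow(pred)))
  Z <- if (zscore_first) zscore(pred, axis = "columns") else pred
  h <- hclust(dist(Z, method = "euclidean"), method = linkage)
  raw <- cutree(h, k = k)
  means <- tapply(rowMeans(pred), raw, mean)
  ord <- as.integer(names(sort(means, decreasing = TRUE)))
  labels <- match(raw, ord)
  names(labels) <- rownames(pred)
  structure(list(labels = labels, k = as.integer(k), metric = "euclidean",
                 linkage = linkage, merge_heights = h$height, hclust = h),
            class = "gpdrp_clusters")
}

#' @method print gpdrp_clusters
#' @export
print.gpdrp_clusters <- function(x, ...) {
  cat("Hierarchical clustering (", x$metric, " distance, ", x$linkage,
      " linkage): ", length(x$labels), " samples in ", x$k, " clusters\n",
      sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Per-cluster pathway-score summaries
#'
#' Pools the scores of a pathway subset over the samples of each cluster
#' and summarizes the pooled distribution (n, mean, median, quartiles) —
#' the numbers behind per-cluster pathway boxplots.
#'
#' @param clusters A [hierarchical_cluster()] result.
#' @param scores A [pathway_matrix()] whose columns cover all clustered
#'   samples.
#' @param pathway_subset Character vector of pathway ids to pool (e.g. a
#'   proliferation-related set).
#' @return Data frame with one row per cluster: `cluster`, `n_samples`,
#'   `n_values`, `mean`, `median`, `q1`, `q3`. The pooled values are
#'   attached as attribute `"values"` (a list, one vector per cluster).
#' @export
summarize_cluster_pathways <- function(clusters, scores, pathway_subset) {
  stopifnot(inherits(clusters, "gpdrp_clusters"),
            inherits(scores, "pathway_matrix"))
  unknown <- setdiff(pathway_subset, scores$pathway_ids)
  if (length(unknown)) {
    stop("unknown pathway id(s): ", paste(unknown, collapse = ", "))
  }
  missing_samples <- setdiff(names(clusters$labels), scores$cell_line_ids)
  if (length(missing_samples)) {
    stop("samples absent from score matrix: ",
         paste(head(missing_samples, 5L), collapse = ", "))
  }
  rows <- lapply(sort(unique(clusters$labels)), function(cl) {
    members <- names(clusters$labels)[clusters$labels == cl]
    vals <- as.vector(scores$values[pathway_subset, members, drop = FALSE])
    data.frame(cluster = cl, n_samples = length(members),
               n_values = length(vals), mean = mean(vals),
               median = median(vals),
               q1 = unname(quantile(vals, 0.25)),
               q3 = unname(quantile(vals, 0.75)))
  })
  out <- do.call(rbind, rows)
  attr(out, "values") <- lapply(sort(unique(clusters$labels)), function(cl) {
    members <- names(clusters$labels)[clusters$labels == cl]
    as.vector(scores$values[pathway_subset, members, drop = FALSE])
  })
  out
}

#' Write analysis reports
#'
#' Writes the drug ranking and cluster assignment as CSV (byte-identical on
#' re-runs), a clustered prediction heatmap (PDF), and per-cluster pathway
#' boxplots (PDF) into `out_dir`.
#'
#' @param pred Samples x drugs prediction matrix.
#' @param ranking Output of [rank_drugs_by_median()].
#' @param clusters Output of [hierarchical_cluster()].
#' @param summaries Output of [summarize_cluster_pathways()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the four file paths, invisibly.
#' @export
render_reports <- function(pred, ranking, clusters, summaries, out_dir) {
  pred <- as.matrix(pred)
  if (nrow(pred) < 1L || ncol(pred) < 1L) stop("empty prediction matrix")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  f_rank <- file.path(out_dir, "drug_ranking.csv")
  f_clus <- file.path(out_dir, "cluster_assignment.csv")
  f_heat <- file.path(out_dir, "prediction_heatmap.pdf")
  f_box <- file.path(out_dir, "cluster_pathway_boxplots.pdf")

  write.table(ranking, f_rank, sep = ",", row.names = FALSE, quote = FALSE)
  write.table(data.frame(sample_id = names(clusters$labels),
                         cluster = unname(clusters$labels)),
              f_clus, sep = ",", row.names = FALSE, quote = FALSE)

  pheatmap::pheatmap(pred, clustering_distance_rows = "euclidean",
                     clustering_method = clusters$linkage,
                     filename = f_heat, silent = TRUE)

  vals <- attr(summaries, "values")
  pdf(f_box, width = 6, height = 4)
  boxplot(vals, names = paste("cluster", summaries$cluster),
          ylab = "pathway score", col = "grey85")
  dev.off()
  invisible(c(f_rank, f_clus, f_heat, f_box))
}
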