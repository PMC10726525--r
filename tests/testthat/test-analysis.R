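test_that("drugs rank by ascending median with id tie-breaks", {
  m <- cbind(drug1 = c(3, 3), drug2 = c(1, 1), drug3 = c(2, 2))
  r <- rank_drugs_by_median(m)
  expect_identical(r$drug_id, c("drug2", "drug3", "drug1"))

  # even sample count: midpoint average, vs a sorting oracle
  set.seed(6)
  m2 <- matrix(rnorm(8 * 5), 8, 5,
               dimnames = list(NULL, paste0("d", 1:5)))
  r2 <- rank_drugs_by_median(m2)
  oracle <- vapply(seq_len(5), function(j) {
    v <- sort(m2[, j]); (v[4] + v[5]) / 2
  }, numeric(1))
  expect_equal(sort(r2$median_ln), sort(oracle), tolerance = 1e-12)
  expect_identical(r2$drug_id, paste0("d", order(oracle, paste0("d", 1:5))))

  # all-equal columns fall back to id order
  m3 <- matrix(1, 3, 4, dimnames = list(NULL, c("b", "a", "d", "c")))
  expect_identical(rank_drugs_by_median(m3)$drug_id, c("a", "b", "c", "d"))
  expect_error(rank_drugs_by_median(matrix(numeric(), 0, 0)), "empty")
})

test_that("ranking matches a brute-force sort oracle on random matrices", {
  set.seed(14)
  for (rep in 1:4) {
    m <- matrix(rnorm(21 * 9), 21, 9,
                dimnames = list(NULL, sprintf("dr%02d", sample(9))))
    r <- rank_drugs_by_median(m)
    med <- apply(m, 2, median)
    expect_identical(r$drug_id, names(sort(med)))
    expect_equal(r$median_ln, unname(sort(med)))
  }
  ex <- rank_extremes(rank_drugs_by_median(matrix(rnorm(40 * 15), 40, 15,
        dimnames = list(NULL, sprintf("d%02d", 1:15)))), n = 6)
  expect_identical(nrow(ex$lowest), 6L)
  expect_identical(nrow(ex$highest), 6L)
})

test_that("hierarchical clustering recovers planted blobs and orders clusters", {
  x <- generate_xenograft_fixture(seed = 5)
  cl <- hierarchical_cluster(x$predictions, k = 3)
  expect_identical(sort(unique(cl$labels)), 1:3)
  ari <- mclust::adjustedRandIndex(cl$labels[x$samples$sample_id],
                                   x$samples$cluster)
  expect_equal(ari, 1)
  # cluster 1 is the most resistant (highest mean prediction)
  means <- tapply(rowMeans(x$predictions)[names(cl$labels)], cl$labels, mean)
  expect_identical(order(means, decreasing = TRUE), 1:3 |> as.integer())
  expect_identical(cl$metric, "euclidean")
})

test_that("clustering degenerate cases behave", {
  set.seed(3)
  m <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(paste0("s", 1:6), NULL))
  singles <- hierarchical_cluster(m, k = 6, zscore_first = FALSE)
  expect_identical(sort(unname(singles$labels)), 1:6)

  dup <- m[rep(1:3, each = 2), ]
  rownames(dup) <- paste0("r", 1:6)
  cld <- hierarchical_cluster(dup, k = 3, zscore_first = FALSE)
  expect_identical(unname(cld$labels[c(1, 3, 5)]), unname(cld$labels[c(2, 4, 6)]))

  expect_error(hierarchical_cluster(m, k = 0), ">= 1")
  expect_error(hierarchical_cluster(m, k = 7), "exceed")
})

test_that("clustering is invariant to sample order", {
  x <- generate_xenograft_fixture(seed = 8)
  cl1 <- hierarchical_cluster(x$predictions, k = 3)
  perm <- sample(nrow(x$predictions))
  cl2 <- hierarchical_cluster(x$predictions[perm, ], k = 3)
  common <- names(cl1$labels)
  expect_equal(mclust::adjustedRandIndex(cl1$labels[common],
                                             cl2$labels[common]), 1)
})

test_that("cluster pathway summaries pool correctly", {
  x <- generate_xenograft_fixture(seed = 4, prolif_shift = 2)
  cl <- hierarchical_cluster(x$predictions, k = 3)
  s <- summarize_cluster_pathways(cl, x$scores, x$prolif_pathways)
  expect_identical(sum(s$n_samples), 54L)
  expect_identical(s$n_values, s$n_samples * 12L)
  # planted shift: cluster 1 (resistant) has the lowest proliferation scores,
  # adjacent clusters differ by about the planted 2 units
  expect_lt(s$mean[s$cluster == 1], s$mean[s$cluster == 2])
  expect_equal(s$mean[s$cluster == 2] - s$mean[s$cluster == 1], 2,
               tolerance = 0.15)
  expect_equal(s$mean[s$cluster == 3] - s$mean[s$cluster == 1], 4,
               tolerance = 0.2)

  # single cluster, single pathway: plain row summary
  cl1 <- hierarchical_cluster(x$predictions, k = 1)
  s1 <- summarize_cluster_pathways(cl1, x$scores, x$prolif_pathways[1])
  row <- x$scores$values[x$prolif_pathways[1], ]
  expect_equal(s1$mean, mean(row))
  expect_equal(s1$median, median(row))

  expect_error(summarize_cluster_pathways(cl, x$scores, "NOT_A_PATHWAY"),
               "NOT_A_PATHWAY")
})

test_that("reports render four files with reproducible tabular bytes", {
  x <- generate_xenograft_fixture(seed = 9)
  cl <- hierarchical_cluster(x$predictions, k = 3)
  rk <- rank_drugs_by_median(x$predictions)
  sm <- summarize_cluster_pathways(cl, x$scores, x$prolif_pathways)
  d1 <- withr::local_tempdir()
  files <- render_reports(x$predictions, rk, cl, sm, d1)
  expect_length(files, 4L)
  expect_true(all(file.exists(files)))

  d2 <- withr::local_tempdir()
  files2 <- render_reports(x$predictions, rk, cl, sm, d2)
  expect_identical(readLines(files[1]), readLines(files2[1]))
  expect_identical(readLines(files[2]), readLines(files2[2]))

  d3 <- file.path(withr::local_tempdir(), "fresh")
  expect_error(render_reports(matrix(numeric(), 0, 0), rk, cl, sm, d3), "empty")
  expect_false(dir.exists(d3))  # no partial output on error
})
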