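# gpdrp — multimodal drug-response regression from molecular graphs and pathway activity

`gpdrp` predicts drug sensitivity — the natural-log half-maximal
inhibitory concentration (LN IC50) — for drug / cell-line pairs from two
modalities:

* **drugs as molecular graphs.** SMILES strings become heavy-atom graphs
  with a five-block binary atom featurization (element symbol, heavy-atom
  degree, hydrogen count, implicit valence, aromaticity; 78 dimensions by
  default) and are encoded by a graph neural network. Four encoder
  variants are provided: graph convolution (GCN), graph attention (GAT,
  10 heads on the first layer), graph isomorphism (GIN), and the default
  hybrid of two GIN layers with one graph-transformer layer whose
  self-attention uses Laplacian positional encodings
  (eigenvectors of `L = I − D^(−1/2) A D^(−1/2)`).
* **cell lines as pathway-activity vectors.** Per-pathway min–max
  normalized enrichment scores pass through a dense
  512 → 1024 → (dropout 0.2) → 128 network.

The two 128-dimensional embeddings are concatenated into a
256-dimensional vector and regressed through 1024 → 128 → 1 fully
connected layers with a sigmoid output. Training minimizes mean squared
error on the scaled response

    ŷ = 1 / (1 + exp(−0.1 · x)),        x = LN IC50,

with Adam (learning rate 1e-4), early stopping on validation RMSE, and a
**cell-line-grouped 80/10/10 split**: every pair inherits its cell line's
partition, so no cell line leaks across partitions. Predictions are
reported on both the (0,1) scale and the LN scale via the closed-form
inverse `10·log(ŷ/(1−ŷ))`. The package is written in base R; the graph
layers, attention, normalization layers and backpropagation are
implemented in-package on sparse block-diagonal graph batches and are
verified against dense brute-force oracles and numerical gradients in the
test suite.

A synthetic-study generator ships with the package (valid drug-like
SMILES by scaffold decoration, bounded low-rank pathway scores, responses
with a planted drug × cell-line signal plus Gaussian noise, and a
54-sample xenograft-style clustered fixture), so everything is testable
without external downloads. Downstream analysis tools rank drugs by
median predicted LN IC50, cluster samples hierarchically on Euclidean
distances, and summarize pathway scores per cluster.

## Worked example

```r
library(gpdrp)

spec <- synthetic_spec(n_drugs = 20, n_cell_lines = 30, n_pathways = 60,
                       latent_rank = 6, seed = 11)
ds <- generate_synthetic_dataset(spec)

fit <- gpdrp(ds$responses, ds$drugs, ds$pathways,
             variant = "GIN_TRANSFORMER",
             control = gpdrp_control(max_epochs = 60, seed = 3))
fit
#> Multimodal drug-response model (GIN_TRANSFORMER drug encoder)
#>   20 drugs, 30 cell lines, 60 pathway features
#>   trained 60 epochs (best epoch 55)
#>   test: RMSE 0.0151, PCC 0.9075 on 53 pairs (scaled scale)

summary(fit)
#> Drug-response model, drug encoder: GIN_TRANSFORMER
#> Trainable parameters: 1,292,035
#> Cell-line split: test 3, train 24, validation 3
#> Epochs run: 60  (best: 55 )
#>   train      RMSE 0.0127, PCC 0.9490 on 435 pairs (scaled scale)
#>   validation RMSE 0.0132, PCC 0.9518 on 52 pairs (scaled scale)
#>   test       RMSE 0.0151, PCC 0.9075 on 53 pairs (scaled scale)
```

The test RMSE/PCC are computed on cell lines never seen in training. The
test correlation (0.91) sits close to the ceiling of the planted signal:
`oracle_linear_pcc(ds$responses, ds$truth, fit$split)` — the closed-form
least-squares fit on the generator's true drug/cell descriptors — gives
0.92 on the same held-out cells.

Predict for arbitrary pairs (both scales; `pred_ln` is LN IC50, lower =
more sensitive):

```r
pred <- predict(fit, pairs = expand.grid(drug_id = ds$drugs$drug_id,
                                         cell_line_id = "CL001",
                                         stringsAsFactors = FALSE))
head(pred, 3)
#>   drug_id cell_line_id pred_scaled   pred_ln
#> 1 DRUG001        CL001   0.4345720 -2.632214
#> 2 DRUG002        CL001   0.4422944 -2.318556
#> 3 DRUG003        CL001   0.4315553 -2.755085
```

Downstream analysis on a (here synthetic) samples × drugs prediction
matrix:

```r
x <- generate_xenograft_fixture(seed = 1)        # 54 samples, 3 planted clusters
cl <- hierarchical_cluster(x$predictions, k = 3) # cluster 1 = most resistant
cl
#> Hierarchical clustering (euclidean distance, complete linkage): 54 samples in 3 clusters
#> cluster
#>  1  2  3
#> 18 18 18

summarize_cluster_pathways(cl, x$scores, x$prolif_pathways)
#>   cluster n_samples n_values        mean      median         q1         q3
#> 1       1        18      216 -1.99964450 -1.99613073 -2.1821298 -1.8081962
#> 2       2        18      216 -0.02110595 -0.01527482 -0.2014438  0.1882673
#> 3       3        18      216  1.99185262  1.98072253  1.8041931  2.1846471
```

The resistant cluster shows the lowest proliferation-pathway activity —
the association the fixture plants and the analysis is designed to
expose. `rank_drugs_by_median()` / `rank_extremes()` give the most and
least effective drugs, and `render_reports()` writes the ranking,
cluster assignment, heatmap and boxplots to disk.

A thin command-line wrapper over these functions is installed at
`inst/cli/gpdrp.R` (`simulate`, `train`, `predict`, `evaluate`,
`analyze` subcommands).

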