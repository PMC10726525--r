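---
title: "Modeling drug response from molecular graphs and pathway activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling drug response from molecular graphs and pathway activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpdrp)
```

## The problem

Drug-response prediction asks: given a compound and a cancer cell line,
how sensitive is the cell line to the compound? Sensitivity is summarized
by the natural-log half-maximal inhibitory concentration (LN IC50): lower
values mean less drug is needed to halve viability, i.e. higher
sensitivity. gpdrp frames this as a regression on drug/cell-line pairs
with two input modalities:

* **the drug**, represented not as a string fingerprint but as its
  molecular graph — atoms as nodes, bonds as edges — so that structural
  information survives featurization; and
* **the cell line**, represented by a vector of pathway activity scores
  (per-sample gene-set enrichment values such as GSVA scores), so that
  genes act through their pathway context instead of as thousands of
  independent expression coordinates.

## Drug branch: molecular graphs and graph neural networks

### Atom featurization

`smiles_to_graph()` parses a SMILES string into a heavy-atom graph
(hydrogens are implicit) and attaches to each atom a binary feature
vector with five blocks:

1. one-hot element symbol over a fixed 44-entry vocabulary ending in an
   `"other"` bucket;
2. one-hot heavy-atom degree (0–10, clamped at 10);
3. one-hot hydrogen count (implicit plus explicit, 0–10, clamped);
4. one-hot implicit valence (0–10, clamped);
5. a single aromaticity flag.

The default schema therefore has dimension 44 + 11 + 11 + 11 + 1 = 78,
and every atom row carries exactly one 1 per categorical block — a
property the test suite asserts across whole drug panels. Bonds are
featureless and undirected; bond order is not encoded. Multi-fragment
inputs (salts) keep the largest fragment with a warning.

Two conventions deserve mention. Clamping makes the encoding total: an
exotic atom or high-valence center never fails, it only saturates its
block. And the implicit-valence attribute is defined as the hydrogen
count inferred by the package's default-valence model; for the rare atoms
whose hydrogens are written explicitly in SMILES brackets (pyrrole's
`[nH]`) some toolkits book that hydrogen as "explicit" and report implicit
valence 0 — the total hydrogen count, which is what the feature family is
meant to convey, agrees either way.

### Encoders

Four graph encoders map a molecular graph to a 128-dimensional
embedding; all end with global max pooling over nodes followed by one
fully connected layer to 128 dimensions, with rectifier activations
throughout:

* **GCN** — three spectral convolution layers with the symmetric
  normalized propagation rule
  $H^{(l+1)} = \sigma(\tilde D^{-1/2}\tilde A\tilde D^{-1/2}H^{(l)}W^{(l)})$,
  where $\tilde A = A + I$ adds self-loops (so every degree is at least
  one and the normalization is total).
* **GAT** — three attention layers. Per head, features are transformed
  ($Z = HW$), attention logits over each node's first-order neighborhood
  (self-loop included) are a leaky-rectified additive score, normalized
  by a per-node softmax; the first layer uses 10 heads with concatenated
  outputs, the second and third produce 128 features each.
* **GIN** — three layers of
  $\mathrm{MLP}\big((1+\mu)x_i + \sum_{j \in N(i)} x_j\big)$ with batch
  normalization after each layer; $\mu$ defaults to a fixed 0 and can be
  made learnable.
* **GIN_TRANSFORMER** (default) — two GIN layers combined with one graph
  transformer layer: full self-attention over all atoms of one molecule
  (never across molecules in a batch), residual connections and layer
  normalization, plus a position-wise feed-forward block. Because plain
  attention is blind to graph structure, each node receives a Laplacian
  positional encoding: the eigenvectors of the symmetric normalized
  Laplacian $L = I - D^{-1/2}AD^{-1/2}$ for the 8 smallest nontrivial
  eigenvalues, concatenated to the input features before the first layer.
  Drug graphs here are homogeneous (one edge type), so the general
  heterogeneous-graph machinery a graph transformer supports collapses to
  standard self-attention with positional encodings.

The order of the hybrid stack is genuinely open — attention-first
("global context before local aggregation") and attention-last ("local
features first, then long-range integration") are both defensible. The
package defaults to transformer-last, on the reasoning that GIN's
neighborhood aggregation builds informative local descriptors whose
long-distance relations the attention layer can then capture; the order
is configurable (`transformer_position`).

Two numerical conventions make the drug branch reproducible. Eigenvector
signs are fixed by making the largest-magnitude entry positive (ties
broken by lowest index), and graphs with fewer than $k+1$ atoms are
zero-padded. When the Laplacian spectrum is exactly degenerate — as in
molecules with mirror-symmetric rings — any eigenbasis of the degenerate
subspace is valid, so embeddings are then reproducible for a fixed atom
order but not guaranteed invariant to atom relabeling; the permutation
invariance test uses a molecule with distinct eigenvalues for exactly
this reason.

## Cell branch and fusion

The cell-line encoder is a dense network over the pathway-score vector:
512, then 1024 units, a dropout layer at rate 0.2, then 128 units, all
rectified. Pathway scores are min–max normalized per pathway to [0, 1],
$\hat x_{ik} = (x_{ik} - \min_k x_i) / (\max_k x_i - \min_k x_i)$.
Normalizing across *all* cell lines lets test columns influence the
statistics; the fit therefore computes the row statistics on training
cell lines only by default (`normalize = "train"`), applies them to
held-out columns and clips to [0, 1]. `normalize = "global"` restores the
all-columns variant. Constant rows, where the transform is undefined, map
to zero with a warning so the feature stays inert.

The two 128-dimensional embeddings are concatenated (drug first) into a
256-dimensional vector and passed through two fully connected layers of
1024 and 128 units to a single output. A sigmoid squashes the output into
(0, 1), matching the response scale.

## Response scale

Raw LN IC50 values are unbounded; training uses the transform
$\hat y = 1/(1 + e^{-0.1x})$ — a gentle sigmoid that spreads typical
log-IC50 ranges evenly over (0, 1). Its closed-form inverse,
`unscale_response()`, is $10\,\log(\hat y/(1-\hat y))$, so predictions are
reported on both scales. The exponent is fixed at −0.1 throughout.
Training and the reported RMSE/PCC metrics live on the scaled response
(RMSE on this scale is always in [0, 1]); the correlation is of course
scale-free under the monotone transform only in rank, so both scales are
available on the fitted object.

## Training procedure

* **Split.** Cell lines — not pairs — are partitioned 80/10/10 into
  train/validation/test (`split_by_cellline()`); every pair inherits its
  cell line's partition, so no cell line ever spans two partitions. Group
  sizes are the rounded fractions with the remainder going to train. A
  pair-level split would leak cell-line identity between partitions, so
  the grouped split is the primary design.
* **Loss and optimizer.** Mean squared error on the scaled response,
  Adam with learning rate 1e-4, dropout 0.2, rectifier activations.
* **Batching.** All molecules of the panel are stacked into one
  block-diagonal sparse graph, so each optimizer step re-encodes the
  whole panel as a single sparse matrix product; per-pair work is limited
  to the fusion head. The default batch size is 512 pairs — with the
  panel re-encoded once per step, fewer and larger steps are cheaper at
  equal statistical behavior; batch size, epoch budget (200) and
  early-stopping patience (20 epochs on validation RMSE) are all
  configurable and recorded on the fitted object. Dropout in the cell
  branch is drawn per cell line per step and shared by the step's pairs
  that use that cell line.
* **Determinism.** One integer seed drives initialization, the split,
  shuffling and dropout; two fits with the same seed produce identical
  epoch logs, which the test suite asserts.

Gradients for every layer — including the attention softmax, batch and
layer normalization, and the max-pooling routing — are implemented
in-package and verified against central-difference numerical gradients at
tolerance 1e-3 (relative) in the tests, alongside dense brute-force
oracles for each layer's forward formula at 1e-6.

## Synthetic benchmark

Because real pharmacogenomic screens are large external resources, the
package ships a generator whose defaults define its reference study:

* **Drug panel** — `generate_drug_panel()` decorates 11 drug-like ring
  scaffolds with 18 substituent fragments, guaranteeing valid, distinct,
  featurizable SMILES without rejection sampling (capacity 198; a
  screen-sized panel of 173 is one test case). 60 drugs by default.
* **Pathway matrix** — `generate_pathway_matrix()` draws a rank-10
  latent factor product rescaled into [−1, 1], plus Gaussian noise and
  clipping, mimicking the bounded, correlated structure of per-sample
  enrichment scores. 200 pathways × 80 cell lines by default.
* **Responses** — `generate_responses()` plants
  $y_{dc} = a\,\delta(d) + b\,\pi(c) + c\,\delta(d)\pi(c) + \varepsilon$
  with $\delta$ a standardized graph descriptor (aromatic-atom fraction
  plus scaled heavy-atom count — computable from what the model sees),
  $\pi$ a standardized weighted sum of a sparse 10-pathway subset,
  coefficients (1, 1, 0.5), noise sd 0.5 on the LN scale, and 10% of
  pairs masked as unlabeled. The ground truth is returned so recovery is
  testable; `oracle_linear_pcc()` gives the held-out correlation of the
  closed-form least-squares fit on $(\delta, \pi)$ — the planted ceiling
  the network is compared against.
* **Xenograft fixture** — `generate_xenograft_fixture()` emulates a
  54-sample xenograft study (groups of 9, 8, 10, 12 and 15 samples over
  pre/post-castration, castration-resistant, and treatment-sensitive/
  resistant conditions) with a planted three-cluster structure: cluster
  means in the prediction matrix separated by 3 LN units (cluster 1 most
  resistant) and a 12-pathway proliferation set shifted by 2 units per
  cluster, resistant clusters lowest — so that resistance associates with
  low proliferation scores, the direction the downstream summaries are
  designed to expose.

What the generator does **not** emulate: real pharmacology (no specific
drug classes or mechanisms), dose-response curve fitting upstream of
LN IC50, expression data upstream of pathway scores, batch effects, or
heavy-tailed assay noise. Passing the recovery tests therefore shows the
architecture and training loop can extract a planted multimodal signal at
realistic noise levels under a leak-free split — not that it reproduces
any particular real screen's accuracy.

With the reference conditions (60 × 80 × 200, seed 1), training the
hybrid encoder takes a couple of minutes on one CPU; the test suite and
the acceptance script run the full study at exactly these sizes. The
held-out correlation lands within 0.15 of the linear oracle, and a
shuffled-label control stays near zero — the two ends of the
signal-recovery contract.

## Downstream analyses

`predict()` on a fitted model returns both scales for arbitrary pairs,
including drugs or samples unseen at fit time (new pathway columns are
normalized with the statistics stored at fit time). A prediction matrix
(samples × drugs, LN scale) feeds three analyses:

* `rank_drugs_by_median()` orders drugs by median predicted LN IC50,
  ascending, ties broken by drug id; `rank_extremes()` selects the six
  most and least effective drugs.
* `hierarchical_cluster()` Z-scores each drug column (population sd; the
  per-drug direction makes drugs comparable), computes Euclidean
  distances between sample rows and cuts the agglomerative tree at k.
  Only the metric is inherent to the method; the linkage is a choice and
  defaults to complete (recorded in the output, ward/average available).
  Cluster indices are relabeled by decreasing cluster-mean prediction so
  cluster 1 is always the most resistant group.
* `summarize_cluster_pathways()` pools a pathway subset (e.g. a
  12-pathway proliferation set) over each cluster's samples and reports
  n, mean, median and quartiles — the numbers behind per-cluster
  boxplots. `render_reports()` writes the ranking and assignment as
  byte-reproducible CSVs plus heatmap and boxplot PDFs.

## Degenerate inputs and edge cases

* Constant pathway rows normalize to zero (warning), and constant slices
  are an error for Z-scoring, which names the offending slice.
* Single-atom molecules are legal graphs: no edges, self-loop-normalized
  GCN, self-attention over one token, positional encoding all zeros.
* `unscale_response()` rejects values outside the open unit interval;
  predictions are clipped infinitesimally before unscaling.
* Unknown drug or cell ids at prediction time are an error listing the
  offenders, as is a pathway axis that does not match the fit.
* The split requires at least 3 cell lines and a non-empty validation
  partition (early stopping needs one).

## Known limitations

* The graph transformer is single-head; multi-head attention would be a
  straightforward extension but is not required by the reference
  configuration.
* Exact permutation invariance of the hybrid encoder is guaranteed only
  for molecules with non-degenerate Laplacian spectra (see above).
* Bond types, stereochemistry and 3D geometry are deliberately outside
  the featurization.
* Training runs on one CPU; there is no device parallelism. The engine
  is sized for panel-scale studies (hundreds of drugs, hundreds of cell
  lines), not for million-pair screens.
* Pathway scores are consumed, not computed: producing GSVA-style scores
  from expression data is upstream of this package.
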