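# multigatae

Cancer subtype discovery from multi-omics profiles. The package fuses
per-omics patient similarity networks into one patient graph (similarity
network fusion, SNF), learns a low-dimensional patient embedding with a
graph-attention autoencoder plus an omics-level attention that weighs the
layers, clusters the embedding with silhouette-selected K-means, and scores
the resulting subtypes by survival separation. It is aimed at computational
biologists who have several numeric sample-by-feature matrices (e.g. TCGA
mRNA, miRNA, DNA methylation) over a shared cohort plus a clinical survival
table, and want reproducible subtype calls with survival evidence.

## Method in brief

1. **Similarity graph.** Per layer, a scaled exponential kernel
   `W_ij = exp(-d_ij^2 / (alpha * eps_ij^2))` with local scaling
   `eps_ij = (d̄_i + d̄_j + d_ij)/3`; normalisation with half-mass diagonal
   (`P_ii = 1/2`, rows summing to 1); K-nearest-neighbour operator `S`.
   Fusion iterates `P(h) <- S(h) (mean of the other layers' P) S(h)^T` with
   symmetrisation and re-normalisation, and averages after T rounds.
2. **Embedding.** One two-layer graph-attention encoder per omics layer on
   the shared sparsified graph (masked additive attention, softmax per
   neighbourhood); omics-level attention weights `beta = softmax(w)` with
   `w_i = mean v' tanh(Z_i Wz + A Wa)`; `Z_final = sum_i beta_i Z_i`;
   inner-product decoder `sigmoid(Z Z^T)` trained with positive-reweighted
   binary cross-entropy (Adam, lr 0.01, attention dropout 0.5, seeded).
3. **Subtypes + evaluation.** K-means (k-means++, 10 restarts) with the
   cluster number picked by mean silhouette width over k = 2..10; k-group
   log-rank test reported as -log10 p and Harrell's C-index from a
   subtype-indicator Cox model.

## Worked example

Everything below is computed, not loaded: the package ships a seeded
generator for multi-omics cohorts with known subtypes and subtype-linked
survival.

```r
library(multigatae)

coh <- generate_cohort(synthetic_spec(seed = 42))   # 150 samples, 3 subtypes
res <- run_pipeline(run_config(seed = 42),
                    omics = coh$omics, clinical = coh$clinical)

res$subtypes
#> <subtype_result> 150 samples, k = 3 (silhouette 0.930)
res$metrics
#> $k
#> [1] 3
#> $neglog10_p
#> [1] 11.95417
#> $c_index
#> [1] 0.6964924
mclust::adjustedRandIndex(res$subtypes$labels,
                          coh$true_labels[res$subtypes$sample_ids])
#> [1] 1
```

The three subtypes are recovered exactly (adjusted Rand index 1), the
selected cluster number matches the planted one, the log-rank separation is
far beyond the p < 0.05 convention (-log10 p = 12.0 >> 1.3), and the C-index
of about 0.70 reflects the >= 3-fold hazard ratios built into the cohort.

From the shell, the same pipeline runs as:

```sh
multigatae simulate --config config.yaml --out data/   # or bring your own TSVs
multigatae run --config config.yaml --seed 42
```

with a YAML config naming the omics matrices (samples in rows, first column
sample IDs), the clinical table (`sample_id`, `time`, `event`), and any
non-default parameters. Subcommands `fuse`, `embed`, `cluster`, `evaluate`
run the stages separately over a shared output directory.

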