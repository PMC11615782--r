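# phylofuse

Phylogeny-aware OTU embeddings fused with abundance information, for
microbiome analysis in R.

Amplicon (16S) data arrive as a sparse, high-dimensional OTU-by-sample count
table plus a phylogenetic tree relating the OTUs. Most learning methods use
only the table and discard the tree, even though related taxa tend to share
functional roles and therefore effects on host phenotypes. `phylofuse`
encodes the tree into per-OTU embeddings and combines them with abundances
in two ways:

1. **Unsupervised features** — robust Aitchison PCA (RPCA) of the abundance
   table gives dense per-sample abundance features; summation pooling of the
   embeddings of the OTUs *present* in each sample gives a phylogenetic
   profile; concatenating both yields fused sample features for ordination,
   clustering and PERMANOVA-style testing.
2. **Supervised dual-tower network** — a linear tower encodes the abundance
   vector, `f_A = a(W x_A + b)`; a 1D-convolutional tower slides `h` filters
   of width `l` along the tree-ordered embeddings of the present OTUs and
   max-pools each filter, `f_P = maxpool(a(conv(X_P)))`; the towers fuse by
   element-wise product `f = f_A ⊗ f_P` and a linear head produces the
   prediction (identity for regression, sigmoid for binary / multilabel).
   Training is minibatch AdamW (decoupled weight decay) with early stopping
   on validation loss.

The OTU embeddings are the first `d` principal-component scores of the
patristic distance matrix `D` (`D[i,j]` = summed branch lengths on the path
between leaves `i` and `j`): `X_P = PCA(D)`.

The package also ships the evaluation stack (sensitivity, specificity,
accuracy, precision, F1, MCC, ROC-AUC, AUPR/APS, R²; 68:12:20 and
leave-one-dataset-out splits) and a simulation framework: a birth–death
tree, NorTA (Normal-To-Anything) Gaussian-copula counts with zero-inflated
negative-binomial marginals and tree-decay correlation, and Bernoulli
outcomes driven by phylogenetically clustered OTU effects
(`η_i = Σ_k Σ_{j∈C_k} β_k x_ij`, `β_k ~ N(0, σ_β²)`, `p_i = sigmoid(η_i)`).

## Worked example

```r
library(phylofuse)

tree <- read_newick("((A:1.0,B:2.0):0.5,C:3.0);", text = TRUE)
D <- patristic_distances(tree)
D
#     A   B   C
# A 0.0 3.0 4.5
# B 3.0 0.0 5.5
# C 4.5 5.5 0.0
round(pca_embed(D, d = 2)$X, 3)
#      PC1    PC2
# A  1.587 -2.263
# B  3.107  1.822
# C -4.693  0.441

# two sample groups that differ in which clade is prevalent
sim <- simulate_clade_groups(n_per_group = 30, m_otus = 80, seed = 5)
ab    <- rpca_features(sim$counts, rank = 3)
ph    <- sum_pool_phylo(sim$counts, phylo_embed(sim$tree, d = 16))
fused <- fuse_features(ab, ph)

permanova_f(ab,    sim$groups, n_permutations = 999, seed = 1)
# abundance-only RPCA : F = 1.20 (p = 0.324)
permanova_f(fused, sim$groups, n_permutations = 999, seed = 1)
# fused features      : F = 4.88 (p = 0.001)
kmeans_ari(ab,    sim$groups, k = 2, seed = 1)   # 0.10
kmeans_ari(fused, sim$groups, k = 2, seed = 1)   # 0.58
```

The group difference is a clade-level prevalence shift, so the abundance
block alone barely separates the groups (F = 1.2, not significant) while
the fused features do (F = 4.9, p = 0.001; K-means ARI 0.58 vs 0.10).

Supervised use follows the same pattern:

```r
sim  <- make_benchmark(n_samples = 400, m_otus = 200, K_clusters = 20,
                       signal_density = 0.4, informative = TRUE, seed = 1)
emb  <- phylo_embed(sim$tree, d = 32)
data <- pf_data(sim$counts, emb, sim$y)
cfg  <- pf_config(m = 200, d = 32, h = 64, l = 3, task = "binary",
                  learning_rate = 3e-3, seed = 1)
model <- pf_train(data, cfg, sim$split$train, sim$split$val)
preds <- predict(model, data, sim$split$test)
mean((preds >= 0.5) == sim$y[sim$split$test])   # test accuracy
```

## Command line

Every stage is exposed through one entry point
(`inst/cli/phylofuse`, or `pf_cli()` from R):

```sh
phylofuse embed --tree tree.nwk --dim 64 --out embeddings.tsv
phylofuse ablate-embeddings --embeddings embeddings.tsv --fraction 0.5 --seed 3 --out ablated.tsv
phylofuse fuse --table counts.tsv --embeddings embeddings.tsv --rank 3 --out fused.tsv
phylofuse cluster-eval --features fused.tsv --metadata meta.tsv --group city --seed 1
phylofuse train --table counts.tsv --embeddings embeddings.tsv --labels y.tsv --task binary --seed 1 --out run/
phylofuse simulate --n 400 --m 927 --clusters 20 --density 0.2 --informative --seed 1 --out sim/
```

Each run writes a `key<TAB>value` manifest (parameters, seed, input
checksums, headline results) for reproducibility.

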