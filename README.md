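# lppi — multi-level link prediction on attributed protein–protein interaction networks

Experimentally mapped protein–protein interaction (PPI) networks are large
(hundreds of thousands of links over tens of thousands of proteins),
incomplete, and expensive to extend in the lab, so computational
prioritization of candidate interactions matters. Random-walk node
embeddings (DeepWalk, node2vec) are a strong basis for link prediction on
such networks, but embedding a large graph directly is slow and ignores
what is known about the proteins themselves. `lppi` implements a
multi-level framework that addresses both:

1. **Graph fusion.** Node attributes (binary gene-set membership
   indicators such as positional gene sets, sequence-motif gene sets and
   immunological signatures) define a cosine-similarity graph `A_feat`
   over the same proteins, fused with the interaction topology as

       A_fusion = A_topo + β · A_feat      (default β = 0.1)

   The similarity graph is sparsified to a symmetrized k-nearest-neighbor
   graph (default k = 10).

2. **Spectral coarsening.** Random test vectors are low-pass filtered by
   Gauss–Seidel sweeps on the regularized Laplacian; node pairs with high
   spectral affinity

       a_pq = |⟨K_p, K_q⟩|² / (‖K_p‖² ‖K_q‖²)

   are greedily matched and merged, `l` times (default `l = 1`), with the
   coarse adjacency given by the Galerkin product `HᵀAH`.

3. **Embedding.** The coarsest graph is embedded with weighted random
   walks (10 walks of length 80 per node) and skip-gram with negative
   sampling, in `d = 128` dimensions; node2vec biasing (`p = 1.0`,
   `q = 0.5`) is available alongside first-order DeepWalk walks.

4. **Refinement.** The coarse embedding is prolonged through the
   hierarchy and smoothed with the σ-self-looped normalized adjacency,
   `Ê = (D̃^{-1/2} Ã D̃^{-1/2})^k H E`, back to full resolution.

5. **Classification.** Candidate pairs are featurized symmetrically
   (Hadamard product by default) and scored by L2-regularized logistic
   regression under 5-fold cross-validation, with per-fold negative
   sampling from the graph complement (optionally excluding pairs that
   share a cellular compartment). Reported metrics: Acc, Sen, Pre, MCC
   and ROC-AUC.

A seeded stochastic-block-model generator with block-correlated binary
attributes makes the whole pipeline testable offline; the same readers
accept real edge lists (TSV), attribute matrices (MatrixMarket or dense
TSV) and compartment labels (TSV).

## Worked example

```r
library(lppi)

fx <- lppi_fixture(seed = 7)   # 4 blocks x 75 nodes, binary attributes
fit <- lppi(fx$graph, fx$attributes, fx$compartments, seed = 1)
fit
```

```
Multi-level PPI link-prediction fit
  graph: 300 nodes, 1833 edges (density 0.04073)
  fused graph: 3803 edges (beta = 0.1)
  coarsening: level 1, coarsest graph 156 nodes
  embedding: deepwalk, 128 dimensions
  5-fold CV means: acc 0.9531  sen 0.9062  pre 1.0000  mcc 0.9102  auc 0.9913
```

The fused graph carries the 1,833 observed interactions plus β-weighted
attribute-similarity edges; one coarsening level halves the graph
(300 → 156 nodes) before embedding. The cross-validated means say that
held-out interactions are ranked almost perfectly above sampled
non-interactions (AUC 0.991), that at the 0.5 threshold about 95% of
held-out pairs are classified correctly, and that every pair predicted
to interact truly does (precision 1.0 — misclassifications are missed
positives, not false alarms). `summary(fit)` prints the per-fold
confusion counts and metrics, `plot(fit)` the pooled out-of-fold ROC
curve, and `predict(fit, data.frame(u = 0, v = 250))` scores new pairs.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/lppi.R", package="lppi"))')" \
    simulate --out data/
Rscript .../lppi.R pipeline --edges data/edges.tsv \
    --attrs data/attributes.mtx --compartments data/compartments.tsv \
    --out run1/ --seed 1
```

`pipeline` writes `report.csv` (per-fold Table-style metrics plus an
average row), `embedding.tsv` and a JSON `manifest.json` that makes the
run reproducible.

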