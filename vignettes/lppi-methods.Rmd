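---
title: "Multi-level link prediction on attributed PPI networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level link prediction on attributed PPI networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its own science: the model the
pipeline implements, the assumptions behind each stage, the parameters
that matter and why their defaults are what they are, what the synthetic
benchmark does and does not emulate, and the numerical and design choices
made where more than one reasonable option existed.

# The problem and the model

Given an undirected PPI network `A_topo` over `N` proteins and an
optional `N × F` matrix of non-negative node attributes, the package
predicts whether an unobserved protein pair interacts. The pipeline has
five stages.

**Graph fusion.** Attributes induce a second graph over the same
proteins: edge weights are cosine similarities between attribute rows,
and the fused working graph is the weighted sum
`A_fusion = A_topo + β A_feat`. The assumption is that attribute-similar
proteins (shared chromosomal position, shared regulatory motifs, shared
immunological signatures) are more likely to interact, so similarity
edges act as a structured prior that densifies the topology. The package
sparsifies `A_feat` to a symmetrized k-nearest-neighbor graph rather
than keeping all `O(N²)` pairs: full pairwise similarity would defeat
the scalability the multi-level scheme exists for, and beyond the top
few neighbors cosine similarities on sparse binary attributes are noise.
A dense mode is impractical only above a few thousand nodes, so the
tests use a brute-force dense similarity oracle to validate the sparse
path on small graphs. Attributes are used raw (no TF-IDF or
binarization). Similarity-only pairs are allowed to create new edges —
the fusion formula operates on all pairs, not only observed links.

**Spectral coarsening.** The graph is shrunk by merging node pairs that
the low-frequency spectrum of the Laplacian cannot distinguish. Rather
than computing eigenvectors, the package draws `t` standard-Gaussian
test vectors and applies a few Gauss–Seidel sweeps to the homogeneous
system `(D + σI − A) x = 0`; each sweep damps high-frequency components
fastest, so the smoothed rows `K_p` act as per-node low-frequency
signatures. The merge criterion is the spectral affinity
`a_pq = |⟨K_p,K_q⟩|² / (‖K_p‖²‖K_q‖²)`, the squared cosine of the two
signatures. Merging is a greedy maximal matching over graph edges sorted
by affinity, so a pass at most halves the node count and never merges
non-adjacent nodes; the coarse adjacency is the Galerkin product `HᵀAH`,
which conserves total edge weight (asserted to 1e-9 in the tests).

**Embedding.** The coarsest graph is embedded with weighted random walks
and skip-gram with negative sampling. Transition probabilities are
proportional to edge weight — the fused and coarse graphs are weighted,
and uniform walks would discard β's effect entirely. Node2vec walks
multiply each candidate step by the bias `1/p`, `1`, `1/q` according to
the candidate's hop distance (0, 1, 2) from the previous node; at
`p = q = 1` this reduces exactly to the first-order law, which the tests
verify at the transition-distribution level (χ² on 10,000+ steps).

**Refinement.** The coarse embedding is prolonged level by level
(`H E`, each fine node inheriting its cluster's row) and smoothed with
`k` applications of the σ-self-looped symmetric-normalized adjacency
`D̃^{-1/2}(A + σI)D̃^{-1/2}`, whose eigenvalues lie in `[−1, 1]`; the
smoothing adapts the copied rows to the fine topology without ever
growing the embedding norm.

**Classification.** Pair features are built from the two endpoint
embeddings with a symmetric operator and scored by L2-regularized
logistic regression under 5-fold cross-validation. Negatives are
sampled uniformly from the graph complement, per fold, optionally
excluding pairs that share a cellular compartment.

# Parameters, defaults, and why

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `beta` | 0.1 | Weight of the attribute-similarity graph in the fusion sum. The baseline configuration of the framework; the topology remains the dominant signal. |
| `knn_k` | 10 | Neighbors kept per node in the similarity graph. Enough to connect blocks of related proteins without densifying the graph. |
| `level` | 1 | Coarsening levels. One level roughly halves the graph; deeper levels trade accuracy for speed (the acceptance tests show level 3 shrinks the fixture > 4× while mean accuracy moves < 0.05). |
| `t_vectors` | 16 | Test vectors for the spectral signatures. More vectors sharpen affinities at linear extra cost; 16 is ample for graphs up to tens of thousands of nodes. |
| `gs_iters` | 2 | Gauss–Seidel sweeps. Low-pass filtering needs few sweeps: more sweeps shrink *all* components toward zero (the system is nonsingular for σ > 0) without changing their ordering much, and few sweeps keep coarsening linear-time. |
| `sigma` | 1.0 | Self-loop regularization in the smoothing and refinement operators (the standard renormalization convention); any small positive value works, it only needs to keep every node's degree positive. |
| `method` | `"deepwalk"` | First-order walks are the baseline embedder; `"node2vec"` with `p = 1.0`, `q = 0.5` (outward-biased walks) is the biased alternative. |
| `dim` | 128 | Embedding dimension. |
| `num_walks`, `walk_length` | 10, 80 | Walks per node and walk length — the usual corpus size for skip-gram graph embedding. |
| `window`, `epochs`, `negative`, learning rate | 10, 5, 5, 0.025 | Skip-gram training constants, following the original DeepWalk/node2vec conventions. |
| `power` (`k`) | 2 | Refinement smoothing rounds; 0 gives the pure projection. |
| `operator` | `"hadamard"` | Pair featurization. Nothing in the multi-level scheme dictates this choice, so it is exposed (`average`, `l1`, `l2` are available); the Hadamard product is the standard in the node-embedding link-prediction literature. |
| `folds` | 5 | Cross-validation folds. |

One deliberate naming change: the test-vector count, the refinement
power and the embedding dimension are three different quantities and get
three names (`t_vectors`, `power`, `dim`), even though they are all
conventionally called *k* somewhere in the multi-level embedding
literature.

The classifier is ridge-penalized logistic regression via glmnet with
`lambda = 1/n` — the same effective penalty as the common
scikit-learn-style default `C = 1` — fitted without standardization, and
a fixed decision threshold of 0.5. The threshold is not tuned: AUC is
reported alongside precisely because thresholded metrics on balanced
folds can saturate (a classifier that only errs by missing positives
shows precision exactly 1.0 while sensitivity absorbs all the error —
visible in the worked example).

# The synthetic benchmark

`lppi_fixture()` is the canonical test bed: a stochastic block model of
4 blocks × 75 nodes with `p_in = 0.15`, `p_out = 0.005`, 120 binary
attributes split evenly into block-owned groups (`signal = 0.6` within
the owning block, `noise = 0.05` elsewhere), compartment labels equal to
block labels, generator seed 7. The sizes were chosen once so that the
full default pipeline (128 dimensions, 10×80 walks) completes in seconds
on one CPU while link prediction is clearly above chance but not
saturated at machine precision.

What it emulates: community-structured interaction topology,
block-correlated binary gene-set membership, and compartment-restricted
negative sampling (block labels double as compartments, so filtered
negatives are inter-block pairs, the analogue of requiring negatives to
span cellular compartments).

What it does not emulate: the heavy-tailed degree distribution of real
PPI networks (the SBM is degree-homogeneous within blocks), overlapping
functional modules, attribute sparsity patterns of real gene-set
collections (real membership matrices are far sparser and correlated
across sets), and assay noise in the positive links themselves. Passing
the fixture therefore demonstrates that the machinery is correct and
that attribute fusion and coarsening behave as designed — not that the
reported metric levels transfer to any particular real network.

# Numerical choices and degenerate inputs

* **Mean removal after smoothing.** The constant vector is the trivial
  null mode of the Laplacian; without removing each test vector's mean,
  all affinities drift to 1 and matching becomes arbitrary.
* **Tie-breaking.** kNN similarity ties break by ascending node id;
  matching ties break by lexicographic `(min id, max id)` edge order.
  Both make runs bit-reproducible under a fixed seed.
* **Zero vectors.** Cosine similarity and spectral affinity involving an
  all-zero row are defined as 0; zero-attribute nodes simply contribute
  no similarity edges.
* **Coarse self-loops.** Cluster-internal weight lands on the diagonal
  of `HᵀAH`; it is zeroed in the stored coarse graph (self-loops are
  uninformative for walks) but included in the weight-conservation
  check.
* **Early stop.** Coarsening stops when a pass shrinks the graph by less
  than 2% (an edgeless graph cannot shrink at all), recording the
  achieved depth.
* **Isolated nodes.** They emit singleton walks, receive zero embedding
  rows, and are kept well-defined in the smoothing operators by the σ
  self-loop.
* **Degenerate metrics.** Any confusion-derived metric with a zero
  denominator is reported as 0 and flagged; counts are accumulated in
  double precision to keep the MCC denominator exact far beyond 32-bit
  range.
* **Duplicate edges.** Raw interaction lists are symmetrized and
  deduplicated keeping the maximum weight — deterministic and
  independent of input order. The loader reports self-loop and
  duplicate counts under both the directed and undirected reading of
  the input, since public snapshots differ in whether they list each
  pair twice.
* **Density convention.** `graph_density()` uses the `2m/N²` convention
  (so `K_n` has density `(n−1)/n`, not 1) to match the summary-table
  convention used for the benchmark PPI datasets this framework
  targets.

# Open design decisions

* **Transductive by default.** The embedding is computed once on the
  full graph and then cross-validated, matching the framework's
  embed-once pipeline order. Held-out positives are thus visible to the
  embedder — an optimistic bias shared by this entire family of
  evaluations. `inductive = TRUE` re-runs fusion, coarsening and
  embedding per fold with the held-out positives removed; it is slower
  and yields lower, more honest numbers.
* **Negative sets per fold.** A fresh negative sample of the full
  positive-set size is drawn at each fold with a fold-derived seed; the
  held-out fold receives exactly as many negatives as it has positives
  and the rest train the classifier, keeping both sides class-balanced.
  Negatives are checked against the complete graph's edge set, not just
  the training folds.
* **Matching restricted to edges, clusters of size ≤ 2.** "Locally
  clustered" admits many rules; edge-restricted pairwise matching gives
  the provable `⌈n/2⌉` shrink bound per pass, deterministic behavior,
  and never merges disconnected nodes.
* **Coarse adjacency via the Galerkin product.** `HᵀAH` is the natural
  aggregation consistent with using `H` as the prolongation operator in
  refinement, and it conserves total weight exactly.
* **Per-stage seeding.** One user-facing seed deterministically derives
  per-stage seeds (fusion has no randomness; smoothing, walks, skip-gram,
  fold assignment and negative sampling each get their own stream), so
  any stage can be reproduced in isolation from the run manifest.

# Problem sizes used in the tests

The unit tests run on graphs of 3–60 nodes where dense oracles (full
similarity matrices, dense Laplacians and Galerkin products,
enumeration of complements and transition laws) are exact and cheap.
The end-to-end and acceptance tests use the 300-node fixture with the
full default parameters — large enough that coarsening, refinement and
cross-validation are all non-trivial, small enough that the whole suite
runs in about two minutes on a single CPU. The β comparison is paired
across 5 model seeds on the fixed fixture, testing non-inferiority of
`β = 0.1` against `β = 0` with a margin of half an AUC point.

# Known limitations

* Negative sampling assumes non-edges are true non-interactions; in
  incomplete interactomes some sampled negatives are undiscovered
  positives, deflating apparent precision on real data.
* The compartment filter needs external labels; when absent, sampling
  silently falls back to the unfiltered complement.
* Skip-gram training is single-threaded for determinism; embedding very
  large coarse graphs is compute-bound there.
* Only undirected simple graphs are supported — no directed interactions,
  multi-edges, or streaming of graphs larger than memory.
* Random-forest or naive-Bayes classifiers are not reimplemented; the
  classifier stage is pluggable at the feature-table level
  (`edge_features()` + any scorer) but only logistic regression ships.
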