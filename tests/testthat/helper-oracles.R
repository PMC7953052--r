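# Independent dense/brute-force oracles used to check the sparse
# implementations, plus tiny graph builders.

path_graph <- function(n) {
  lppi_graph(n, data.frame(u = 0:(n - 2L), v = 1:(n - 1L)))
}

complete_graph <- function(n) {
  p <- t(utils::combn(n, 2)) - 1L
  lppi_graph(n, data.frame(u = p[, 1], v = p[, 2]))
}

# dense symmetric adjacency from an lppi_graph
dense_adj <- function(g) {
  A <- matrix(0, g$n_nodes, g$n_nodes)
  e <- g$edges
  for (i in seq_len(nrow(e))) {
    A[e$u[i] + 1L, e$v[i] + 1L] <- e$w[i]
    A[e$v[i] + 1L, e$u[i] + 1L] <- e$w[i]
  }
  A
}

dense_laplacian <- function(g) {
  A <- dense_adj(g)
  diag(rowSums(A)) - A
}

rayleigh <- function(L, x) as.numeric(t(x) %*% L %*% x / sum(x * x))

# one-hot fine -> coarse matrix from an lppi_mapping
dense_H <- function(mapping) {
  H <- matrix(0, mapping$n_fine, mapping$n_coarse)
  H[cbind(seq_len(mapping$n_fine), mapping$assignment + 1L)] <- 1
  H
}

# brute-force full cosine-similarity matrix
dense_cosine <- function(x) {
  n <- nrow(x)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s[i, j] <- cosine_similarity(x[i, ], x[j, ])
  }
  s
}

# trapezoidal integration of the empirical ROC curve
trapezoid_auc <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  # step only at distinct thresholds to handle ties
  tp <- cumsum(lab == 1); fp <- cumsum(lab == 0)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  tpr <- c(0, tp[keep] / sum(lab == 1))
  fpr <- c(0, fp[keep] / sum(lab == 0))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# all non-edge unordered pairs of a graph, as sorted keys
complement_pairs <- function(g) {
  n <- g$n_nodes
  all <- t(utils::combn(n, 2)) - 1L
  keys <- all[, 1] * n + all[, 2]
  pos <- g$edges$u * n + g$edges$v
  all[!keys %in% pos, , drop = FALSE]
}

edge_key_set <- function(g) {
  paste(g$edges$u, g$edges$v, signif(g$edges$w, 12), sep = "/")
}
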