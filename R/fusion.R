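#' Cosine similarity between two attribute vectors
#'
#' `<a, b> / (||a|| ||b||)`, with the convention that the similarity is 0
#' when either vector is all-zero (a node with no recorded attributes
#' carries no similarity signal).
#'
#' @param a,b Numeric vectors of equal length.
#' @return A similarity score in `[-1, 1]` (in `[0, 1]` for non-negative
#'   attributes).
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    stop("cosine_similarity: vectors have different lengths", call. = FALSE)
  }
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Row-normalize an attribute matrix; all-zero rows stay zero.
row_normalize <- function(x) {
  nrm <- sqrt(rowSums(x * x))
  nz <- nrm > 0
  x[nz, ] <- x[nz, , drop = FALSE] / nrm[nz]
  x
}

#' Build the attribute-similarity graph
#'
#' Connects each node to its `knn_k` most cosine-similar other nodes, with
#' edge weight equal to the cosine similarity of the two attribute rows;
#' the k-nearest-neighbor graph is symmetrized by union. Candidate edges
#' with zero similarity are dropped, so all-zero attribute rows contribute
#' no edges. Ties in the similarity ranking are broken by ascending node
#' id, making the construction deterministic.
#'
#' The full `N x N` similarity computation is blocked over rows, so memory
#' stays at `O(block * N)`.
#'
#' @param attrs Numeric `N x F` attribute matrix (rows are nodes).
#' @param knn_k Number of neighbors per node; must be `< N`.
#' @param block Row-block size for the blocked similarity computation.
#' @return An [lppi_graph()] on the same `N` nodes.
#' @export
build_feature_graph <- function(attrs, knn_k = 10, block = 1024L) {
  attrs <- as.matrix(attrs)
  n <- nrow(attrs)
  if (knn_k >= n) {
    stop("knn_k must be smaller than the number of nodes", call. = FALSE)
  }
  if (knn_k < 1L) stop("knn_k must be >= 1", call. = FALSE)
  xn <- row_normalize(attrs)
  us <- vector("list", ceiling(n / block))
  vs <- us; ws <- us
  bi <- 0L
  for (start in seq(1L, n, by = block)) {
    end <- min(start + block - 1L, n)
    sim <- xn[start:end, , drop = FALSE] %*% t(xn)  # rows x N
    bi <- bi + 1L
    bu <- integer(0); bv <- integer(0); bw <- numeric(0)
    for (r in seq_len(end - start + 1L)) {
      i <- start + r - 1L
      s <- sim[r, ]
      s[i] <- -Inf                       # exclude self
      # top knn_k by similarity, ties by ascending node id
      ord <- order(-s, seq_len(n))[seq_len(knn_k)]
      keep <- s[ord] > 0
      ord <- ord[keep]
      if (length(ord)) {
        bu <- c(bu, rep(i - 1L, length(ord)))
        bv <- c(bv, ord - 1L)
        bw <- c(bw, s[ord])
      }
    }
    us[[bi]] <- bu; vs[[bi]] <- bv; ws[[bi]] <- bw
  }
  u <- unlist(us); v <- unlist(vs); w <- unlist(ws)
  if (length(u) == 0L) return(lppi_graph(n))
  # symmetrize by union; duplicate (u,v)/(v,u) entries carry the same
  # cosine weight, keep one
  key <- pair_key(u, v, n)
  first <- !duplicated(key)
  a <- pmin(u, v)[first]; b <- pmax(u, v)[first]
  lppi_graph(n, data.frame(u = a, v = b, w = w[first]))
}

#' Fuse a topology graph with an attribute-similarity graph
#'
#' Weighted sum of the two adjacency matrices,
#' `A_fusion = A_topo + beta * A_feat`, on a shared node set. With
#' `beta = 0` the fused graph equals the topology; similarity-only pairs
#' enter as new edges with weight `beta * similarity`.
#'
#' @param topo Topology graph ([lppi_graph()]).
#' @param feat Attribute-similarity graph on the same nodes (e.g. from
#'   [build_feature_graph()]).
#' @param beta Non-negative fusion weight; default 0.1.
#' @return The fused [lppi_graph()].
#' @export
fuse_graphs <- function(topo, feat, beta = 0.1) {
  stopifnot(inherits(topo, "lppi_graph"), inherits(feat, "lppi_graph"))
  if (topo$n_nodes != feat$n_nodes) {
    stop("fuse_graphs: node counts differ", call. = FALSE)
  }
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (beta == 0 || nrow(feat$edges) == 0L) {
    return(lppi_graph(topo$n_nodes, topo$edges,
                      node_names = topo$node_names))
  }
  n <- topo$n_nodes
  e <- rbind(topo$edges,
             data.frame(u = feat$edges$u, v = feat$edges$v,
                        w = beta * feat$edges$w))
  agg <- rowsum(e$w, pair_key(e$u, e$v, n))
  key <- as.numeric(rownames(agg))
  lppi_graph(n, data.frame(u = as.integer(key %/% n),
                           v = as.integer(key %% n),
                           w = agg[, 1L]),
             node_names = topo$node_names)
}
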