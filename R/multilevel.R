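#' Gauss-Seidel smoothed spectral test vectors
#'
#' Draws `t` standard-Gaussian random vectors and low-pass filters each
#' with `gs_iters` Gauss-Seidel sweeps on the homogeneous system
#' `L_sigma x = 0`, where `L_sigma = D + sigma I - A` is the graph
#' Laplacian regularized with a `sigma` self-loop on every node (this also
#' keeps isolated nodes well-defined). Smoothing damps the high-frequency
#' eigencomponents, so the surviving rows act as per-node low-frequency
#' spectral signatures. After smoothing, the per-vector mean is removed:
#' the constant vector is the trivial null mode of the Laplacian and would
#' otherwise dominate every affinity.
#'
#' @param g An [lppi_graph()].
#' @param t Number of test vectors (default 16).
#' @param gs_iters Number of Gauss-Seidel sweeps (default 2).
#' @param sigma Self-loop weight, `> 0` (default 1).
#' @param seed RNG seed; the result is deterministic given the seed.
#' @return An object of class `lppi_test_vectors`: list with `K`
#'   (`N x t` matrix of smoothed signatures), `t`, `gs_iters`, `seed`.
#' @export
smooth_test_vectors <- function(g, t = 16, gs_iters = 2, sigma = 1,
                                seed = 1) {
  stopifnot(inherits(g, "lppi_graph"))
  if (t < 1L) stop("t must be >= 1", call. = FALSE)
  if (gs_iters < 1L) stop("gs_iters must be >= 1", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  n <- g$n_nodes
  x0 <- with_seed(seed, matrix(stats::rnorm(n * t), nrow = n, ncol = t))
  csr <- graph_csr(g)
  K <- gauss_seidel_smooth(csr$ptr, csr$idx, csr$w, x0,
                           as.integer(gs_iters), as.numeric(sigma))
  K <- sweep(K, 2L, colMeans(K))
  structure(list(K = K, t = as.integer(t), gs_iters = as.integer(gs_iters),
                 seed = seed),
            class = "lppi_test_vectors")
}

# CSR adjacency (0-based) with neighbor lists sorted by id, for the
# compiled kernels.
graph_csr <- function(g) {
  n <- g$n_nodes
  e <- g$edges
  u <- c(e$u, e$v); v <- c(e$v, e$u); w <- c(e$w, e$w)
  o <- order(u, v)
  u <- u[o]; v <- v[o]; w <- w[o]
  ptr <- c(0L, cumsum(tabulate(u + 1L, nbins = n)))
  list(ptr = as.integer(ptr), idx = as.integer(v), w = as.numeric(w))
}

#' Spectral affinity between two nodes
#'
#' Squared cosine similarity of the two nodes' smoothed test-vector rows,
#' `a_pq = |<K_p, K_q>|^2 / (||K_p||^2 ||K_q||^2)`, in `[0, 1]`; 0 if a
#' row is all-zero. Node pairs with affinity near 1 respond identically to
#' the low-frequency modes of the graph and are candidates for merging.
#'
#' @param tv An `lppi_test_vectors` object (or a bare numeric matrix of
#'   row signatures).
#' @param p,q Distinct 0-based node ids.
#' @return The affinity in `[0, 1]`.
#' @export
spectral_affinity <- function(tv, p, q) {
  K <- if (inherits(tv, "lppi_test_vectors")) tv$K else as.matrix(tv)
  n <- nrow(K)
  if (p < 0 || q < 0 || p >= n || q >= n) {
    stop("node id out of range", call. = FALSE)
  }
  if (p == q) stop("spectral affinity requires two distinct nodes",
                   call. = FALSE)
  kp <- K[p + 1L, ]; kq <- K[q + 1L, ]
  np <- sum(kp * kp); nq <- sum(kq * kq)
  if (np == 0 || nq == 0) return(0)
  sum(kp * kq)^2 / (np * nq)
}

# Vectorized affinity for the edge list (u, v both 0-based vectors).
edge_affinities <- function(K, u, v) {
  ku <- K[u + 1L, , drop = FALSE]
  kv <- K[v + 1L, , drop = FALSE]
  nu <- rowSums(ku * ku); nv <- rowSums(kv * kv)
  ip <- rowSums(ku * kv)
  a <- numeric(length(u))
  ok <- nu > 0 & nv > 0
  a[ok] <- ip[ok]^2 / (nu[ok] * nv[ok])
  a
}

#' Coarsen a graph one level by spectral matching
#'
#' Greedy maximal matching on spectral affinity: edges are sorted by
#' affinity (descending; ties by lexicographic `(min id, max id)` order),
#' and an edge merges its endpoints when both are still unmatched, so
#' clusters have at most two fine nodes per pass. Unmatched nodes survive
#' as singletons. Coarse ids are assigned contiguously in order of the
#' smallest fine id in each cluster. The coarse adjacency is the Galerkin
#' product `H' A H` with the diagonal (internal cluster weight) zeroed —
#' self-loops carry no information for the random walks generated later,
#' while total weight including that diagonal is conserved.
#'
#' @param g An [lppi_graph()] with at least one node.
#' @param tv Smoothed test vectors for `g` (see [smooth_test_vectors()]).
#' @return List with `graph` (coarse [lppi_graph()]) and `mapping` (an
#'   `lppi_mapping`: integer vector `assignment` of length `n_fine` giving
#'   each fine node's 0-based coarse id, plus `n_fine`, `n_coarse`).
#' @export
coarsen_once <- function(g, tv) {
  stopifnot(inherits(g, "lppi_graph"))
  K <- if (inherits(tv, "lppi_test_vectors")) tv$K else as.matrix(tv)
  if (nrow(K) != g$n_nodes) stop("test vectors do not match graph size",
                                 call. = FALSE)
  n <- g$n_nodes
  e <- g$edges
  match_of <- rep(NA_integer_, n)          # partner fine id or NA
  if (nrow(e)) {
    a <- edge_affinities(K, e$u, e$v)
    o <- order(-a, e$u, e$v)
    matched <- logical(n)
    for (i in o) {
      u <- e$u[i]; v <- e$v[i]
      if (!matched[u + 1L] && !matched[v + 1L]) {
        matched[u + 1L] <- TRUE; matched[v + 1L] <- TRUE
        match_of[u + 1L] <- v; match_of[v + 1L] <- u
      }
    }
  }
  # cluster representative = min(fine id, partner); coarse ids contiguous
  # by ascending representative
  rep_id <- pmin(seq_len(n) - 1L, ifelse(is.na(match_of), n, match_of))
  reps <- sort(unique(rep_id))
  assignment <- match(rep_id, reps) - 1L
  n_coarse <- length(reps)
  mapping <- new_mapping(assignment, n, n_coarse)
  list(graph = galerkin_graph(g, mapping), mapping = mapping)
}

new_mapping <- function(assignment, n_fine, n_coarse) {
  structure(list(assignment = as.integer(assignment),
                 n_fine = as.integer(n_fine),
                 n_coarse = as.integer(n_coarse)),
            class = "lppi_mapping")
}

# Coarse graph H' A H with zeroed diagonal; off-diagonal weights aggregate
# all fine edges crossing between the two clusters.
galerkin_graph <- function(g, mapping) {
  e <- g$edges
  cu <- mapping$assignment[e$u + 1L]
  cv <- mapping$assignment[e$v + 1L]
  keep <- cu != cv
  nc <- mapping$n_coarse
  if (!any(keep)) return(lppi_graph(nc))
  agg <- rowsum(e$w[keep], pair_key(cu[keep], cv[keep], nc))
  key <- as.numeric(rownames(agg))
  lppi_graph(nc, data.frame(u = as.integer(key %/% nc),
                            v = as.integer(key %% nc),
                            w = agg[, 1L]))
}

#' Build a spectral coarsening hierarchy
#'
#' Applies [smooth_test_vectors()] + [coarsen_once()] `level` times,
#' recomputing test vectors at each level with a level-derived seed.
#' Because matching merges at most pairs, each pass removes at most half
#' the nodes. Coarsening stops early when a pass shrinks the graph by less
#' than 2% (e.g. an edgeless graph cannot shrink at all); the achieved
#' depth is recorded.
#'
#' @param g The finest-level [lppi_graph()].
#' @param level Requested number of coarsening levels `l >= 0`.
#' @param t,gs_iters,sigma Passed to [smooth_test_vectors()].
#' @param seed Base seed; level `i` uses `seed + i`.
#' @return An object of class `lppi_hierarchy`: `levels` (list of graphs,
#'   finest first), `mappings` (list of `lppi_mapping`, one per coarsening
#'   step), `depth` (achieved level count).
#' @export
build_hierarchy <- function(g, level = 1, t = 16, gs_iters = 2, sigma = 1,
                            seed = 1) {
  stopifnot(inherits(g, "lppi_graph"))
  if (level < 0L) stop("level must be >= 0", call. = FALSE)
  levels <- list(g)
  mappings <- list()
  cur <- g
  i <- 0L
  while (i < level) {
    tv <- smooth_test_vectors(cur, t = t, gs_iters = gs_iters,
                              sigma = sigma, seed = seed + i)
    step <- coarsen_once(cur, tv)
    if (step$graph$n_nodes > 0.98 * cur$n_nodes) break
    i <- i + 1L
    cur <- step$graph
    levels[[i + 1L]] <- cur
    mappings[[i]] <- step$mapping
  }
  structure(list(levels = levels, mappings = mappings, depth = i),
            class = "lppi_hierarchy")
}

#' @export
print.lppi_hierarchy <- function(x, ...) {
  cat(sprintf("<lppi_hierarchy> depth %d\n", x$depth))
  for (i in seq_along(x$levels)) {
    g <- x$levels[[i]]
    cat(sprintf("  level %d: %d nodes, %d edges\n", i - 1L, g$n_nodes,
                nrow(g$edges)))
  }
  invisible(x)
}

# sigma-self-looped symmetric-normalized smoothing operator applied k
# times: E <- (D~^{-1/2} (A + sigma I) D~^{-1/2})^k E with D~ = D + sigma I.
laplacian_smooth <- function(g, E, k, sigma) {
  if (k == 0L) return(E)
  A <- as_adjacency(g)
  s <- 1 / sqrt(node_degrees(g) + sigma)
  for (i in seq_len(k)) {
    Es <- E * s
    E <- as.matrix(A %*% Es) * s + (sigma * s * s) * E
  }
  E
}

#' Refine a coarse embedding one level up
#'
#' Prolongs the coarse embedding to the fine graph by copying each fine
#' node its cluster's row (`H E_coarse`), then applies `k` rounds of the
#' sigma-self-looped symmetric-normalized adjacency
#' `D~^{-1/2} (A + sigma I) D~^{-1/2}` of the fine graph, a Laplacian-
#' smoothing step that adapts the copied rows to the fine topology. With
#' `k = 0` the result is the pure projection.
#'
#' @param e_coarse Numeric matrix, one row per coarse node.
#' @param mapping The `lppi_mapping` from the fine to the coarse level.
#' @param g_fine The fine-level [lppi_graph()].
#' @param k Smoothing power (default 2).
#' @param sigma Self-loop weight `> 0` (default 1).
#' @return Numeric matrix with `g_fine$n_nodes` rows.
#' @export
refine_level <- function(e_coarse, mapping, g_fine, k = 2, sigma = 1) {
  e_coarse <- as.matrix(e_coarse)
  if (nrow(e_coarse) != mapping$n_coarse) {
    stop("embedding rows do not match coarse node count", call. = FALSE)
  }
  if (mapping$n_fine != g_fine$n_nodes) {
    stop("mapping does not match fine graph", call. = FALSE)
  }
  if (k < 0L) stop("k must be >= 0", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  E <- e_coarse[mapping$assignment + 1L, , drop = FALSE]
  laplacian_smooth(g_fine, E, as.integer(k), sigma)
}

#' Refine the coarsest embedding through the whole hierarchy
#'
#' Applies [refine_level()] from the coarsest level down to level 0 and
#' returns the full-resolution `N x d` embedding.
#'
#' @param hier An `lppi_hierarchy` from [build_hierarchy()].
#' @param e_coarsest Embedding of the coarsest level (rows = coarsest node
#'   count).
#' @param k,sigma Passed to [refine_level()].
#' @return Numeric matrix with as many rows as the original graph.
#' @export
refine_all <- function(hier, e_coarsest, k = 2, sigma = 1) {
  stopifnot(inherits(hier, "lppi_hierarchy"))
  E <- as.matrix(e_coarsest)
  if (nrow(E) != hier$levels[[hier$depth + 1L]]$n_nodes) {
    stop("embedding rows do not match coarsest node count", call. = FALSE)
  }
  for (i in rev(seq_len(hier$depth))) {
    E <- refine_level(E, hier$mappings[[i]], hier$levels[[i]],
                      k = k, sigma = sigma)
  }
  E
}
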