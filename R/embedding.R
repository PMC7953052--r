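#' Node2vec transition bias factor
#'
#' The unnormalized bias applied to a candidate next node at hop distance
#' `d_prev` from the previous node of the walk: `1/p` if the candidate is
#' the previous node itself (`d_prev = 0`, return step), `1` if it is a
#' neighbor of the previous node (`d_prev = 1`), and `1/q` otherwise
#' (`d_prev = 2`, outward step). `q < 1` favors outward (DFS-like)
#' exploration, `q > 1` keeps the walk local (BFS-like).
#'
#' @param d_prev Hop distance from the previous node: 0, 1 or 2.
#' @param p Return parameter, `> 0`.
#' @param q In-out parameter, `> 0`.
#' @return The bias factor.
#' @examples
#' node2vec_alpha(1, p = 1, q = 0.5)  # 1
#' node2vec_alpha(2, p = 1, q = 0.5)  # 2
#' @export
node2vec_alpha <- function(d_prev, p = 1, q = 0.5) {
  if (p <= 0 || q <= 0) stop("p and q must be > 0", call. = FALSE)
  if (!d_prev %in% c(0, 1, 2)) {
    stop("d_prev must be 0, 1 or 2", call. = FALSE)
  }
  switch(as.character(d_prev), "0" = 1 / p, "1" = 1, "2" = 1 / q)
}

#' Generate a random-walk corpus
#'
#' Generates `num_walks` walks of length `walk_length` rooted at every
#' node, in per-round shuffled start order. `"deepwalk"` walks step to a
#' neighbor with probability proportional to edge weight; `"node2vec"`
#' walks additionally multiply each candidate's weight by the bias
#' [node2vec_alpha()] given the previous node (second-order walk). At
#' `p = q = 1` the two transition laws coincide. Isolated nodes emit the
#' singleton walk `c(v)`.
#'
#' @param g An [lppi_graph()].
#' @param method `"deepwalk"` or `"node2vec"`.
#' @param num_walks Walks per node (default 10).
#' @param walk_length Maximum walk length in nodes (default 80).
#' @param p,q Node2vec return and in-out parameters (defaults 1.0, 0.5).
#' @param seed RNG seed; the corpus is reproducible token-for-token.
#' @return A list of integer vectors of 0-based node ids, of length
#'   `num_walks * n_nodes`.
#' @export
generate_walks <- function(g, method = c("deepwalk", "node2vec"),
                           num_walks = 10, walk_length = 80,
                           p = 1.0, q = 0.5, seed = 1) {
  stopifnot(inherits(g, "lppi_graph"))
  method <- match.arg(method)
  if (num_walks < 1L) stop("num_walks must be >= 1", call. = FALSE)
  if (walk_length < 1L) stop("walk_length must be >= 1", call. = FALSE)
  if (p <= 0 || q <= 0) stop("p and q must be > 0", call. = FALSE)
  if (g$n_nodes == 0L) return(list())
  csr <- graph_csr(g)
  walk_corpus(csr$ptr, csr$idx, csr$w, g$n_nodes,
              as.integer(num_walks), as.integer(walk_length),
              if (method == "node2vec") 1L else 0L,
              as.numeric(p), as.numeric(q), as.integer(seed))
}

#' Train skip-gram node embeddings on a walk corpus
#'
#' Skip-gram with negative sampling (the word2vec objective) over the walk
#' corpus: each node within a reduced window of a center node is trained
#' to predict it against `negative` unigram^0.75-sampled negatives, with a
#' linearly decaying learning rate. Runs single-threaded and is
#' deterministic given the seed. Nodes that never appear in the corpus get
#' zero rows.
#'
#' @param corpus List of integer walks (0-based ids), e.g. from
#'   [generate_walks()].
#' @param n_nodes Number of nodes (rows of the result).
#' @param dim Embedding dimension (default 128).
#' @param window Context window half-width (default 10).
#' @param epochs Passes over the corpus (default 5).
#' @param negative Negative samples per context pair (default 5).
#' @param alpha Initial learning rate (default 0.025).
#' @param seed RNG seed.
#' @return A numeric `n_nodes x dim` embedding matrix.
#' @export
train_skipgram <- function(corpus, n_nodes, dim = 128, window = 10,
                           epochs = 5, negative = 5, alpha = 0.025,
                           seed = 1) {
  if (!length(corpus)) stop("empty walk corpus", call. = FALSE)
  if (dim < 1L) stop("dim must be >= 1", call. = FALSE)
  sgns_train(corpus, as.integer(n_nodes), as.integer(dim),
             as.integer(window), as.integer(epochs), as.integer(negative),
             as.numeric(alpha), as.integer(seed))
}

#' Embed a graph with random walks + skip-gram
#'
#' Convenience wrapper chaining [generate_walks()] and [train_skipgram()].
#'
#' @inheritParams generate_walks
#' @inheritParams train_skipgram
#' @return A numeric `n_nodes x dim` embedding matrix.
#' @export
embed_graph <- function(g, method = c("deepwalk", "node2vec"),
                        dim = 128, num_walks = 10, walk_length = 80,
                        p = 1.0, q = 0.5, window = 10, epochs = 5,
                        negative = 5, seed = 1) {
  corpus <- generate_walks(g, method = method, num_walks = num_walks,
                           walk_length = walk_length, p = p, q = q,
                           seed = seed)
  train_skipgram(corpus, g$n_nodes, dim = dim, window = window,
                 epochs = epochs, negative = negative, seed = seed + 1L)
}
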