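#' Construct an undirected weighted graph
#'
#' The package's graph container: an undirected, weighted, simple graph over
#' contiguous 0-based integer node ids. Edges are stored once with
#' `u < v`; self-loops and duplicates are rejected (use [read_edge_list()]
#' for raw edge lists that still contain them).
#'
#' @param n_nodes Number of nodes; node ids are `0 .. n_nodes - 1`.
#' @param edges Data frame with integer columns `u`, `v` and numeric `w`
#'   (non-negative finite weights). A missing `w` column defaults to 1.
#' @param node_names Optional character vector of length `n_nodes` giving
#'   the original (external) node identifiers.
#'
#' @return An object of class `lppi_graph` with elements `n_nodes`,
#'   `edges` (canonicalized, `u < v`, ordered) and optionally `node_names`.
#' @examples
#' g <- lppi_graph(3, data.frame(u = c(0, 1), v = c(1, 2)))
#' graph_density(g)
#' @export
lppi_graph <- function(n_nodes, edges = NULL, node_names = NULL) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 0L) {
    stop("n_nodes must be a non-negative integer", call. = FALSE)
  }
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(u = integer(), v = integer(), w = numeric())
  } else {
    if (!all(c("u", "v") %in% names(edges))) {
      stop("edges must have columns 'u' and 'v'", call. = FALSE)
    }
    if (is.null(edges$w)) edges$w <- 1
    u <- as.integer(edges$u); v <- as.integer(edges$v); w <- as.numeric(edges$w)
    if (anyNA(u) || anyNA(v) || any(u < 0L) || any(v < 0L) ||
        any(u >= n_nodes) || any(v >= n_nodes)) {
      stop("edge endpoints must be integers in [0, n_nodes)", call. = FALSE)
    }
    if (anyNA(w) || any(!is.finite(w)) || any(w < 0)) {
      stop("edge weights must be finite and >= 0", call. = FALSE)
    }
    if (any(u == v)) stop("self-loops are not allowed", call. = FALSE)
    a <- pmin(u, v); b <- pmax(u, v)
    if (anyDuplicated(a * as.numeric(n_nodes) + b)) {
      stop("duplicate edges are not allowed", call. = FALSE)
    }
    o <- order(a, b)
    edges <- data.frame(u = a[o], v = b[o], w = w[o])
  }
  if (!is.null(node_names) && length(node_names) != n_nodes) {
    stop("node_names must have length n_nodes", call. = FALSE)
  }
  structure(
    list(n_nodes = n_nodes, edges = edges, node_names = node_names),
    class = "lppi_graph"
  )
}

#' @export
print.lppi_graph <- function(x, ...) {
  cat(sprintf("<lppi_graph> %d nodes, %d edges, density %.4g\n",
              x$n_nodes, nrow(x$edges),
              if (x$n_nodes > 0) graph_density(x) else NA_real_))
  invisible(x)
}

n_edges <- function(g) nrow(g$edges)

#' Sparse adjacency matrix of a graph
#'
#' @param g An [lppi_graph()].
#' @return A symmetric `n x n` `dgCMatrix` with zero diagonal.
#' @export
as_adjacency <- function(g) {
  stopifnot(inherits(g, "lppi_graph"))
  n <- g$n_nodes
  e <- g$edges
  Matrix::sparseMatrix(
    i = c(e$u, e$v) + 1L, j = c(e$v, e$u) + 1L, x = c(e$w, e$w),
    dims = c(n, n)
  )
}

# Weighted degree vector (length n_nodes).
node_degrees <- function(g) {
  d <- numeric(g$n_nodes)
  e <- g$edges
  if (nrow(e)) {
    tab <- rowsum(c(e$w, e$w), c(e$u, e$v))
    d[as.integer(rownames(tab)) + 1L] <- tab[, 1L]
  }
  d
}

#' Read an undirected weighted edge list from TSV
#'
#' Reads lines of the form `u<TAB>v[<TAB>w]` (missing weight defaults to
#' 1.0; lines starting with `#` are ignored), removes self-interactions,
#' collapses duplicate interactions — `(u,v)` and `(v,u)` are the same
#' edge, duplicates keep the maximum weight — and returns a simple
#' undirected graph. Node ids may be non-negative integers (used directly;
#' `n_nodes` is `max(id) + 1` unless declared larger) or arbitrary strings
#' (mapped to `0..k-1` in sorted order, kept in `node_names`).
#'
#' A cleaning report is attached as `attr(g, "report")`: raw pair count,
#' removed self-loops, collapsed duplicate count under both the
#' directed-pair and the undirected-unique reading of the input.
#'
#' @param path Path to the TSV file.
#' @param n_nodes Optional declared node count (must cover all ids seen).
#' @param deduplicate Collapse duplicate edges (default `TRUE`); with
#'   `FALSE` duplicates still collapse (the container is simple) but an
#'   error is raised if any were present.
#' @return An [lppi_graph()] with attribute `report`.
#' @export
read_edge_list <- function(path, n_nodes = NULL, deduplicate = TRUE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    n <- as.integer(n_nodes %||% 0L)
    g <- lppi_graph(n)
    attr(g, "report") <- list(raw_pairs = 0L, self_loops = 0L,
                              duplicate_directed = 0L,
                              duplicate_undirected = 0L)
    return(g)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2L)
  if (length(bad)) {
    stop(sprintf("malformed edge line %d: expected 'u\\tv[\\tw]', got %s",
                 lineno[bad[1L]], shQuote(lines[bad[1L]])), call. = FALSE)
  }
  us <- vapply(parts, `[`, "", 1L)
  vs <- vapply(parts, `[`, "", 2L)
  ws <- rep(1.0, length(parts))
  has_w <- nf >= 3L
  if (any(has_w)) {
    wtxt <- vapply(parts[has_w], `[`, "", 3L)
    wval <- suppressWarnings(as.numeric(wtxt))
    if (anyNA(wval)) {
      i <- which(has_w)[which(is.na(wval))[1L]]
      stop(sprintf("malformed weight on line %d: %s",
                   lineno[i], shQuote(lines[i])), call. = FALSE)
    }
    ws[has_w] <- wval
  }
  if (any(ws < 0)) {
    i <- which(ws < 0)[1L]
    stop(sprintf("negative weight on line %d", lineno[i]), call. = FALSE)
  }

  ui <- suppressWarnings(as.integer(us))
  vi <- suppressWarnings(as.integer(vs))
  node_names <- NULL
  if (anyNA(ui) || anyNA(vi) || any(ui < 0L, na.rm = TRUE) ||
      any(vi < 0L, na.rm = TRUE)) {
    ids <- sort(unique(c(us, vs)))
    ui <- match(us, ids) - 1L
    vi <- match(vs, ids) - 1L
    node_names <- ids
  }
  n <- max(ui, vi) + 1L
  if (!is.null(n_nodes)) {
    if (n_nodes < n) stop("declared n_nodes smaller than largest id + 1",
                          call. = FALSE)
    n <- as.integer(n_nodes)
    if (!is.null(node_names)) node_names <- c(node_names,
                                              rep(NA_character_,
                                                  n - length(node_names)))
  }

  raw <- length(ui)
  self <- ui == vi
  n_self <- sum(self)
  ui <- ui[!self]; vi <- vi[!self]; ws <- ws[!self]
  dup_directed <- sum(duplicated(as.numeric(ui) * n + vi))
  key <- pair_key(ui, vi, n)
  dup_undirected <- sum(duplicated(key))
  if (!deduplicate && dup_undirected > 0L) {
    stop(sprintf("%d duplicate edges present and deduplicate = FALSE",
                 dup_undirected), call. = FALSE)
  }
  if (dup_undirected > 0L) {
    # collapse keeping the maximum weight: deterministic, order-independent
    o <- order(key, -ws)
    first <- !duplicated(key[o])
    ui <- ui[o][first]; vi <- vi[o][first]; ws <- ws[o][first]
  }
  g <- lppi_graph(n, data.frame(u = ui, v = vi, w = ws),
                  node_names = node_names)
  attr(g, "report") <- list(raw_pairs = raw, self_loops = n_self,
                            duplicate_directed = dup_directed,
                            duplicate_undirected = dup_undirected)
  g
}

#' Write a graph as an edge-list TSV
#'
#' Inverse of [read_edge_list()]: writes one `u\tv\tw` line per edge with
#' `u < v`.
#'
#' @param g An [lppi_graph()].
#' @param path Output path.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "lppi_graph"))
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Graph density
#'
#' Density of an undirected graph defined as `2 * #links / #nodes^2`.
#' Note the `N^2` denominator (not `N (N - 1)`): this is the convention
#' used for the interaction-network summary statistics this package
#' reports, so a complete graph has density `(n - 1) / n`.
#'
#' @param g An [lppi_graph()] with at least one node.
#' @return Density as a fraction in `[0, 1)`.
#' @export
graph_density <- function(g) {
  stopifnot(inherits(g, "lppi_graph"))
  if (g$n_nodes < 1L) stop("density undefined for a graph with zero nodes",
                           call. = FALSE)
  2 * nrow(g$edges) / as.numeric(g$n_nodes)^2
}

#' Load a node-attribute matrix
#'
#' Reads an `N x F` matrix of non-negative node attributes, either in
#' MatrixMarket coordinate format (detected from the `%%MatrixMarket`
#' banner) or as a dense TSV with one row per node. Typical attributes are
#' binary gene-set membership indicators (positional gene sets, sequence
#' motif gene sets, immunological signatures).
#'
#' @param path Path to an `.mtx` file or dense TSV.
#' @param n_nodes Expected row count (graph node count).
#' @return A dense numeric matrix with `n_nodes` rows.
#' @export
read_attributes <- function(path, n_nodes) {
  first <- readLines(path, n = 1L)
  if (grepl("^%%MatrixMarket", first)) {
    m <- as.matrix(Matrix::readMM(path))
  } else {
    m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                     comment.char = "#"))
  }
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  if (nrow(m) != n_nodes) {
    stop(sprintf("attribute matrix has %d rows but graph has %d nodes",
                 nrow(m), n_nodes), call. = FALSE)
  }
  if (anyNA(m) || any(!is.finite(m))) {
    stop("attribute matrix contains NaN/Inf entries", call. = FALSE)
  }
  if (any(m < 0)) stop("attribute values must be non-negative", call. = FALSE)
  m
}

#' Load cellular-compartment labels
#'
#' Reads a TSV `node<TAB>compartment` mapping used to exclude same-
#' compartment pairs during negative sampling.
#'
#' @param path Path to the TSV file.
#' @param n_nodes Graph node count; every node must be labeled.
#' @return An integer-indexed character vector of length `n_nodes`
#'   (position `i + 1` holds node `i`'s compartment).
#' @export
read_compartments <- function(path, n_nodes) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#",
                           colClasses = c("integer", "character"))
  comp <- rep(NA_character_, n_nodes)
  if (any(tab[[1]] < 0L | tab[[1]] >= n_nodes)) {
    stop("compartment file references node id outside [0, n_nodes)",
         call. = FALSE)
  }
  comp[tab[[1]] + 1L] <- tab[[2]]
  if (anyNA(comp)) {
    stop("compartment labels must cover all nodes or be absent entirely",
         call. = FALSE)
  }
  comp
}
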