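#' Fit the multi-level link-prediction model
#'
#' Runs the whole framework on an attributed interaction network and
#' cross-validates link prediction:
#'
#' 1. **Fusion** — the topology adjacency is fused with a k-nearest-
#'    neighbor cosine-similarity graph over the node attributes,
#'    `A_fusion = A_topo + beta * A_feat` ([build_feature_graph()],
#'    [fuse_graphs()]). With `beta = 0` or no attributes this stage is the
#'    identity.
#' 2. **Spectral coarsening** — the fused graph is coarsened `level`
#'    times by merging node pairs with high spectral affinity
#'    ([build_hierarchy()]). With `level = 0` the raw graph is embedded.
#' 3. **Embedding** — the coarsest graph is embedded with weighted random
#'    walks (DeepWalk or node2vec) and skip-gram with negative sampling
#'    ([embed_graph()]).
#' 4. **Refinement** — the coarse embedding is prolonged and Laplacian-
#'    smoothed back to full resolution ([refine_all()]).
#' 5. **Classification** — protein pairs are scored by L2-regularized
#'    logistic regression on symmetric pair features under `folds`-fold
#'    cross-validation with per-fold negative sampling
#'    ([cross_validate()]); a final classifier is fitted on all positives
#'    plus one sampled negative set for use with [predict.lppi()].
#'
#' @param graph An [lppi_graph()] of observed interactions, or a path to
#'   an edge-list TSV readable by [read_edge_list()].
#' @param attributes Optional `N x F` node-attribute matrix (or a path
#'   readable by [read_attributes()]); `NULL` disables fusion.
#' @param compartments Optional per-node compartment labels (or a path
#'   readable by [read_compartments()]) used to restrict negative
#'   sampling to cross-compartment pairs.
#' @param beta Fusion weight for the attribute-similarity graph
#'   (default 0.1).
#' @param knn_k Neighbors in the attribute-similarity graph (default 10).
#' @param level Coarsening levels `l` (default 1).
#' @param t_vectors,gs_iters,sigma Spectral-coarsening controls, see
#'   [smooth_test_vectors()].
#' @param method Embedding method, `"deepwalk"` (default) or
#'   `"node2vec"`.
#' @param dim Embedding dimension (default 128).
#' @param num_walks,walk_length Walks per node and walk length
#'   (defaults 10 and 80).
#' @param p,q Node2vec bias parameters (defaults 1.0 and 0.5; ignored by
#'   DeepWalk).
#' @param window,epochs,negative Skip-gram controls, see
#'   [train_skipgram()].
#' @param power Refinement smoothing power `k` (default 2).
#' @param operator Pair-feature operator (default `"hadamard"`), see
#'   [edge_features()].
#' @param folds Cross-validation folds (default 5).
#' @param inductive If `TRUE`, re-run fusion/coarsening/embedding per fold
#'   with the held-out positives removed (honest but slower evaluation);
#'   default `FALSE` embeds once on the full graph, matching the
#'   embed-once-then-cross-validate pipeline order (optimistically
#'   biased, see the vignette).
#' @param seed Global seed; all stage seeds derive from it.
#' @param verbose Print per-stage progress (default `FALSE`).
#'
#' @return An object of class `lppi` with components `graph`, `fused`,
#'   `hierarchy`, `embedding` (`N x dim`), `cv` (an `lppi_cv`),
#'   `classifier`, `config` and `call`. Methods: [print.lppi()],
#'   [summary.lppi()], [coef.lppi()], [predict.lppi()], [plot.lppi()].
#' @examples
#' \donttest{
#' fx <- lppi_fixture(seed = 7)
#' fit <- lppi(fx$graph, fx$attributes, fx$compartments,
#'             dim = 32, epochs = 2, seed = 1)
#' fit
#' }
#' @export
lppi <- function(graph, attributes = NULL, compartments = NULL,
                 beta = 0.1, knn_k = 10, level = 1,
                 t_vectors = 16, gs_iters = 2, sigma = 1,
                 method = c("deepwalk", "node2vec"),
                 dim = 128, num_walks = 10, walk_length = 80,
                 p = 1.0, q = 0.5, window = 10, epochs = 5, negative = 5,
                 power = 2, operator = "hadamard", folds = 5,
                 inductive = FALSE, seed = 1, verbose = FALSE) {
  method <- match.arg(method)
  cl <- match.call()
  if (is.character(graph)) graph <- read_edge_list(graph)
  stopifnot(inherits(graph, "lppi_graph"))
  if (is.character(attributes) && length(attributes) == 1L) {
    attributes <- read_attributes(attributes, graph$n_nodes)
  }
  # a length-1 character is a file path; a longer vector is the labels
  if (is.character(compartments) && length(compartments) == 1L) {
    compartments <- read_compartments(compartments, graph$n_nodes)
  }
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  config <- list(beta = beta, knn_k = knn_k, level = level,
                 t_vectors = t_vectors, gs_iters = gs_iters, sigma = sigma,
                 method = method, dim = dim, num_walks = num_walks,
                 walk_length = walk_length, p = p, q = q, window = window,
                 epochs = epochs, negative = negative, power = power,
                 operator = operator, folds = folds,
                 inductive = inductive, seed = seed)

  # Stages 1-4 as a closure so inductive CV can re-run them per fold on
  # the fold-reduced graph.
  embed_pipeline <- function(g) {
    fused <- g
    if (!is.null(attributes) && beta > 0) {
      feat <- build_feature_graph(attributes, knn_k = knn_k)
      fused <- fuse_graphs(g, feat, beta = beta)
      say("fusion: %d topology + %d similarity edges -> %d fused",
          n_edges(g), n_edges(feat), n_edges(fused))
    }
    hier <- build_hierarchy(fused, level = level, t = t_vectors,
                            gs_iters = gs_iters, sigma = sigma,
                            seed = stage_seed(seed, 2L))
    coarsest <- hier$levels[[hier$depth + 1L]]
    say("coarsening: depth %d, %d -> %d nodes", hier$depth, g$n_nodes,
        coarsest$n_nodes)
    e_coarse <- embed_graph(coarsest, method = method, dim = dim,
                            num_walks = num_walks,
                            walk_length = walk_length, p = p, q = q,
                            window = window, epochs = epochs,
                            negative = negative,
                            seed = stage_seed(seed, 3L))
    emb <- refine_all(hier, e_coarse, k = power, sigma = sigma)
    say("embedding: %d x %d refined to %d x %d", nrow(e_coarse), dim,
        nrow(emb), ncol(emb))
    list(fused = fused, hierarchy = hier, embedding = emb)
  }

  full <- embed_pipeline(graph)
  cv <- cross_validate(
    graph,
    embedding = if (inductive) {
      function(g_train) embed_pipeline(g_train)$embedding
    } else {
      full$embedding
    },
    compartments = compartments, operator = operator, folds = folds,
    seed = stage_seed(seed, 5L)
  )
  say("cross-validation: mean acc %.4f, mean auc %.4f",
      cv$means[["acc"]], cv$means[["auc"]])

  # final scorer on all positives + one fresh negative set
  pos <- graph$edges[, c("u", "v")]
  neg <- sample_negatives(graph, nrow(pos), compartments = compartments,
                          seed = stage_seed(seed, 6L))
  xall <- edge_features(full$embedding, rbind(pos, neg), operator)
  yall <- rep(c(1L, 0L), c(nrow(pos), nrow(neg)))
  clf <- train_link_classifier(xall, yall)

  structure(list(graph = graph, fused = full$fused,
                 hierarchy = full$hierarchy, embedding = full$embedding,
                 cv = cv, classifier = clf, compartments = compartments,
                 config = config, call = cl),
            class = "lppi")
}

#' @export
print.lppi <- function(x, ...) {
  h <- x$hierarchy
  coarsest <- h$levels[[h$depth + 1L]]
  cat("Multi-level PPI link-prediction fit\n")
  cat(sprintf("  graph: %d nodes, %d edges (density %.4g)\n",
              x$graph$n_nodes, n_edges(x$graph), graph_density(x$graph)))
  cat(sprintf("  fused graph: %d edges (beta = %g)\n", n_edges(x$fused),
              x$config$beta))
  cat(sprintf("  coarsening: level %d, coarsest graph %d nodes\n",
              h$depth, coarsest$n_nodes))
  cat(sprintf("  embedding: %s, %d dimensions\n", x$config$method,
              x$config$dim))
  cat(sprintf("  %d-fold CV means: acc %.4f  sen %.4f  pre %.4f  mcc %.4f  auc %.4f\n",
              x$config$folds, x$cv$means[["acc"]], x$cv$means[["sen"]],
              x$cv$means[["pre"]], x$cv$means[["mcc"]],
              x$cv$means[["auc"]]))
  invisible(x)
}

#' Summarize a fitted link-prediction model
#'
#' @param object An `lppi` fit.
#' @param ... Unused.
#' @return An object of class `summary.lppi`: the per-fold metric table,
#'   fold means, and the hierarchy shrink profile.
#' @export
summary.lppi <- function(object, ...) {
  h <- object$hierarchy
  shrink <- data.frame(
    level = seq_along(h$levels) - 1L,
    nodes = vapply(h$levels, function(g) g$n_nodes, 0L),
    edges = vapply(h$levels, n_edges, 0L)
  )
  structure(list(report = object$cv$report, means = object$cv$means,
                 shrink = shrink, config = object$config),
            class = "summary.lppi")
}

#' @export
print.summary.lppi <- function(x, digits = 4, ...) {
  cat("Per-fold cross-validation metrics:\n")
  print(cbind(x$report[, c("fold", "tp", "tn", "fp", "fn")],
              round(x$report[, c("acc", "sen", "pre", "mcc", "auc")],
                    digits)),
        row.names = FALSE)
  cat("\nFold means:\n")
  print(round(x$means, digits))
  cat("\nCoarsening hierarchy:\n")
  print(x$shrink, row.names = FALSE)
  invisible(x)
}

#' @export
coef.lppi <- function(object, ...) {
  cf <- stats::coef(object$classifier$fit, s = object$classifier$lambda)
  stats::setNames(as.numeric(cf), rownames(cf))
}

#' Predict interaction probability for new protein pairs
#'
#' Scores unordered node pairs with the final classifier fitted on the
#' full graph, using the refined full-resolution embedding.
#'
#' @param object An `lppi` fit.
#' @param pairs Data frame with 0-based integer columns `u`, `v`.
#' @param type `"response"` for probabilities (default) or `"class"` for
#'   0/1 labels at the 0.5 threshold.
#' @param ... Unused.
#' @return Numeric (or integer, for `"class"`) vector, one value per
#'   pair.
#' @export
predict.lppi <- function(object, pairs, type = c("response", "class"),
                         ...) {
  type <- match.arg(type)
  x <- edge_features(object$embedding, pairs, object$config$operator)
  pr <- predict(object$classifier, x)
  if (type == "class") as.integer(pr >= 0.5) else pr
}

#' ROC curve of the cross-validated fit
#'
#' Plots the pooled out-of-fold ROC curve and reports the rank-based AUC
#' in the legend.
#'
#' @param x An `lppi` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lppi <- function(x, ...) {
  sc <- x$cv$scores; lb <- x$cv$labels
  o <- order(sc, decreasing = TRUE)
  tpr <- cumsum(lb[o] == 1L) / sum(lb == 1L)
  fpr <- cumsum(lb[o] == 0L) / sum(lb == 0L)
  graphics::plot(c(0, fpr, 1), c(0, tpr, 1), type = "l",
                 xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = "Pooled out-of-fold ROC", ...)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright",
                   sprintf("AUC = %.4f", rank_auc(sc, lb)), bty = "n")
  invisible(x)
}
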