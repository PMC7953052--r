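#' Sample negative (non-interacting) protein pairs
#'
#' Draws `n` unordered node pairs uniformly without replacement from the
#' complement of the graph's edge set — candidate non-interactions. When
#' compartment labels are supplied, pairs whose endpoints share a cellular
#' compartment are excluded as well, following the convention that
#' proteins from different compartments do not interact. Sampling is
#' rejection-based with a 100x oversampling cap, falling back to explicit
#' complement enumeration on small graphs; deterministic given the seed.
#'
#' @param g An [lppi_graph()].
#' @param n Number of negative pairs required.
#' @param compartments Optional character vector of length `n_nodes`
#'   (compartment per node), or `NULL` to skip the compartment filter.
#' @param seed RNG seed.
#' @return A data frame with integer columns `u`, `v` (`u < v`), one row
#'   per sampled negative pair.
#' @export
sample_negatives <- function(g, n, compartments = NULL, seed = 1) {
  stopifnot(inherits(g, "lppi_graph"))
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  nn <- g$n_nodes
  if (!is.null(compartments) && length(compartments) != nn) {
    stop("compartments must have one label per node", call. = FALSE)
  }
  pos_keys <- pair_key(g$edges$u, g$edges$v, nn)

  eligible <- function(u, v) {
    ok <- u != v
    ok <- ok & !(pair_key(u, v, nn) %in% pos_keys)
    if (!is.null(compartments)) {
      ok <- ok & (compartments[u + 1L] != compartments[v + 1L])
    }
    ok
  }

  got <- numeric(0)  # keys of accepted pairs
  drawn <- 0
  cap <- 100 * n
  with_seed(seed, {
    while (length(got) < n && drawn < cap) {
      m <- min(cap - drawn, max(2L * n, 1000L))
      u <- sample.int(nn, m, replace = TRUE) - 1L
      v <- sample.int(nn, m, replace = TRUE) - 1L
      drawn <- drawn + m
      ok <- eligible(u, v)
      keys <- pair_key(u[ok], v[ok], nn)
      got <- c(got, keys[!keys %in% got])
      got <- got[!duplicated(got)]
    }
  })
  if (length(got) < n) {
    # exhaustive fallback: enumerate the complement (small graphs only)
    if (as.numeric(nn) * (nn - 1) / 2 <= 5e6) {
      iu <- rep(0:(nn - 2L), times = (nn - 1L):1L)
      iv <- unlist(lapply(1:(nn - 1L), function(s) s:(nn - 1L)))
      ok <- eligible(iu, iv)
      all_keys <- pair_key(iu[ok], iv[ok], nn)
      if (length(all_keys) < n) {
        stop(sprintf(
          "only %d eligible negative pairs available, %d requested",
          length(all_keys), n), call. = FALSE)
      }
      got <- with_seed(seed + 1L, sample(all_keys, n))
    } else {
      stop(sprintf(
        "negative sampling found only %d of %d pairs within the %dx cap",
        length(got), n, 100L), call. = FALSE)
    }
  }
  got <- got[seq_len(n)]
  data.frame(u = as.integer(got %/% nn), v = as.integer(got %% nn))
}

#' Pair features from node embeddings
#'
#' Combines the two endpoint embeddings of each candidate pair into one
#' feature vector with a symmetric binary operator: `"hadamard"`
#' (elementwise product, the default in the node-embedding link-prediction
#' literature), `"average"`, `"l1"` (`|e_u - e_v|`) or `"l2"`
#' (`(e_u - e_v)^2`). All four are symmetric in `(u, v)`.
#'
#' @param emb Numeric `N x d` embedding matrix.
#' @param pairs Data frame with 0-based integer columns `u`, `v`.
#' @param operator One of `"hadamard"`, `"average"`, `"l1"`, `"l2"`.
#' @return Numeric matrix with `nrow(pairs)` rows and `d` columns.
#' @export
edge_features <- function(emb, pairs,
                          operator = c("hadamard", "average", "l1", "l2")) {
  operator <- match.arg(operator)
  emb <- as.matrix(emb)
  u <- pairs$u; v <- pairs$v
  if (any(u < 0L) || any(v < 0L) || any(u >= nrow(emb)) ||
      any(v >= nrow(emb))) {
    stop("pair references node id outside the embedding", call. = FALSE)
  }
  eu <- emb[u + 1L, , drop = FALSE]
  ev <- emb[v + 1L, , drop = FALSE]
  switch(operator,
         hadamard = eu * ev,
         average = (eu + ev) / 2,
         l1 = abs(eu - ev),
         l2 = (eu - ev)^2)
}

#' Confusion-matrix classification metrics
#'
#' Accuracy `(TP + TN) / (TP + TN + FP + FN)`, sensitivity
#' `TP / (TP + FN)`, precision `TP / (TP + FP)` and the Matthews
#' correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. Any metric
#' whose denominator is zero is reported as 0, with the affected metrics
#' named in the `"undefined"` attribute.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts, total `> 0`.
#' @return Named numeric vector `c(acc, sen, pre, mcc)` with attribute
#'   `"undefined"`.
#' @examples
#' confusion_metrics(50, 40, 10, 0)
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)  # avoid integer overflow in
  fp <- as.numeric(fp); fn <- as.numeric(fn)  # the MCC denominator
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("confusion counts must be >= 0", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("confusion counts are all zero", call. = FALSE)
  undefined <- character(0)
  acc <- (tp + tn) / total
  if (tp + fn > 0) sen <- tp / (tp + fn)
  else { sen <- 0; undefined <- c(undefined, "sen") }
  if (tp + fp > 0) pre <- tp / (tp + fp)
  else { pre <- 0; undefined <- c(undefined, "pre") }
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (mcc_den > 0) mcc <- (tp * tn - fp * fn) / sqrt(mcc_den)
  else { mcc <- 0; undefined <- c(undefined, "mcc") }
  structure(c(acc = acc, sen = sen, pre = pre, mcc = mcc),
            undefined = undefined)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with half-credit for tied scores:
#' the probability that a random positive outscores a random negative.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC requires both classes present", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties with half credit
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train the pair classifier
#'
#' L2-regularized logistic regression (ridge penalty, strength equivalent
#' to the common default `C = 1`, i.e. `lambda = 1/n` on glmnet's scale)
#' fitted on pair features. Returns a scorer object whose
#' [predict()][predict.lppi_classifier] method maps feature rows to
#' interaction probabilities in `[0, 1]`.
#'
#' @param x Numeric feature matrix (rows = pairs).
#' @param y Binary labels (0/1); both classes must be present.
#' @return An object of class `lppi_classifier`.
#' @export
train_link_classifier <- function(x, y) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  lam <- 1 / nrow(x)
  # glmnet wants a decreasing path; fit down to the target lambda
  path <- exp(seq(log(lam * 100), log(lam), length.out = 20))
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = path, standardize = FALSE)
  structure(list(fit = fit, lambda = lam), class = "lppi_classifier")
}

#' Predict interaction probabilities
#'
#' @param object An `lppi_classifier` from [train_link_classifier()].
#' @param newdata Numeric feature matrix.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.lppi_classifier <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$fit, as.matrix(newdata),
                            s = object$lambda, type = "response"))
}

#' Cross-validate link prediction on a graph
#'
#' Partitions the positive edges into `folds` folds of sizes differing by
#' at most one. For each fold a fresh negative set of the full positive
#' size is sampled (fold-derived seed, never colliding with any positive
#' edge of the whole graph); the held-out fold receives exactly as many
#' negatives as it has positives and the remaining negatives join the
#' training folds, so train and test are both class-balanced. A
#' [train_link_classifier()] is fitted per fold on the pair features of
#' the training pairs and evaluated on the held-out pairs at decision
#' threshold 0.5; AUC is threshold-free.
#'
#' By default the embedding is computed once on the full graph
#' (transductive evaluation, matching the embed-once-then-CV pipeline
#' order); pass a function as `embedding` to re-embed per fold on the
#' graph with the held-out positives removed (inductive evaluation).
#'
#' @param g An [lppi_graph()] with at least `folds` edges.
#' @param embedding Either a numeric `N x d` embedding matrix, or a
#'   function `function(graph) -> matrix` called per fold on the
#'   training graph.
#' @param compartments Optional per-node compartment labels for negative
#'   sampling.
#' @param operator Pair-feature operator, see [edge_features()].
#' @param folds Number of folds (default 5).
#' @param seed RNG seed; fold assignment and per-fold negative sampling
#'   derive from it.
#' @return An object of class `lppi_cv`: data frame `report` with one row
#'   per fold (`fold`, `tp`, `tn`, `fp`, `fn`, `acc`, `sen`, `pre`,
#'   `mcc`, `auc`) plus a `means` vector, and the pooled out-of-fold
#'   `scores`/`labels` for ROC plotting.
#' @export
cross_validate <- function(g, embedding, compartments = NULL,
                           operator = "hadamard", folds = 5, seed = 1) {
  stopifnot(inherits(g, "lppi_graph"))
  m <- nrow(g$edges)
  if (m < folds) stop("graph has fewer positive edges than folds",
                      call. = FALSE)
  perm <- with_seed(stage_seed(seed, 90L), sample.int(m))
  fold_of <- integer(m)
  fold_of[perm] <- rep(seq_len(folds), length.out = m)

  emb_fun <- if (is.function(embedding)) embedding else NULL
  emb_fixed <- if (is.function(embedding)) NULL else as.matrix(embedding)
  if (!is.null(emb_fixed) && nrow(emb_fixed) != g$n_nodes) {
    stop("embedding rows do not match graph node count", call. = FALSE)
  }

  rows <- vector("list", folds)
  all_scores <- numeric(0); all_labels <- integer(0)
  for (f in seq_len(folds)) {
    test_pos <- g$edges[fold_of == f, c("u", "v")]
    train_pos <- g$edges[fold_of != f, c("u", "v")]
    neg <- sample_negatives(g, m, compartments = compartments,
                            seed = stage_seed(seed, 100L + f))
    test_neg <- neg[seq_len(nrow(test_pos)), , drop = FALSE]
    train_neg <- neg[-seq_len(nrow(test_pos)), , drop = FALSE]
    train_neg <- train_neg[seq_len(nrow(train_pos)), , drop = FALSE]

    emb <- emb_fixed
    if (!is.null(emb_fun)) {
      g_train <- lppi_graph(g$n_nodes, g$edges[fold_of != f, ],
                            node_names = g$node_names)
      emb <- as.matrix(emb_fun(g_train))
    }

    xtr <- edge_features(emb, rbind(train_pos, train_neg), operator)
    ytr <- rep(c(1L, 0L), c(nrow(train_pos), nrow(train_neg)))
    xte <- edge_features(emb, rbind(test_pos, test_neg), operator)
    yte <- rep(c(1L, 0L), c(nrow(test_pos), nrow(test_neg)))

    clf <- train_link_classifier(xtr, ytr)
    p <- predict(clf, xte)
    pred <- as.integer(p >= 0.5)
    tp <- sum(pred == 1L & yte == 1L); tn <- sum(pred == 0L & yte == 0L)
    fp <- sum(pred == 1L & yte == 0L); fn <- sum(pred == 0L & yte == 1L)
    mts <- confusion_metrics(tp, tn, fp, fn)
    rows[[f]] <- data.frame(fold = f, tp = tp, tn = tn, fp = fp, fn = fn,
                            acc = mts[["acc"]], sen = mts[["sen"]],
                            pre = mts[["pre"]], mcc = mts[["mcc"]],
                            auc = rank_auc(p, yte))
    all_scores <- c(all_scores, p); all_labels <- c(all_labels, yte)
  }
  report <- do.call(rbind, rows)
  means <- colMeans(report[, c("acc", "sen", "pre", "mcc", "auc")])
  structure(list(report = report, means = means,
                 scores = all_scores, labels = all_labels,
                 folds = folds, operator = operator, seed = seed),
            class = "lppi_cv")
}

#' @export
print.lppi_cv <- function(x, digits = 4, ...) {
  cat(sprintf("<lppi_cv> %d-fold cross-validation (operator: %s)\n",
              x$folds, x$operator))
  print(cbind(x$report[, c("fold", "tp", "tn", "fp", "fn")],
              round(x$report[, c("acc", "sen", "pre", "mcc", "auc")],
                    digits)),
        row.names = FALSE)
  cat("means:", paste(names(x$means),
                      format(round(x$means, digits)), sep = "=",
                      collapse = "  "), "\n")
  invisible(x)
}
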