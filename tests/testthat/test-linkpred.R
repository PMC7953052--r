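test_that("negative sampling enumerates exactly the complement when exhausted", {
  g <- lppi_graph(4, data.frame(u = c(0, 2), v = c(1, 3)))
  neg <- sample_negatives(g, 4, seed = 1)
  got <- sort(paste(neg$u, neg$v))
  expect_equal(got, c("0 2", "0 3", "1 2", "1 3"))
  # complete graph: empty complement -> capacity error with count
  expect_error(sample_negatives(complete_graph(4), 1), "0 eligible")
  # asking for more than available reports the availability
  expect_error(sample_negatives(g, 5), "4 eligible")
})

test_that("compartment labels exclude same-compartment pairs", {
  g <- lppi_graph(4, data.frame(u = c(0, 2), v = c(1, 3)))
  # all four complement pairs span the two compartments: all remain
  comp <- c("A", "A", "B", "B")
  neg <- sample_negatives(g, 4, compartments = comp, seed = 2)
  expect_equal(sort(paste(neg$u, neg$v)), c("0 2", "0 3", "1 2", "1 3"))
  # relabeling node 2 into A removes pair (0,2) and (1,2)
  comp2 <- c("A", "A", "A", "B")
  expect_error(sample_negatives(g, 4, compartments = comp2), "2 eligible")
  neg2 <- sample_negatives(g, 2, compartments = comp2, seed = 3)
  expect_equal(sort(paste(neg2$u, neg2$v)), c("0 3", "1 3"))
})

test_that("sampled negatives never collide with positive edges", {
  fx <- lppi_fixture(seed = 5)
  g <- fx$graph
  neg <- sample_negatives(g, n_edges(g), compartments = fx$compartments,
                          seed = 4)
  expect_equal(nrow(neg), n_edges(g))
  nkey <- paste(neg$u, neg$v)
  expect_false(any(duplicated(nkey)))
  expect_false(any(nkey %in% paste(g$edges$u, g$edges$v)))
  expect_true(all(fx$compartments[neg$u + 1] != fx$compartments[neg$v + 1]))
  # deterministic given seed
  neg2 <- sample_negatives(g, n_edges(g), compartments = fx$compartments,
                           seed = 4)
  expect_identical(neg, neg2)
})

test_that("pair-feature operators are symmetric and match direct arithmetic", {
  set.seed(21)
  emb <- matrix(rnorm(5 * 4), 5, 4)
  pairs <- data.frame(u = c(0L, 1L, 3L), v = c(2L, 4L, 0L))
  flipped <- data.frame(u = pairs$v, v = pairs$u)
  for (op in c("hadamard", "average", "l1", "l2")) {
    expect_equal(edge_features(emb, pairs, op),
                 edge_features(emb, flipped, op))
  }
  # hadamard with an all-ones partner returns the other row unchanged
  emb1 <- rbind(emb[1, ], rep(1, 4))
  expect_equal(edge_features(emb1, data.frame(u = 0L, v = 1L), "hadamard"),
               emb[1, , drop = FALSE], ignore_attr = TRUE)
  # average of rows (0,2,...) and (2,0,...)
  emb2 <- rbind(c(0, 2), c(2, 0))
  expect_equal(edge_features(emb2, data.frame(u = 0L, v = 1L), "average"),
               matrix(1, 1, 2))
  expect_error(edge_features(emb, data.frame(u = 0L, v = 9L)), "outside")
})

test_that("confusion metrics reproduce the hand-computed example to 5 decimals", {
  m <- confusion_metrics(50, 40, 10, 0)
  expect_equal(m[["acc"]], 0.9)
  expect_equal(m[["sen"]], 1.0)
  expect_equal(m[["pre"]], 0.83333, tolerance = 1e-5)
  expect_equal(m[["mcc"]], 2000 / sqrt(6000000), tolerance = 1e-12)
  expect_equal(round(m[["mcc"]], 5), 0.81650)
})

test_that("confusion metrics handle degenerate counts", {
  perfect <- confusion_metrics(5, 5, 0, 0)
  expect_equal(unname(perfect), c(1, 1, 1, 1), ignore_attr = TRUE)
  inverted <- confusion_metrics(0, 0, 3, 3)
  expect_equal(inverted[["acc"]], 0)
  expect_equal(inverted[["mcc"]], -1)
  # zero-denominator metrics are flagged and reported as 0
  no_pos <- confusion_metrics(0, 4, 0, 0)
  expect_equal(no_pos[["sen"]], 0)
  expect_true(all(c("sen", "pre", "mcc") %in% attr(no_pos, "undefined")))
  expect_error(confusion_metrics(0, 0, 0, 0), "all zero")
  expect_error(confusion_metrics(-1, 1, 0, 0), ">= 0")
})

test_that("MCC is invariant under the TP<->TN, FP<->FN swap and bounded", {
  set.seed(2)
  for (i in 1:50) {
    cts <- rpois(4, 20) + c(1, 1, 0, 0)
    a <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])[["mcc"]]
    b <- confusion_metrics(cts[2], cts[1], cts[4], cts[3])[["mcc"]]
    expect_equal(a, b)
    expect_gte(a, -1); expect_lte(a, 1)
  }
})

test_that("rank AUC matches closed-form examples and the trapezoid oracle", {
  expect_equal(rank_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(rank_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(rank_auc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  expect_error(rank_auc(c(1, 2), c(1, 1)), "both classes")
  set.seed(31)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties
    expect_equal(rank_auc(scores, labels), trapezoid_auc(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (i in 1:20) {
    labels <- c(0, 1, rbinom(30, 1, 0.5))
    scores <- rnorm(32) + labels
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rank_auc(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("the classifier separates a separable toy set and bounds probabilities", {
  set.seed(9)
  x <- rbind(matrix(rnorm(100, 3), ncol = 2),
             matrix(rnorm(100, -3), ncol = 2))
  y <- rep(c(1, 0), each = 50)
  clf <- train_link_classifier(x, y)
  p <- predict(clf, x)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(as.integer(p >= 0.5), y)
  expect_error(train_link_classifier(x, rep(1, 100)), "single class")
  # label swap flips the scores
  clf2 <- train_link_classifier(x, 1 - y)
  expect_equal(predict(clf2, x), 1 - p, tolerance = 1e-6)
})

test_that("cross-validation partitions positives into near-equal disjoint folds", {
  sbm <- simulate_sbm(c(30, 30), 0.3, 0.03, seed = 2)
  g <- sbm$graph
  emb <- embed_graph(g, dim = 16, num_walks = 4, walk_length = 20, seed = 1)
  cv <- cross_validate(g, emb, folds = 5, seed = 3)
  rep <- cv$report
  fold_sizes <- rep$tp + rep$fn              # positives per fold
  expect_equal(sum(fold_sizes), n_edges(g))
  expect_lte(max(fold_sizes) - min(fold_sizes), 1)
  # per-fold negatives equal per-fold positives
  expect_equal(rep$tn + rep$fp, fold_sizes)
  # metrics formula vs direct count agree exactly
  expect_equal(rep$acc, (rep$tp + rep$tn) /
                 (rep$tp + rep$tn + rep$fp + rep$fn))
  expect_true(all(rep$auc >= 0 & rep$auc <= 1))
  # deterministic given the seed
  cv2 <- cross_validate(g, emb, folds = 5, seed = 3)
  expect_identical(cv$report, cv2$report)
})

test_that("inductive cross-validation re-embeds without the held-out edges", {
  sbm <- simulate_sbm(c(20, 20), 0.35, 0.03, seed = 6)
  g <- sbm$graph
  seen <- new.env()
  builder <- function(g_train) {
    assign(sprintf("m%d", n_edges(g_train)), TRUE, envir = seen)
    expect_lt(n_edges(g_train), n_edges(g))
    embed_graph(g_train, dim = 8, num_walks = 2, walk_length = 10,
                seed = 1)
  }
  cv <- cross_validate(g, builder, folds = 5, seed = 2)
  expect_equal(nrow(cv$report), 5L)
  expect_gte(length(ls(seen)), 1L)
})
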