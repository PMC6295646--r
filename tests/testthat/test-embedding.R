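# Embedding module: random walks, the walk corpus, and skip-gram training.

test_that("a length-1 walk is just the root and forced paths alternate", {
  g <- path_graph_2()
  expect_identical(random_walk(g, 1, 1), 1L)
  expect_identical(random_walk(g, "a", 4), c(1L, 2L, 1L, 2L))
})

test_that("an isolated start node raises an error naming the node", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  g <- connectivity_graph(w, c("a", "b", "lonely"))
  expect_error(random_walk(g, "lonely", 3), "lonely")
  expect_error(generate_walks(g, walk_config(iterations = 1, walk_length = 5)),
               "lonely")
})

test_that("transition frequencies follow normalized edge weights", {
  g <- triangle_graph(w_ab = 2, w_ac = 1)
  steps <- withr::with_seed(31, {
    vapply(1:10000, function(i) random_walk(g, 1, 2)[2], 1L)
  })
  # fraction of single steps from a going to b should be 2/3
  expect_equal(mean(steps == 2L), 2 / 3, tolerance = 0.02)
  # chi-squared goodness of fit against the weight-normalized law
  p <- g$weights[1, 2:3] / sum(g$weights[1, 2:3])
  gof <- stats::chisq.test(tabulate(steps - 1L, 2), p = p)
  expect_gt(gof$p.value, 0.01)
})

test_that("uniform mode ignores the edge weights", {
  g <- triangle_graph(w_ab = 2, w_ac = 1)
  steps <- withr::with_seed(13, {
    vapply(1:4000, function(i) random_walk(g, 1, 2, mode = "uniform")[2], 1L)
  })
  expect_equal(mean(steps == 2L), 0.5, tolerance = 0.03)
})

test_that("the walk corpus has I walks per node, all edges valid", {
  g <- simulate_modular_graph(10, 2, 0.8, 0.2, 0.05, seed = 3)
  cfg <- walk_config(iterations = 3, walk_length = 8, seed = 21)
  walks <- generate_walks(g, cfg)
  expect_equal(nrow(walks), 30)                      # I * |V|
  expect_equal(ncol(walks), 8)
  expect_equal(as.vector(table(walks[, 1])), rep(3L, 10))  # each root I times
  for (r in seq_len(nrow(walks))) {
    for (s in 2:ncol(walks)) {
      expect_gt(g$weights[walks[r, s - 1], walks[r, s]], 0)
    }
  }
  # determinism under a fixed seed
  expect_identical(walks, generate_walks(g, cfg))
})

test_that("skip-gram context distributions are normalized probabilities", {
  g <- two_clique_graph()
  walks <- generate_walks(g, walk_config(iterations = 3, walk_length = 10,
                                         seed = 2))
  m <- train_skipgram(walks, skipgram_config(dim = 4, epochs = 2, seed = 4))
  for (v in c(1L, 5L, 12L)) {
    p <- skipgram_context_probs(m, v)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_gte(min(p), 0)
  }
  expect_equal(dim(m$input_weights), c(12L, 4L))     # n_nodes x d
  expect_error(train_skipgram(walks[0, , drop = FALSE],
                              skipgram_config(dim = 4)), "empty")
})

test_that("training losses decrease on a structured corpus", {
  g <- two_clique_graph()
  walks <- generate_walks(g, walk_config(seed = 2))
  m <- train_skipgram(walks, skipgram_config(dim = 6, epochs = 5, seed = 4))
  expect_lt(m$epoch_loss[5], m$epoch_loss[1])
})

test_that("embeddings separate two cliques joined by a weak bridge", {
  g <- two_clique_graph(m = 6, w_in = 0.9, w_bridge = 0.05)
  emb <- node2vec(g, walk_config(seed = 10),
                  skipgram_config(dim = 6, epochs = 5, seed = 11))
  cs <- unclass(emb)
  cs <- cs / sqrt(rowSums(cs^2))
  S <- cs %*% t(cs)
  blocks <- rep(1:2, each = 6)
  same <- outer(blocks, blocks, "==") & upper.tri(S)
  diff <- !outer(blocks, blocks, "==") & upper.tri(S)
  expect_gt(mean(S[same]), mean(S[diff]))
})

test_that("2-means on embeddings recovers a planted two-block graph", {
  g <- simulate_modular_graph(30, 2, w_in = 0.9, w_out = 0.1, jitter = 0.05,
                              seed = 17)
  emb <- node2vec(g, walk_config(seed = 5),
                  skipgram_config(dim = 8, epochs = 5, seed = 6))
  km <- withr::with_seed(1, stats::kmeans(unclass(emb), 2, nstart = 10))
  expect_gte(block_agreement(km$cluster, attr(g, "blocks")), 0.9)
})

test_that("node2vec output is shaped |V| x d, reproducible, id-aligned", {
  g <- simulate_modular_graph(15, 3, 0.8, 0.1, 0.05, seed = 8)
  wc <- walk_config(iterations = 2, walk_length = 10, seed = 1)
  sc <- skipgram_config(dim = 5, epochs = 2, seed = 2)
  e1 <- node2vec(g, wc, sc)
  e2 <- node2vec(g, wc, sc)
  expect_identical(unclass(e1), unclass(e2))
  expect_equal(dim(e1), c(15L, 5L))
  expect_identical(rownames(e1), g$node_ids)
  expect_true(all(is.finite(e1)))
})

test_that("relabeling node ids relabels embedding rows in place", {
  g <- simulate_modular_graph(12, 2, 0.9, 0.1, 0, seed = 4)
  ids2 <- rev(g$node_ids)
  g2 <- connectivity_graph(g$weights, ids2)
  wc <- walk_config(iterations = 2, walk_length = 8, seed = 3)
  sc <- skipgram_config(dim = 4, epochs = 2, seed = 5)
  e1 <- node2vec(g, wc, sc)
  e2 <- node2vec(g2, wc, sc)
  expect_identical(unname(unclass(e1)), unname(unclass(e2)))
  expect_identical(rownames(e2), ids2)
})

test_that("embedding dimension must stay far below the graph order", {
  g <- simulate_modular_graph(10, 2, 0.9, 0.1, 0, seed = 1)
  expect_error(node2vec(g, walk_config(iterations = 1, walk_length = 4),
                        skipgram_config(dim = 10)), "<<")
  expect_error(node2vec(g, walk_config(iterations = 1, walk_length = 4),
                        skipgram_config(dim = 15)), "<<")
})

test_that("negative-sampling training also separates structure", {
  g <- two_clique_graph(m = 6, w_in = 0.9, w_bridge = 0.05)
  walks <- generate_walks(g, walk_config(seed = 9))
  m <- train_skipgram(walks, skipgram_config(dim = 6, epochs = 5,
                                             negative = 5, seed = 12))
  cs <- m$input_weights / sqrt(rowSums(m$input_weights^2))
  S <- cs %*% t(cs)
  blocks <- rep(1:2, each = 6)
  same <- outer(blocks, blocks, "==") & upper.tri(S)
  diff <- !outer(blocks, blocks, "==") & upper.tri(S)
  expect_gt(mean(S[same]), mean(S[diff]))
})

test_that("top-k sparsification keeps walks on the strongest edges", {
  g <- simulate_modular_graph(12, 2, 0.9, 0.1, 0.02, seed = 6)
  walks <- generate_walks(g, walk_config(iterations = 2, walk_length = 10,
                                         seed = 7, top_k = 3))
  # sparsified support: each step's edge is in the union of either
  # endpoint's top-3 edges
  topk <- lapply(seq_len(12), function(i) {
    order(g$weights[i, ], decreasing = TRUE)[1:3]
  })
  for (r in seq_len(nrow(walks))) {
    for (s in 2:ncol(walks)) {
      a <- walks[r, s - 1]; b <- walks[r, s]
      expect_true(b %in% topk[[a]] || a %in% topk[[b]])
    }
  }
})
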