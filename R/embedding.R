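# Embedding stage: weighted first-order random walks over the connectivity
# graph serve as "sentences"; a skip-gram model trained on those walks yields
# one low-dimensional vector per node (the |V| x d matrix Phi).

#' Random-walk configuration
#'
#' @param iterations walks started per node (each node roots one walk per
#'   iteration).
#' @param walk_length nodes per walk (>= 2; a length-1 walk is just the root).
#' @param seed integer seed for the walk stream.
#' @param mode `"weighted"` (next node drawn with probability proportional to
#'   edge weight — the default, since a dense PLI graph carries all structure
#'   in its weights) or `"uniform"` (uniform over positive-weight neighbors).
#' @param top_k optional per-node edge sparsification: keep only each node's
#'   `top_k` strongest edges (symmetrized by union) before walking.
#' @return a `walk_config` list.
#' @export
walk_config <- function(iterations = 10L, walk_length = 40L, seed = 1L,
                        mode = c("weighted", "uniform"), top_k = NULL) {
  mode <- match.arg(mode)
  if (!is.null(top_k)) top_k <- check_count(top_k, "top_k")
  structure(list(iterations = check_count(iterations, "iterations"),
                 walk_length = check_count(walk_length, "walk_length"),
                 seed = check_count(seed, "seed", min = 0L),
                 mode = mode, top_k = top_k),
            class = "walk_config")
}

#' Skip-gram configuration
#'
#' @param window context window half-width `w`: for a focus node at position
#'   `j`, nodes at positions `j-w .. j+w` (clipped at the walk boundaries,
#'   excluding `j`) are positive contexts.
#' @param dim embedding dimension `d` (must satisfy `d << |V|`; configurations
#'   with `d >= |V|` are rejected at training time).
#' @param epochs passes over the full pair corpus.
#' @param learning_rate initial step size; decays linearly to ~0 over
#'   training.
#' @param batch_size focus-context pairs per stochastic gradient step.
#' @param negative number of negative samples per pair; 0 (default) trains
#'   the exact softmax, which is cheap for vocabularies of a few hundred
#'   nodes. Positive values switch to negative-sampling for large graphs.
#' @param seed integer seed for initialization and shuffling.
#' @return a `skipgram_config` list.
#' @export
skipgram_config <- function(window = 5L, dim = 20L, epochs = 5L,
                            learning_rate = 0.025, batch_size = 256L,
                            negative = 0L, seed = 1L) {
  if (!is_scalar_number(learning_rate) || learning_rate <= 0) {
    stop_param("`learning_rate` must be positive")
  }
  structure(list(window = check_count(window, "window"),
                 dim = check_count(dim, "dim"),
                 epochs = check_count(epochs, "epochs"),
                 learning_rate = learning_rate,
                 batch_size = check_count(batch_size, "batch_size"),
                 negative = check_count(negative, "negative", min = 0L),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "skipgram_config")
}

# Per-node transition tables: positive-weight neighbors and their cumulative
# sampling probabilities.  The diagonal is ignored; self-loops are never
# walked.
transition_tables <- function(graph, mode = "weighted", top_k = NULL) {
  w <- graph$weights
  diag(w) <- 0
  if (!is.null(top_k)) {
    keep <- matrix(FALSE, nrow(w), ncol(w))
    for (i in seq_len(nrow(w))) {
      nb <- which(w[i, ] > 0)
      if (length(nb) > top_k) nb <- nb[order(w[i, nb], decreasing = TRUE)[seq_len(top_k)]]
      keep[i, nb] <- TRUE
    }
    keep <- keep | t(keep)                    # symmetrize by union
    w[!keep] <- 0
  }
  lapply(seq_len(nrow(w)), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) == 0L) return(list(nb = integer(), cum = numeric()))
    p <- if (mode == "uniform") rep(1, length(nb)) else w[i, nb]
    list(nb = nb, cum = cumsum(p) / sum(p))
  })
}

walk_from <- function(tables, start, length) {
  path <- integer(length)
  path[1L] <- start
  if (length > 1L) {
    u <- stats::runif(length - 1L)
    cur <- start
    for (s in 2:length) {
      tab <- tables[[cur]]
      cur <- tab$nb[findInterval(u[s - 1L], tab$cum, left.open = TRUE) + 1L]
      path[s] <- cur
    }
  }
  path
}

#' Single weighted random walk
#'
#' Starts at `start` and, at each step, samples the next node among the
#' current node's positive-weight neighbors — by default with probability
#' proportional to edge weight.  Uses the current RNG state; seed externally
#' (or via [generate_walks()]) for reproducibility.
#'
#' @param graph a [connectivity_graph()].
#' @param start node index (1-based) or node id.
#' @param length walk length `l` (number of nodes, including the root).
#' @param mode,top_k see [walk_config()].
#' @return integer vector of node indices of length `length`.
#' @export
random_walk <- function(graph, start, length, mode = "weighted", top_k = NULL) {
  stopifnot(inherits(graph, "connectivity_graph"))
  if (is.character(start)) start <- match(start, graph$node_ids)
  start <- check_count(start, "start")
  n <- base::length(graph$node_ids)
  if (start > n) stop_param("`start` (%d) exceeds graph order (%d)", start, n)
  length <- check_count(length, "length")
  tables <- transition_tables(graph, mode = mode, top_k = top_k)
  if (base::length(tables[[start]]$nb) == 0L && length > 1L) {
    stop_param("node '%s' is isolated (no positive-weight neighbors)",
               graph$node_ids[start])
  }
  walk_from(tables, start, length)
}

#' Walk corpus over a whole graph
#'
#' Runs `iterations` sweeps; in each sweep every node roots exactly one walk
#' (so `iterations * |V|` walks in total).  Fully reproducible under the
#' configured seed.
#'
#' @param graph a [connectivity_graph()].
#' @param cfg a [walk_config()].
#' @return integer matrix, one walk per row (`iterations * |V|` rows,
#'   `walk_length` columns), with attribute `n_nodes`.
#' @export
generate_walks <- function(graph, cfg) {
  stopifnot(inherits(graph, "connectivity_graph"), inherits(cfg, "walk_config"))
  n <- length(graph$node_ids)
  tables <- transition_tables(graph, mode = cfg$mode, top_k = cfg$top_k)
  iso <- which(vapply(tables, function(t) length(t$nb) == 0L, TRUE))
  if (length(iso) > 0L && cfg$walk_length > 1L) {
    stop_param("isolated node(s): %s",
               paste(graph$node_ids[iso], collapse = ", "))
  }
  walks <- matrix(0L, nrow = cfg$iterations * n, ncol = cfg$walk_length)
  with_seed(cfg$seed, {
    row <- 0L
    for (it in seq_len(cfg$iterations)) {
      for (v in seq_len(n)) {
        row <- row + 1L
        walks[row, ] <- walk_from(tables, v, cfg$walk_length)
      }
    }
  })
  attr(walks, "n_nodes") <- n
  walks
}

# Flatten a walk matrix into focus/context index pairs under window w.
context_pairs <- function(walks, window) {
  l <- ncol(walks)
  foc <- list(); ctx <- list(); k <- 0L
  for (off in seq_len(min(window, l - 1L))) {
    a <- walks[, seq_len(l - off), drop = FALSE]
    b <- walks[, (off + 1L):l, drop = FALSE]
    k <- k + 1L; foc[[k]] <- as.integer(a); ctx[[k]] <- as.integer(b)
    k <- k + 1L; foc[[k]] <- as.integer(b); ctx[[k]] <- as.integer(a)
  }
  list(focus = unlist(foc), context = unlist(ctx))
}

#' Train a skip-gram model on a walk corpus
#'
#' Maximizes the softmax co-occurrence probability of each node's window
#' contexts by minibatched stochastic gradient ascent.  One-hot node inputs
#' make the model equivalent to two shared weight matrices: `input_weights`
#' (`n_nodes x d`, the embedding read out by [node2vec()]) and
#' `output_weights` (`d x n_nodes`, the context scorer).
#'
#' @param walks integer walk matrix from [generate_walks()] (or any matrix of
#'   node indices, one walk per row).
#' @param cfg a [skipgram_config()].
#' @param n_nodes vocabulary size (defaults to the walk matrix attribute).
#' @return a `skipgram_model` list with `input_weights`, `output_weights`,
#'   `config`, and the mean training loss per epoch.
#' @export
train_skipgram <- function(walks, cfg, n_nodes = attr(walks, "n_nodes")) {
  stopifnot(inherits(cfg, "skipgram_config"))
  walks <- as.matrix(walks)
  if (nrow(walks) == 0L) stop_param("empty walk corpus")
  if (is.null(n_nodes)) n_nodes <- max(walks)
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2L)
  if (max(walks) > n_nodes) stop_param("walk indices exceed `n_nodes`")
  if (cfg$dim >= n_nodes) {
    stop_param("embedding dim d = %d must be << graph order |V| = %d",
               cfg$dim, n_nodes)
  }
  pr <- context_pairs(walks, cfg$window)
  n_pairs <- length(pr$focus)
  d <- cfg$dim
  epoch_loss <- numeric(cfg$epochs)

  with_seed(cfg$seed, {
    w_in <- matrix(stats::runif(n_nodes * d, -0.5, 0.5) / d, n_nodes, d)
    w_out <- matrix(0, d, n_nodes)
    total_steps <- cfg$epochs * ceiling(n_pairs / cfg$batch_size)
    step <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n_pairs)
      starts <- seq(1L, n_pairs, by = cfg$batch_size)
      loss_sum <- 0
      for (s in starts) {
        step <- step + 1L
        lr <- cfg$learning_rate * max(1e-4, 1 - (step - 1L) / total_steps)
        take <- ord[s:min(s + cfg$batch_size - 1L, n_pairs)]
        f <- pr$focus[take]; ctx <- pr$context[take]
        b <- length(take)
        h <- w_in[f, , drop = FALSE]                        # b x d
        if (cfg$negative == 0L) {
          sc <- h %*% w_out                                 # b x |V|
          sc <- sc - apply(sc, 1L, max)
          e <- exp(sc)
          p <- e / rowSums(e)
          loss_sum <- loss_sum - sum(log(pmax(p[cbind(seq_len(b), ctx)], 1e-300)))
          g <- p
          g[cbind(seq_len(b), ctx)] <- g[cbind(seq_len(b), ctx)] - 1
          gh <- g %*% t(w_out)                              # b x d
          # summed (not averaged) batch gradient: each pair contributes the
          # same step it would take under per-pair SGD at this learning rate
          w_out <- w_out - lr * (t(h) %*% g)
        } else {
          neg <- matrix(sample.int(n_nodes, b * cfg$negative, replace = TRUE),
                        b, cfg$negative)
          tgt <- cbind(ctx, neg)
          lab <- cbind(matrix(1, b, 1L), matrix(0, b, cfg$negative))
          gh <- matrix(0, b, d)
          dws <- vector("list", ncol(tgt))
          sig <- function(z) 1 / (1 + exp(-z))
          for (cidx in seq_len(ncol(tgt))) {
            wj <- t(w_out[, tgt[, cidx], drop = FALSE])     # b x d
            z <- sig(rowSums(h * wj))
            loss_sum <- loss_sum - sum(log(pmax(ifelse(lab[, cidx] == 1, z, 1 - z), 1e-300)))
            gz <- z - lab[, cidx]
            gh <- gh + gz * wj
            dws[[cidx]] <- list(j = tgt[, cidx], g = gz * h)
          }
          for (u in dws) {
            agg <- rowsum(u$g, group = u$j)
            jj <- as.integer(rownames(agg))
            w_out[, jj] <- w_out[, jj] - lr * t(agg)
          }
        }
        agg <- rowsum(gh, group = f)
        ii <- as.integer(rownames(agg))
        w_in[ii, ] <- w_in[ii, ] - lr * agg
      }
      epoch_loss[ep] <- loss_sum / n_pairs
    }
  })
  structure(list(input_weights = w_in, output_weights = w_out,
                 config = cfg, n_nodes = n_nodes, epoch_loss = epoch_loss),
            class = "skipgram_model")
}

#' Predicted context distribution of one node
#'
#' Softmax over the model's output scores for a focus node; sums to 1 by
#' construction.
#'
#' @param model a `skipgram_model`.
#' @param node node index (1-based).
#' @return numeric probability vector of length `n_nodes`.
#' @export
skipgram_context_probs <- function(model, node) {
  stopifnot(inherits(model, "skipgram_model"))
  node <- check_count(node, "node")
  sc <- drop(model$input_weights[node, , drop = FALSE] %*% model$output_weights)
  e <- exp(sc - max(sc))
  e / sum(e)
}

#' Node embedding of a weighted graph
#'
#' The full embedding stage: generate the walk corpus, train the skip-gram
#' model, and return the input-weight matrix Phi (`|V| x d`), with rows
#' aligned to the graph's node order.
#'
#' @param graph a [connectivity_graph()].
#' @param walk_cfg a [walk_config()].
#' @param sg_cfg a [skipgram_config()].
#' @return an `embedding_matrix`: numeric matrix with node ids as rownames.
#' @export
#' @examples
#' g <- simulate_modular_graph(20, 2, w_in = 0.9, w_out = 0.1,
#'                             jitter = 0.05, seed = 7)
#' emb <- node2vec(g, walk_config(iterations = 2, walk_length = 10, seed = 1),
#'                 skipgram_config(dim = 4, epochs = 2, seed = 2))
#' dim(emb)
node2vec <- function(graph, walk_cfg = walk_config(),
                     sg_cfg = skipgram_config()) {
  stopifnot(inherits(graph, "connectivity_graph"))
  n <- length(graph$node_ids)
  if (n < 2L) stop_param("graph order must be >= 2")
  if (sg_cfg$dim >= n) {
    stop_param("embedding dim d = %d must be << graph order |V| = %d",
               sg_cfg$dim, n)
  }
  walks <- generate_walks(graph, walk_cfg)
  model <- train_skipgram(walks, sg_cfg, n_nodes = n)
  phi <- model$input_weights
  rownames(phi) <- graph$node_ids
  colnames(phi) <- sprintf("dim%02d", seq_len(ncol(phi)))
  class(phi) <- c("embedding_matrix", class(phi))
  phi
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %d nodes x %d dimensions\n",
              nrow(x), ncol(x)))
  invisible(x)
}
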