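# Imaging stage: PCA-align the embedding features, pair consecutive
# features, and bin each pair into an r x r count histogram; the channel
# stack is the image fed to the CNN.  Every channel's pixel values sum to
# |V| because each node lands in exactly one bin.

#' PCA-aligned node features
#'
#' Projects the embedding rows onto their top `d_pca` principal components
#' (mean-centered, unscaled), ordering features by decreasing explained
#' variance.  A deterministic sign convention is applied — each component's
#' loading vector is flipped so that its largest-magnitude entry is positive
#' — removing the run-to-run sign ambiguity of eigenvectors.
#'
#' @param emb embedding matrix (`|V| x d`), e.g. from [node2vec()].
#' @param d_pca number of features to keep; `2 <= d_pca < d` and
#'   `|V| > d_pca`.
#' @return a `node_features` matrix (`|V| x d_pca`) with attributes
#'   `explained_variance` (per-component variances) and `loadings`.
#' @export
pca_features <- function(emb, d_pca = 4L) {
  emb <- unclass(as.matrix(emb))
  d <- ncol(emb)
  d_pca <- check_count(d_pca, "d_pca", min = 2L)
  if (d_pca >= d) stop_param("`d_pca` (%d) must be < embedding dim (%d)", d_pca, d)
  if (nrow(emb) <= d_pca) stop_param("need more nodes (%d) than features (%d)",
                                     nrow(emb), d_pca)
  pc <- stats::prcomp(emb, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(d_pca), drop = FALSE]
  scores <- pc$x[, seq_len(d_pca), drop = FALSE]
  for (j in seq_len(d_pca)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- sprintf("f%d", seq_len(d_pca))
  structure(scores,
            explained_variance = pc$sdev[seq_len(d_pca)]^2,
            loadings = rot,
            class = c("node_features", "matrix", "array"))
}

#' Extract one feature pair
#'
#' Pair `c` is the 2 x `|V|` matrix whose first row is feature `2c - 1` and
#' second row feature `2c`; pair 1 holds the first two features, pair 2 the
#' third and fourth, and so on.
#'
#' @param feats a `node_features` matrix from [pca_features()].
#' @param c pair index (`2c <= d_pca`).
#' @return a 2 x `|V|` numeric matrix (class `feature_pair_matrix`).
#' @export
feature_pair <- function(feats, c) {
  c <- check_count(c, "c")
  d_pca <- ncol(feats)
  if (2L * c > d_pca) {
    stop_param("pair %d needs features %d-%d but only %d are available",
               c, 2L * c - 1L, 2L * c, d_pca)
  }
  m <- t(unclass(feats)[, c(2L * c - 1L, 2L * c), drop = FALSE])
  structure(m, pair_index = c, class = c("feature_pair_matrix", "matrix", "array"))
}

# Equal-width bin index over [mn, mx] with the maximum assigned to the top
# bin; a zero-range feature sends every node to bin 1 (with a warning from
# the caller).
bin_index <- function(v, r) {
  mn <- min(v); mx <- max(v)
  if (mx == mn) return(list(idx = rep(1L, length(v)), degenerate = TRUE))
  idx <- floor((v - mn) / (mx - mn) * r) + 1L
  idx[idx > r] <- r
  list(idx = as.integer(idx), degenerate = FALSE)
}

#' 2D count histogram of one feature pair
#'
#' Bins each feature of the pair into `r` equal-width bins spanning its
#' per-graph min-max range (maximum value closed into the top bin) and counts
#' the nodes falling into each of the `r x r` cells.  The first feature of
#' the pair indexes rows, the second columns.  Every node contributes exactly
#' one count, so the matrix total equals the node count.
#'
#' @param pairs a `feature_pair_matrix` from [feature_pair()] (2 x `|V|`).
#' @param r image resolution (bins per axis).
#' @return an `r x r` integer count matrix.
#' @export
histogram_channel <- function(pairs, r = 10L) {
  r <- check_count(r, "r")
  pairs <- as.matrix(pairs)
  if (nrow(pairs) != 2L) stop_param("`pairs` must have exactly 2 rows")
  if (ncol(pairs) < 1L) stop_param("need at least one node")
  if (!all(is.finite(pairs))) stop_param("non-finite feature values")
  bx <- bin_index(pairs[1L, ], r)
  by <- bin_index(pairs[2L, ], r)
  if (bx$degenerate || by$degenerate) {
    warning("zero-range feature: all nodes mapped to bin 1 on that axis",
            call. = FALSE)
  }
  counts <- tabulate((by$idx - 1L) * r + bx$idx, nbins = r * r)
  matrix(as.integer(counts), nrow = r, ncol = r)
}

#' Graph image from an embedding matrix
#'
#' The full imaging stage: PCA-align to `d_pca` features, split them into
#' `d_pca / 2` consecutive pairs, and render each pair as an `r x r` count
#' histogram.  The channels stack into an `r x r x d_pca/2` image; with the
#' defaults (`d_pca = 4`, `r = 10`) each graph becomes a 10 x 10 x 2 image.
#'
#' @param emb embedding matrix (`|V| x d`).
#' @param d_pca number of PCA features (even, `< d`).
#' @param r image resolution.
#' @return a `graph_image`: integer array `r x r x d_pca/2` whose every
#'   channel sums to `|V|`.
#' @export
graph_to_image <- function(emb, d_pca = 4L, r = 10L) {
  d_pca <- check_count(d_pca, "d_pca", min = 2L)
  if (d_pca %% 2L != 0L) stop_param("`d_pca` must be even (channels are feature pairs)")
  r <- check_count(r, "r")
  feats <- pca_features(emb, d_pca)
  n_chan <- d_pca %/% 2L
  img <- array(0L, dim = c(r, r, n_chan))
  for (c in seq_len(n_chan)) {
    img[, , c] <- histogram_channel(feature_pair(feats, c), r)
  }
  structure(img, n_nodes = nrow(emb), class = "graph_image")
}

#' @export
print.graph_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<graph_image> %d x %d x %d (each channel sums to %d nodes)\n",
              d[1L], d[2L], d[3L], attr(x, "n_nodes")))
  invisible(x)
}

#' Plot a graph image
#'
#' Raster plot of every histogram channel, facetted by channel.
#'
#' @param object a `graph_image`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot graph_image
#' @export
autoplot.graph_image <- function(object, ...) {
  d <- dim(object)
  df <- expand.grid(x = seq_len(d[1L]), y = seq_len(d[2L]),
                    channel = seq_len(d[3L]))
  df$count <- as.vector(unclass(object))
  df$channel <- factor(paste("channel", df$channel))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$x,
                                   fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "feature 2c bin", y = "feature 2c-1 bin",
                  fill = "nodes") +
    ggplot2::theme_minimal()
}
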