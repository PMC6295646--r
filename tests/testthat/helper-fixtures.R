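# Shared fixtures, all built in code at test time.

# sinusoidal recording: one row per (freq, phase) pair
sine_recording <- function(freqs, phases = rep(0, length(freqs)),
                           fs = 100, n = 1000) {
  tt <- (seq_len(n) - 1) / fs
  x <- t(mapply(function(f, p) sin(2 * pi * f * tt + p), freqs, phases))
  recording(x, fs)
}

# small deterministic weighted graph: path a-b with a single edge
path_graph_2 <- function() {
  connectivity_graph(matrix(c(0, 0.8, 0.8, 0), 2, 2), c("a", "b"))
}

triangle_graph <- function(w_ab = 2, w_ac = 1, w_bc = 1) {
  w <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  w["a", "b"] <- w["b", "a"] <- w_ab
  w["a", "c"] <- w["c", "a"] <- w_ac
  w["b", "c"] <- w["c", "b"] <- w_bc
  connectivity_graph(w / max(w))
}

# two dense cliques joined by one weak bridge
two_clique_graph <- function(m = 6, w_in = 0.9, w_bridge = 0.05) {
  n <- 2 * m
  w <- matrix(0, n, n)
  w[1:m, 1:m] <- w_in
  w[(m + 1):n, (m + 1):n] <- w_in
  w[m, m + 1] <- w[m + 1, m] <- w_bridge
  diag(w) <- 0
  connectivity_graph(w)
}

# best 2-means agreement with planted labels (label-permutation invariant)
block_agreement <- function(cluster, blocks) {
  max(mean(cluster == blocks), mean(cluster == (3 - blocks)))
}

# fast small-image CNN config for toy training runs
toy_cnn_config <- function(...) {
  cnn_config(max_epochs = 200, early_stop_patience = 200, seed = 11, ...)
}

# tiny toy image set: class signature at one of two pixels
toy_image_set <- function(n_per_class = 4, magnitude = 20) {
  n <- 2 * n_per_class
  imgs <- array(0, c(n, 10, 10, 2))
  for (i in seq_len(n)) {
    if (i <= n_per_class) imgs[i, 2, 2, 1] <- magnitude
    else imgs[i, 8, 8, 1] <- magnitude
  }
  labeled_image_set(imgs, rep(c("control", "case"), each = n_per_class))
}
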