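# Classifier stage: a compact LeNet-style CNN for small multi-channel count
# images, implemented with im2col + matrix products in base R.  Layer order:
# input -> conv(32, 3x3, ReLU) -> conv(128, 3x3, ReLU) -> maxpool(2x2)
# -> flatten -> FC(32, ReLU) -> FC(16, ReLU) -> FC(n_classes, softmax).
# Convolutions are unpadded ("valid"): a 10x10 input shrinks 10 -> 8 -> 6,
# pools to 3, and flattens to 3*3*128 = 1152 units.

#' CNN configuration
#'
#' Defaults mirror the reference architecture and training recipe for
#' 10 x 10 x 2 graph images: two valid 3 x 3 convolution layers (32 then 128
#' maps), one 2 x 2 max-pool, fully connected layers of 32 and 16 units, a
#' 2-way softmax; dropout 0.25 after both convolution layers and the first
#' fully connected layer; Adam with learning rate 0.001 and L2 weight decay
#' 5e-4; up to 1000 epochs with early stopping on validation loss.
#'
#' @param input_shape `c(rows, cols, channels)` of one image.
#' @param conv1_maps,conv2_maps feature maps of the two convolution layers.
#' @param kernel square kernel size (unpadded convolutions).
#' @param pool max-pool window (and stride).
#' @param fc1_units,fc2_units fully connected layer widths.
#' @param n_classes output classes.
#' @param dropout_rate dropout probability in `[0, 1)` (training only).
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty coefficient on all weight matrices (not
#'   biases).
#' @param max_epochs training epoch cap.
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping (best weights are restored).
#' @param min_delta minimum validation-loss improvement that resets patience.
#' @param momentum recorded for provenance but unused: the optimizer is Adam
#'   (beta1 = 0.9, beta2 = 0.999), which has no plain momentum term.
#' @param batch_size minibatch size; `NULL` (default) trains full-batch,
#'   which is deterministic and fast at cohort sizes of tens of subjects.
#' @param input_scaling `"counts"` feeds raw histogram counts (default);
#'   `"per_node"` divides each image by its node count.
#' @param seed integer seed for weight initialization and dropout.
#' @return a `cnn_config` list.
#' @export
cnn_config <- function(input_shape = c(10L, 10L, 2L),
                       conv1_maps = 32L, conv2_maps = 128L,
                       kernel = 3L, pool = 2L,
                       fc1_units = 32L, fc2_units = 16L, n_classes = 2L,
                       dropout_rate = 0.25, learning_rate = 0.001,
                       weight_decay = 5e-4, max_epochs = 1000L,
                       early_stop_patience = 50L, min_delta = 0,
                       momentum = 0.1, batch_size = NULL,
                       input_scaling = c("counts", "per_node"),
                       seed = 1L) {
  input_scaling <- match.arg(input_scaling)
  if (length(input_shape) != 3L || any(input_shape < 1L)) {
    stop_param("`input_shape` must be c(rows, cols, channels), all >= 1")
  }
  if (!is_scalar_number(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1) {
    stop_param("`dropout_rate` must lie in [0, 1)")
  }
  for (nm in c("conv1_maps", "conv2_maps", "kernel", "pool", "fc1_units",
               "fc2_units", "n_classes", "max_epochs", "early_stop_patience")) {
    assign(nm, check_count(get(nm), nm))
  }
  if (n_classes < 2L) stop_param("`n_classes` must be >= 2")
  s1 <- input_shape[1L] - (kernel - 1L)
  s2 <- s1 - (kernel - 1L)
  t1 <- input_shape[2L] - (kernel - 1L)
  t2 <- t1 - (kernel - 1L)
  if (s2 < pool || t2 < pool) {
    stop_param(paste0("input %dx%d too small for two valid %dx%d convolutions",
                      " plus %dx%d pooling"),
               input_shape[1L], input_shape[2L], kernel, kernel, pool, pool)
  }
  structure(list(input_shape = as.integer(input_shape),
                 conv1_maps = conv1_maps, conv2_maps = conv2_maps,
                 kernel = kernel, pool = pool,
                 fc1_units = fc1_units, fc2_units = fc2_units,
                 n_classes = n_classes, dropout_rate = dropout_rate,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 max_epochs = max_epochs,
                 early_stop_patience = early_stop_patience,
                 min_delta = min_delta, momentum = momentum,
                 batch_size = if (is.null(batch_size)) NULL else
                   check_count(batch_size, "batch_size"),
                 input_scaling = input_scaling,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "cnn_config")
}

# im2col index map: row p enumerates output positions (row-major in memory,
# i.e. output row index fastest), column q enumerates the k*k*C patch
# entries; values are flat indices into the (H, W, C) column-major layout.
im2col_idx <- function(H, W, C, k) {
  out_h <- H - k + 1L
  out_w <- W - k + 1L
  idx <- matrix(0L, out_h * out_w, k * k * C)
  p <- 0L
  for (j in seq_len(out_w)) {
    for (i in seq_len(out_h)) {
      p <- p + 1L
      q <- 0L
      for (cc in seq_len(C)) {
        for (dj in 0:(k - 1L)) {
          for (di in 0:(k - 1L)) {
            q <- q + 1L
            idx[p, q] <- (i + di) + (j + dj - 1L) * H + (cc - 1L) * H * W
          }
        }
      }
    }
  }
  list(idx = idx, P = out_h * out_w, K = k * k * C,
       out_h = out_h, out_w = out_w)
}

# Max-pool selector: one flat index vector per window position, each of
# length out_h*out_w*M, into the (H, W, M) column-major layout.
pool_idx <- function(H, W, M, pool) {
  out_h <- H %/% pool
  out_w <- W %/% pool
  grid <- expand.grid(i = seq_len(out_h), j = seq_len(out_w), m = seq_len(M))
  sel <- vector("list", pool * pool)
  q <- 0L
  for (b in 0:(pool - 1L)) {
    for (a in 0:(pool - 1L)) {
      q <- q + 1L
      sel[[q]] <- as.integer((grid$i - 1L) * pool + 1L + a +
                             ((grid$j - 1L) * pool + b) * H +
                             (grid$m - 1L) * H * W)
    }
  }
  list(sel = sel, out_h = out_h, out_w = out_w, n_out = out_h * out_w * M)
}

#' Build a CNN model
#'
#' Initializes all layer weights (He-scaled Gaussians, zero biases) from the
#' configured seed and precomputes the layer geometry.  The flatten width is
#' asserted at build time: for the default 10 x 10 x 2 input it must equal
#' 3 * 3 * 128 = 1152.
#'
#' @param cfg a [cnn_config()].
#' @return a `cnn_model` (parameters + geometry + config).
#' @export
build_cnn <- function(cfg = cnn_config()) {
  stopifnot(inherits(cfg, "cnn_config"))
  H <- cfg$input_shape[1L]; W <- cfg$input_shape[2L]; C <- cfg$input_shape[3L]
  im1 <- im2col_idx(H, W, C, cfg$kernel)
  im2 <- im2col_idx(im1$out_h, im1$out_w, cfg$conv1_maps, cfg$kernel)
  pl <- pool_idx(im2$out_h, im2$out_w, cfg$conv2_maps, cfg$pool)
  flat <- pl$n_out
  stopifnot(flat == pl$out_h * pl$out_w * cfg$conv2_maps)
  geom <- list(im1 = im1, im2 = im2, pool = pl, flat = flat)
  he <- function(fan_in, nr, nc) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  params <- with_seed(cfg$seed, list(
    W1 = he(im1$K, im1$K, cfg$conv1_maps), b1 = numeric(cfg$conv1_maps),
    W2 = he(im2$K, im2$K, cfg$conv2_maps), b2 = numeric(cfg$conv2_maps),
    Wf1 = he(flat, flat, cfg$fc1_units),   bf1 = numeric(cfg$fc1_units),
    Wf2 = he(cfg$fc1_units, cfg$fc1_units, cfg$fc2_units),
    bf2 = numeric(cfg$fc2_units),
    Wo = he(cfg$fc2_units, cfg$fc2_units, cfg$n_classes),
    bo = numeric(cfg$n_classes)))
  structure(list(params = params, geom = geom, config = cfg),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cfg <- x$config
  pc <- count_parameters(x)
  cat(sprintf(paste0("<cnn_model> input %s | conv %d>%d (%dx%d valid) | ",
                     "pool %dx%d | fc %d>%d>%d\n  flatten %d units; ",
                     "%d weights (%d with biases)\n"),
              paste(cfg$input_shape, collapse = "x"),
              cfg$conv1_maps, cfg$conv2_maps, cfg$kernel, cfg$kernel,
              cfg$pool, cfg$pool, cfg$fc1_units, cfg$fc2_units,
              cfg$n_classes, x$geom$flat, pc$weights, pc$with_biases))
  invisible(x)
}

#' Count trainable parameters
#'
#' Totals the trainable scalars of a built model, reported both without and
#' with bias terms (layer-by-layer breakdown included), since published
#' parameter totals are often quoted without biases.
#'
#' @param model a `cnn_model`.
#' @return list with `weights`, `with_biases`, and a `by_layer` breakdown.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  p <- model$params
  wts <- c(W1 = length(p$W1), W2 = length(p$W2), Wf1 = length(p$Wf1),
           Wf2 = length(p$Wf2), Wo = length(p$Wo))
  bs <- c(b1 = length(p$b1), b2 = length(p$b2), bf1 = length(p$bf1),
          bf2 = length(p$bf2), bo = length(p$bo))
  list(weights = sum(wts), with_biases = sum(wts) + sum(bs),
       by_layer = list(weights = wts, biases = bs))
}

#' Number of distinct 3x3 kernel slices in the second convolution layer
#'
#' A convolution layer with `m_in` input maps and `m_out` output maps holds
#' `m_in * m_out` distinct spatial kernel slices.
#'
#' @param model a `cnn_model`.
#' @return integer.
#' @export
conv2_kernel_slices <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  model$config$conv1_maps * model$config$conv2_maps
}

relu <- function(x) x * (x > 0)

# Full forward pass.  `train = TRUE` draws inverted-dropout masks from the
# current RNG (placed after conv1, conv2 and FC1 activations) and returns
# every intermediate needed by the backward pass.
cnn_forward <- function(model, X, train = FALSE) {
  g <- model$geom; p <- model$params; cfg <- model$config
  N <- nrow(X)
  dp <- cfg$dropout_rate
  mask <- function(nr, nc) {
    if (!train || dp == 0) return(NULL)
    (matrix(stats::runif(nr * nc), nr, nc) >= dp) / (1 - dp)
  }
  apply_mask <- function(A, m) if (is.null(m)) A else A * m

  Xc1 <- X[, as.vector(g$im1$idx), drop = FALSE]
  dim(Xc1) <- c(N * g$im1$P, g$im1$K)
  Z1 <- Xc1 %*% p$W1
  Z1 <- Z1 + rep(p$b1, each = nrow(Z1))
  m1 <- mask(nrow(Z1), ncol(Z1))
  A1 <- apply_mask(relu(Z1), m1)
  A1r <- A1; dim(A1r) <- c(N, g$im1$P * cfg$conv1_maps)

  Xc2 <- A1r[, as.vector(g$im2$idx), drop = FALSE]
  dim(Xc2) <- c(N * g$im2$P, g$im2$K)
  Z2 <- Xc2 %*% p$W2
  Z2 <- Z2 + rep(p$b2, each = nrow(Z2))
  m2 <- mask(nrow(Z2), ncol(Z2))
  A2 <- apply_mask(relu(Z2), m2)
  A2r <- A2; dim(A2r) <- c(N, g$im2$P * cfg$conv2_maps)

  nq <- length(g$pool$sel)
  slabs <- lapply(g$pool$sel, function(s) A2r[, s, drop = FALSE])
  pooled <- slabs[[1L]]
  if (nq > 1L) for (q in 2:nq) pooled <- pmax(pooled, slabs[[q]])

  Zf1 <- pooled %*% p$Wf1
  Zf1 <- Zf1 + rep(p$bf1, each = N)
  m3 <- mask(N, cfg$fc1_units)
  Af1 <- apply_mask(relu(Zf1), m3)

  Zf2 <- Af1 %*% p$Wf2
  Zf2 <- Zf2 + rep(p$bf2, each = N)
  Af2 <- relu(Zf2)

  Zo <- Af2 %*% p$Wo
  Zo <- Zo + rep(p$bo, each = N)
  Zo <- Zo - apply(Zo, 1L, max)
  E <- exp(Zo)
  probs <- E / rowSums(E)

  list(probs = probs, X = X, Xc1 = Xc1, Z1 = Z1, m1 = m1, A1r = A1r,
       Xc2 = Xc2, Z2 = Z2, m2 = m2, A2r = A2r, slabs = slabs,
       pooled = pooled, Zf1 = Zf1, m3 = m3, Af1 = Af1, Zf2 = Zf2,
       Af2 = Af2)
}

# Backward pass for mean categorical cross-entropy; returns gradients with
# the same names as the parameter list.  `Y` is the one-hot label matrix.
cnn_backward <- function(model, fw, Y) {
  g <- model$geom; p <- model$params; cfg <- model$config
  N <- nrow(Y)
  dZo <- (fw$probs - Y) / N
  gWo <- t(fw$Af2) %*% dZo
  gbo <- colSums(dZo)
  dAf2 <- dZo %*% t(p$Wo)
  dZf2 <- dAf2 * (fw$Zf2 > 0)
  gWf2 <- t(fw$Af1) %*% dZf2
  gbf2 <- colSums(dZf2)
  dAf1 <- dZf2 %*% t(p$Wf2)
  if (!is.null(fw$m3)) dAf1 <- dAf1 * fw$m3
  dZf1 <- dAf1 * (fw$Zf1 > 0)
  gWf1 <- t(fw$pooled) %*% dZf1
  gbf1 <- colSums(dZf1)
  dpooled <- dZf1 %*% t(p$Wf1)

  # route pooled gradients to the (first) argmax within each window
  dA2r <- matrix(0, N, ncol(fw$A2r))
  chosen <- matrix(FALSE, N, ncol(dpooled))
  for (q in seq_along(g$pool$sel)) {
    mk <- (fw$slabs[[q]] == fw$pooled) & !chosen
    dA2r[, g$pool$sel[[q]]] <- dA2r[, g$pool$sel[[q]]] + dpooled * mk
    chosen <- chosen | mk
  }

  dA2 <- dA2r; dim(dA2) <- c(N * g$im2$P, cfg$conv2_maps)
  if (!is.null(fw$m2)) dA2 <- dA2 * fw$m2
  dZ2 <- dA2 * (fw$Z2 > 0)
  gW2 <- t(fw$Xc2) %*% dZ2
  gb2 <- colSums(dZ2)
  dXc2 <- dZ2 %*% t(p$W2)
  dA1r <- matrix(0, N, ncol(fw$A1r))
  dim(dXc2) <- c(N, g$im2$P, g$im2$K)
  for (k in seq_len(g$im2$K)) {
    cols <- g$im2$idx[, k]
    dA1r[, cols] <- dA1r[, cols] + dXc2[, , k]
  }

  dA1 <- dA1r; dim(dA1) <- c(N * g$im1$P, cfg$conv1_maps)
  if (!is.null(fw$m1)) dA1 <- dA1 * fw$m1
  dZ1 <- dA1 * (fw$Z1 > 0)
  gW1 <- t(fw$Xc1) %*% dZ1
  gb1 <- colSums(dZ1)

  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, Wf1 = gWf1, bf1 = gbf1,
       Wf2 = gWf2, bf2 = gbf2, Wo = gWo, bo = gbo)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Labeled image set
#'
#' Bundles graph images with binary class labels.  The class encoding is
#' fixed: factor levels `c("control", "case")`, one-hot in that order.
#'
#' @param images either a numeric array `N x r x r x channels` or a list of
#'   `graph_image` objects of identical shape.
#' @param labels character/factor of length `N` over
#'   `{"control", "case"}`.
#' @param subject_ids optional identifiers (default `s001`, ...).
#' @return a `labeled_image_set`.
#' @export
labeled_image_set <- function(images, labels, subject_ids = NULL) {
  if (is.list(images)) {
    d <- dim(images[[1L]])
    arr <- array(0, dim = c(length(images), d))
    for (i in seq_along(images)) arr[i, , , ] <- unclass(images[[i]])
    images <- arr
  }
  if (length(dim(images)) != 4L) {
    stop_param("`images` must be an N x rows x cols x channels array")
  }
  n <- dim(images)[1L]
  if (n < 2L) stop_param("need >= 2 images")
  if (min(images) < 0) stop_param("images must be non-negative")
  labels <- factor(as.character(labels), levels = c("control", "case"))
  if (any(is.na(labels))) stop_param("labels must be 'control' or 'case'")
  if (length(labels) != n) stop_param("labels length mismatch")
  if (is.null(subject_ids)) subject_ids <- sprintf("s%03d", seq_len(n))
  structure(list(images = images, labels = labels,
                 subject_ids = as.character(subject_ids)),
            class = "labeled_image_set")
}

subset_image_set <- function(set, idx) {
  labeled_image_set(set$images[idx, , , , drop = FALSE], set$labels[idx],
                    set$subject_ids[idx])
}

# Flatten an image array into the N x (r*r*C) matrix layout the forward
# pass expects, applying the configured input scaling.
set_matrix <- function(set, cfg) {
  X <- set$images
  dims <- dim(X)
  dim(X) <- c(dims[1L], prod(dims[-1L]))
  if (cfg$input_scaling == "per_node") {
    per_chan <- prod(dims[2:3])
    n_nodes <- rowSums(X[, seq_len(per_chan), drop = FALSE])
    X <- X / pmax(n_nodes, 1)
  }
  X
}

one_hot <- function(labels, n_classes) {
  Y <- matrix(0, length(labels), n_classes)
  Y[cbind(seq_along(labels), as.integer(labels))] <- 1
  Y
}

eval_loss_acc <- function(model, X, Y) {
  fw <- cnn_forward(model, X, train = FALSE)
  loss <- -mean(log(pmax(rowSums(fw$probs * Y), 1e-300)))
  acc <- mean(max.col(fw$probs, ties.method = "first") == max.col(Y))
  list(loss = loss, acc = acc)
}

#' Train a CNN on labeled graph images
#'
#' Minimizes categorical cross-entropy with Adam plus an L2 penalty on all
#' weight matrices.  Dropout is active only during training forward passes.
#' After each epoch the validation loss is evaluated; training stops at
#' `max_epochs` or once the validation loss has failed to improve by
#' `min_delta` for `early_stop_patience` consecutive epochs, and the weights
#' with the best validation loss are restored.  Fully reproducible under the
#' configured seed.
#'
#' @param model a `cnn_model` from [build_cnn()].
#' @param train_set,val_set [labeled_image_set()] objects; training requires
#'   both classes present in `train_set`.
#' @param cfg optional [cnn_config()] override (defaults to the model's).
#' @return list with the trained `model` and a `history` object (class
#'   `train_history`): per-epoch training loss, validation loss/accuracy,
#'   `stopped_epoch`, and `best_epoch`.
#' @export
train_cnn <- function(model, train_set, val_set, cfg = model$config) {
  stopifnot(inherits(model, "cnn_model"),
            inherits(train_set, "labeled_image_set"),
            inherits(val_set, "labeled_image_set"))
  if (length(unique(train_set$labels)) < 2L) {
    stop_param("training set contains a single class")
  }
  X <- set_matrix(train_set, cfg)
  Y <- one_hot(train_set$labels, cfg$n_classes)
  Xv <- set_matrix(val_set, cfg)
  Yv <- one_hot(val_set$labels, cfg$n_classes)
  N <- nrow(X)
  bs <- if (is.null(cfg$batch_size)) N else min(cfg$batch_size, N)

  params <- model$params
  state <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- matrix(NA_real_, cfg$max_epochs, 3L,
                 dimnames = list(NULL, c("train_loss", "val_loss", "val_acc")))
  stopped <- cfg$max_epochs
  wait <- 0L

  with_seed(derive_seed(cfg$seed, "cnn-train"), {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- if (bs < N) sample.int(N) else seq_len(N)
      tr_loss <- 0
      for (s in seq(1L, N, by = bs)) {
        take <- ord[s:min(s + bs - 1L, N)]
        m <- model; m$params <- params
        fw <- cnn_forward(m, X[take, , drop = FALSE], train = TRUE)
        Yb <- Y[take, , drop = FALSE]
        tr_loss <- tr_loss -
          sum(log(pmax(rowSums(fw$probs * Yb), 1e-300)))
        grads <- cnn_backward(m, fw, Yb)
        for (nm in c("W1", "W2", "Wf1", "Wf2", "Wo")) {
          grads[[nm]] <- grads[[nm]] + cfg$weight_decay * params[[nm]]
        }
        upd <- adam_step(params, grads, state, cfg$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      m <- model; m$params <- params
      vl <- eval_loss_acc(m, Xv, Yv)
      hist[epoch, ] <- c(tr_loss / N, vl$loss, vl$acc)
      if (vl$loss < best$loss - cfg$min_delta) {
        best <- list(loss = vl$loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$early_stop_patience) {
          stopped <- epoch
          break
        }
      }
    }
  })
  model$params <- best$params
  history <- structure(
    list(metrics = tibble::tibble(
           epoch = seq_len(stopped),
           train_loss = hist[seq_len(stopped), "train_loss"],
           val_loss = hist[seq_len(stopped), "val_loss"],
           val_acc = hist[seq_len(stopped), "val_acc"]),
         stopped_epoch = stopped, best_epoch = best$epoch,
         best_val_loss = best$loss),
    class = "train_history")
  list(model = model, history = history)
}

#' Predict class probabilities for graph images
#'
#' Deterministic (dropout-free) forward pass; per image, the two class
#' probabilities sum to 1 and the hard label is the argmax.
#'
#' @param object a trained `cnn_model`.
#' @param images a [labeled_image_set()] or an `N x r x r x channels` array.
#' @param ... unused.
#' @return a tibble with one row per image: `subject_id`, one probability
#'   column per class (`prob_control`, `prob_case`), and `pred_class`.
#' @export
predict.cnn_model <- function(object, images, ...) {
  if (inherits(images, "labeled_image_set")) {
    set <- images
  } else {
    if (length(dim(images)) == 3L) {
      images <- array(images, dim = c(1L, dim(images)))
    }
    n <- dim(images)[1L]
    set <- structure(list(images = images,
                          labels = factor(rep(c("control", "case"),
                                              length.out = n),
                                          levels = c("control", "case")),
                          subject_ids = sprintf("s%03d", seq_len(n))),
                     class = "labeled_image_set")
  }
  expect <- object$config$input_shape
  got <- dim(set$images)[-1L]
  if (!all(got == expect)) {
    stop_param("image shape %s does not match model input %s",
               paste(got, collapse = "x"), paste(expect, collapse = "x"))
  }
  X <- set_matrix(set, object$config)
  fw <- cnn_forward(object, X, train = FALSE)
  cls <- c("control", "case")
  tibble::tibble(
    subject_id = set$subject_ids,
    prob_control = fw$probs[, 1L],
    prob_case = fw$probs[, 2L],
    pred_class = factor(cls[max.col(fw$probs, ties.method = "first")],
                        levels = cls))
}

#' Assemble a cross-validation result
#'
#' Constructor used by [cross_validate()] and the pipeline; also handy for
#' summarizing externally obtained fold accuracies (the mean accuracy is
#' always recomputed as the plain mean of the folds).
#'
#' @param fold_results tibble with at least `iteration`, `fold`, `accuracy`.
#' @param histories optional list of `train_history` objects.
#' @param k,iterations fold count and repeat count.
#' @return a `cv_result`.
#' @export
new_cv_result <- function(fold_results, histories = list(), k = NA_integer_,
                          iterations = NA_integer_) {
  stopifnot(all(c("iteration", "fold", "accuracy") %in% names(fold_results)))
  structure(list(fold_results = tibble::as_tibble(fold_results),
                 mean_accuracy = mean(fold_results$accuracy),
                 histories = histories, k = k, iterations = iterations),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s-fold x %s iteration(s): mean accuracy %.4f\n",
              x$k, x$iterations, x$mean_accuracy))
  print(x$fold_results)
  invisible(x)
}

# Random partition into k near-equal folds (sizes differ by at most 1).
make_folds <- function(n, k) {
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split(sample.int(n), rep(seq_len(k), times = sizes))
}

#' k-fold cross-validation of the CNN
#'
#' Per iteration: a fresh random partition of the subjects into `k`
#' near-equal folds; each fold serves once as the held-out test set while a
#' freshly initialized model (new seed from the seed stream) is trained on
#' the rest.  By default the held-out fold also drives early stopping
#' (`inner_val = FALSE`); `inner_val = TRUE` instead carves a stratified
#' validation split out of the training folds so the test fold stays unseen
#' until evaluation.  The summary accuracy is the plain mean of all fold
#' accuracies over all iterations.
#'
#' @param data a [labeled_image_set()].
#' @param k number of folds (`2 <= k <= N`).
#' @param iterations number of independent repetitions of the full k-fold
#'   procedure.
#' @param cfg a [cnn_config()].
#' @param seed master seed for partitioning and per-fold model seeds.
#' @param inner_val use an inner validation split for early stopping.
#' @return a `cv_result`: per-fold accuracies (tibble), `mean_accuracy`, and
#'   the per-fold training histories.
#' @export
cross_validate <- function(data, k = 4L, iterations = 1L, cfg = cnn_config(),
                           seed = 1L, inner_val = FALSE) {
  stopifnot(inherits(data, "labeled_image_set"))
  n <- length(data$labels)
  k <- check_count(k, "k", min = 2L)
  if (k > n) stop_param("k = %d exceeds the number of subjects (%d)", k, n)
  iterations <- check_count(iterations, "iterations")
  rows <- list(); hists <- list(); r <- 0L
  for (it in seq_len(iterations)) {
    folds <- with_seed(derive_seed(seed, sprintf("cv-partition-%03d", it)),
                       make_folds(n, k))
    for (f in seq_len(k)) {
      test_idx <- folds[[f]]
      train_idx <- setdiff(seq_len(n), test_idx)
      fold_cfg <- cfg
      fold_cfg$seed <- derive_seed(seed, sprintf("cv-model-%03d-%02d", it, f))
      test_set <- subset_image_set(data, test_idx)
      if (inner_val) {
        val_idx <- with_seed(
          derive_seed(seed, sprintf("cv-val-%03d-%02d", it, f)), {
            by_class <- split(train_idx, data$labels[train_idx])
            unlist(lapply(by_class, function(ix) {
              sample(ix, max(1L, round(length(ix) / 5)))
            }), use.names = FALSE)
          })
        fit_idx <- setdiff(train_idx, val_idx)
        fit <- train_cnn(build_cnn(fold_cfg),
                         subset_image_set(data, fit_idx),
                         subset_image_set(data, val_idx), fold_cfg)
      } else {
        fit <- train_cnn(build_cnn(fold_cfg),
                         subset_image_set(data, train_idx),
                         test_set, fold_cfg)
      }
      pred <- stats::predict(fit$model, test_set)
      r <- r + 1L
      rows[[r]] <- tibble::tibble(
        iteration = it, fold = f, n_test = length(test_idx),
        accuracy = mean(pred$pred_class == test_set$labels),
        stopped_epoch = fit$history$stopped_epoch,
        best_epoch = fit$history$best_epoch)
      hists[[r]] <- fit$history
    }
  }
  new_cv_result(do.call(rbind, rows), hists, k = k, iterations = iterations)
}
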