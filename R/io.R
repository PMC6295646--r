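# Plain-text interchange formats: self-describing (headers), diffable,
# locale-independent (period decimal separator), and byte-stable across
# reruns so pipeline determinism can be checked on the artifacts themselves.
# All writers round-trip doubles well within 1e-9.

read_lines_checked <- function(path) {
  if (!file.exists(path)) stop_param("file not found: %s", path)
  readLines(path, warn = FALSE)
}

parse_error <- function(path, line, msg) {
  stop_param("parse error in %s, line %d: %s", path, line, msg)
}

split_fields <- function(line) strsplit(line, "\t", fixed = TRUE)[[1L]]

num_fields <- function(x, path, line) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) parse_error(path, line, sprintf("non-numeric field '%s'",
                                                x[which(is.na(v))[1L]]))
  v
}

#' Write / read a multichannel recording
#'
#' Tab-separated text: a `#sampling_rate=<Hz>` header line, then one row per
#' channel (`channel_id` followed by the samples).
#'
#' @param rec a [recording()].
#' @param path file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a [recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  rows <- vapply(seq_len(nrow(rec$samples)), function(i) {
    paste(c(rec$channel_ids[i], fmt_num(rec$samples[i, ])), collapse = "\t")
  }, "")
  writeLines(c(sprintf("#sampling_rate=%s", fmt_num(rec$sampling_rate)), rows),
             path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  lines <- read_lines_checked(path)
  if (length(lines) < 3L) parse_error(path, length(lines),
                                      "expected header + >= 2 channel rows")
  if (!startsWith(lines[1L], "#sampling_rate=")) {
    parse_error(path, 1L, "missing '#sampling_rate=' header")
  }
  fs <- as.numeric(sub("#sampling_rate=", "", lines[1L], fixed = TRUE))
  if (is.na(fs)) parse_error(path, 1L, "bad sampling rate")
  ids <- character(); vals <- list()
  width <- NA_integer_
  for (i in 2:length(lines)) {
    f <- split_fields(lines[i])
    if (length(f) < 3L) parse_error(path, i, "row too short")
    if (is.na(width)) width <- length(f)
    if (length(f) != width) parse_error(path, i, "ragged row")
    ids <- c(ids, f[1L])
    vals[[length(vals) + 1L]] <- num_fields(f[-1L], path, i)
  }
  recording(do.call(rbind, vals), fs, ids)
}

#' Write / read a square adjacency matrix
#'
#' Tab-separated: a header row of node ids, then one row per node
#' (`node_id` followed by the weights).
#'
#' @param graph a [connectivity_graph()].
#' @param path file path.
#' @return `write_adjacency` returns `path` invisibly; `read_adjacency`
#'   returns a [connectivity_graph()].
#' @export
write_adjacency <- function(graph, path) {
  stopifnot(inherits(graph, "connectivity_graph"))
  hdr <- paste(c("node_id", graph$node_ids), collapse = "\t")
  rows <- vapply(seq_along(graph$node_ids), function(i) {
    paste(c(graph$node_ids[i], fmt_num(graph$weights[i, ])), collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  lines <- read_lines_checked(path)
  if (length(lines) < 2L) parse_error(path, length(lines), "no data rows")
  hdr <- split_fields(lines[1L])
  if (hdr[1L] != "node_id") parse_error(path, 1L, "missing 'node_id' header")
  ids <- hdr[-1L]
  n <- length(ids)
  if (length(lines) - 1L != n) {
    parse_error(path, length(lines),
                sprintf("expected %d data rows, found %d", n,
                        length(lines) - 1L))
  }
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    f <- split_fields(lines[i + 1L])
    if (length(f) != n + 1L) parse_error(path, i + 1L, "ragged row")
    if (f[1L] != ids[i]) parse_error(path, i + 1L, "row id does not match header order")
    w[i, ] <- num_fields(f[-1L], path, i + 1L)
  }
  connectivity_graph(w, ids)
}

#' Write / read a weighted edge list
#'
#' Upper-triangle positive-weight edges as `node_a TAB node_b TAB weight`,
#' preceded by a `#nodes=` header carrying the full node order (so isolated
#' nodes survive the round trip); the reader reconstructs the full symmetric
#' matrix.
#'
#' @param graph a [connectivity_graph()].
#' @param path file path.
#' @return `write_edge_list` returns `path` invisibly; `read_edge_list`
#'   returns a [connectivity_graph()].
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "connectivity_graph"))
  n <- length(graph$node_ids)
  ut <- which(upper.tri(graph$weights) & graph$weights > 0, arr.ind = TRUE)
  rows <- vapply(seq_len(nrow(ut)), function(r) {
    i <- ut[r, 1L]; j <- ut[r, 2L]
    paste(graph$node_ids[i], graph$node_ids[j],
          fmt_num(graph$weights[i, j]), sep = "\t")
  }, "")
  writeLines(c(sprintf("#nodes=%s", paste(graph$node_ids, collapse = ",")),
               rows), path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  lines <- read_lines_checked(path)
  if (!startsWith(lines[1L], "#nodes=")) {
    parse_error(path, 1L, "missing '#nodes=' header")
  }
  ids <- strsplit(sub("#nodes=", "", lines[1L], fixed = TRUE), ",",
                  fixed = TRUE)[[1L]]
  n <- length(ids)
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  if (length(lines) > 1L) {
    for (ln in 2:length(lines)) {
      f <- split_fields(lines[ln])
      if (length(f) != 3L) parse_error(path, ln, "expected 3 fields")
      i <- match(f[1L], ids); j <- match(f[2L], ids)
      if (is.na(i) || is.na(j)) parse_error(path, ln, "unknown node id")
      w[i, j] <- w[j, i] <- num_fields(f[3L], path, ln)
    }
  }
  connectivity_graph(w, ids)
}

#' Write / read an embedding table
#'
#' Tab-separated: header `node_id dim01 ... dimNN`, then one row per node.
#'
#' @param emb an `embedding_matrix` (or any numeric matrix with rownames).
#' @param path file path.
#' @return `write_embedding` returns `path` invisibly; `read_embedding`
#'   returns an `embedding_matrix`.
#' @export
write_embedding <- function(emb, path) {
  emb <- as.matrix(emb)
  ids <- rownames(emb)
  if (is.null(ids)) ids <- sprintf("n%03d", seq_len(nrow(emb)))
  hdr <- paste(c("node_id", sprintf("dim%02d", seq_len(ncol(emb)))),
               collapse = "\t")
  rows <- vapply(seq_len(nrow(emb)), function(i) {
    paste(c(ids[i], fmt_num(emb[i, ])), collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  lines <- read_lines_checked(path)
  if (length(lines) < 2L) parse_error(path, length(lines), "no data rows")
  hdr <- split_fields(lines[1L])
  if (hdr[1L] != "node_id") parse_error(path, 1L, "missing 'node_id' header")
  d <- length(hdr) - 1L
  ids <- character(length(lines) - 1L)
  m <- matrix(0, length(lines) - 1L, d)
  for (i in 2:length(lines)) {
    f <- split_fields(lines[i])
    if (length(f) != d + 1L) parse_error(path, i, "ragged row")
    ids[i - 1L] <- f[1L]
    m[i - 1L, ] <- num_fields(f[-1L], path, i)
  }
  dimnames(m) <- list(ids, hdr[-1L])
  class(m) <- c("embedding_matrix", class(m))
  m
}

#' Write / read a graph image tensor
#'
#' Channel-blocked text: for each channel a `#channel=<c>` line followed by
#' `r` rows of `r` tab-separated integer counts.
#'
#' @param img a `graph_image` from [graph_to_image()].
#' @param path file path.
#' @return `write_graph_image` returns `path` invisibly; `read_graph_image`
#'   returns a `graph_image`.
#' @export
write_graph_image <- function(img, path) {
  stopifnot(inherits(img, "graph_image"))
  d <- dim(img)
  out <- character(0L)
  for (c in seq_len(d[3L])) {
    out <- c(out, sprintf("#channel=%d", c),
             apply(unclass(img)[, , c], 1L, paste, collapse = "\t"))
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_graph_image
#' @export
read_graph_image <- function(path) {
  lines <- read_lines_checked(path)
  chan_at <- which(startsWith(lines, "#channel="))
  if (length(chan_at) == 0L) parse_error(path, 1L, "no '#channel=' blocks")
  r <- if (length(chan_at) > 1L) chan_at[2L] - chan_at[1L] - 1L else
    length(lines) - chan_at[1L]
  img <- array(0L, dim = c(r, r, length(chan_at)))
  for (ci in seq_along(chan_at)) {
    for (row in seq_len(r)) {
      ln <- chan_at[ci] + row
      if (ln > length(lines)) parse_error(path, length(lines), "truncated channel block")
      f <- split_fields(lines[ln])
      if (length(f) != r) parse_error(path, ln, "ragged image row")
      img[row, , ci] <- as.integer(num_fields(f, path, ln))
    }
  }
  structure(img, n_nodes = sum(img[, , 1L]), class = "graph_image")
}

#' Write results as JSON
#'
#' Versioned schema, auto-unboxed scalars, full double precision.
#'
#' @param x a list (e.g. a summarized `cv_result`).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(x, path) {
  x$schema_version <- x$schema_version %||% "1.0"
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a pipeline configuration as YAML
#'
#' @param config a named list (see [pipeline_config()]).
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_param("config file not found: %s", path)
  yaml::read_yaml(path)
}
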