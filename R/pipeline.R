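# Pipeline orchestration: connectivity -> embedding -> imaging -> classifier,
# persisting every intermediate as plain text, with one master seed feeding
# named per-stage, per-subject seed streams.

#' Assemble a pipeline configuration
#'
#' Collects every stage's settings plus a master seed.  Cross-field
#' consistency (d_pca below the embedding dimension; the CNN input shape
#' matching `r` and `d_pca / 2`) is enforced here, before any stage runs.
#'
#' @param band optional `c(low_hz, high_hz)` band-pass applied before phase
#'   extraction (`NULL` = none; the analyzed band is a user choice).
#' @param epoch_length optional PLI epoch length in samples.
#' @param walk a [walk_config()] (its seed field is overridden by derived
#'   per-subject seeds).
#' @param skipgram a [skipgram_config()] (seed likewise derived).
#' @param d_pca,r imaging settings (see [graph_to_image()]).
#' @param cnn a [cnn_config()]; its `input_shape` must equal
#'   `c(r, r, d_pca / 2)`.
#' @param cv_k,cv_iterations cross-validation settings.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(band = NULL, epoch_length = NULL,
                            walk = walk_config(), skipgram = skipgram_config(),
                            d_pca = 4L, r = 10L,
                            cnn = NULL, cv_k = 4L, cv_iterations = 1L,
                            seed = 1L) {
  d_pca <- check_count(d_pca, "d_pca", min = 2L)
  if (d_pca %% 2L != 0L) stop_param("`d_pca` must be even")
  if (d_pca >= skipgram$dim) {
    stop_param("`d_pca` (%d) must be < embedding dim (%d)", d_pca, skipgram$dim)
  }
  r <- check_count(r, "r")
  if (is.null(cnn)) cnn <- cnn_config(input_shape = c(r, r, d_pca %/% 2L))
  if (!all(cnn$input_shape == c(r, r, d_pca %/% 2L))) {
    stop_param("CNN input shape %s does not match r = %d, d_pca/2 = %d",
               paste(cnn$input_shape, collapse = "x"), r, d_pca %/% 2L)
  }
  structure(list(band = band, epoch_length = epoch_length, walk = walk,
                 skipgram = skipgram, d_pca = d_pca, r = r, cnn = cnn,
                 cv_k = check_count(cv_k, "cv_k", min = 2L),
                 cv_iterations = check_count(cv_iterations, "cv_iterations"),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "pipeline_config")
}

config_snapshot <- function(config) {
  drop_class <- function(x) {
    if (is.list(x)) lapply(unclass(x), drop_class) else x
  }
  drop_class(config)
}

#' Run the full classification pipeline
#'
#' Executes connectivity, embedding, imaging, and cross-validated
#' classification on a labeled cohort, persisting each intermediate
#' (adjacency matrices, embedding tables, image tensors) plus a JSON summary
#' and the configuration snapshot under `out_dir`.  Any earlier stage is
#' skipped when its output is supplied directly: pass `recordings` to run
#' everything, `graphs` to skip connectivity, or `images` to go straight to
#' the classifier.
#'
#' @param config a [pipeline_config()].
#' @param labels class labels (control/case), one per subject.
#' @param recordings list of [recording()] objects (stage 1 input).
#' @param graphs list of [connectivity_graph()] objects (skips stage 1).
#' @param images list of `graph_image` objects (skips stages 1-3).
#' @param subject_ids optional ids; default `s001`, ...
#' @param out_dir output directory (`NULL` = keep everything in memory).
#' @return a `cv_result`, with the labeled image set attached as attribute
#'   `image_set`.
#' @export
run_pipeline <- function(config, labels, recordings = NULL, graphs = NULL,
                         images = NULL, subject_ids = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  n <- length(labels)
  if (n < 2L) stop_param("pipeline needs >= 2 subjects")
  if (is.null(subject_ids)) subject_ids <- sprintf("s%03d", seq_len(n))
  persist <- !is.null(out_dir)
  if (persist) {
    for (d in c("networks", "embeddings", "images")) {
      dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
    }
    write_config(config_snapshot(config), file.path(out_dir, "config.yaml"))
  }
  seed_log <- list(master = config$seed)

  if (is.null(images)) {
    if (is.null(graphs)) {
      if (is.null(recordings)) {
        stop_param("connectivity stage: no input (supply recordings, graphs, or images)")
      }
      if (length(recordings) != n) {
        stop_param("connectivity stage: %d recordings for %d labels",
                   length(recordings), n)
      }
      graphs <- lapply(seq_len(n), function(i) {
        build_network(recordings[[i]], band = config$band,
                      epoch_length = config$epoch_length)
      })
    }
    if (length(graphs) != n) {
      stop_param("embedding stage: %d graphs for %d labels", length(graphs), n)
    }
    if (persist) {
      for (i in seq_len(n)) {
        write_adjacency(graphs[[i]],
                        file.path(out_dir, "networks",
                                  paste0(subject_ids[i], ".tsv")))
      }
    }
    images <- vector("list", n)
    for (i in seq_len(n)) {
      wcfg <- config$walk
      scfg <- config$skipgram
      wcfg$seed <- derive_seed(config$seed, sprintf("walks-%s", subject_ids[i]))
      scfg$seed <- derive_seed(config$seed, sprintf("skipgram-%s", subject_ids[i]))
      seed_log[[paste0("walks_", subject_ids[i])]] <- wcfg$seed
      seed_log[[paste0("skipgram_", subject_ids[i])]] <- scfg$seed
      emb <- node2vec(graphs[[i]], wcfg, scfg)
      if (persist) {
        write_embedding(emb, file.path(out_dir, "embeddings",
                                       paste0(subject_ids[i], ".tsv")))
      }
      images[[i]] <- graph_to_image(emb, d_pca = config$d_pca, r = config$r)
    }
  }
  if (length(images) != n) {
    stop_param("classifier stage: %d images for %d labels", length(images), n)
  }
  if (persist) {
    for (i in seq_len(n)) {
      write_graph_image(images[[i]],
                        file.path(out_dir, "images",
                                  paste0(subject_ids[i], ".tsv")))
    }
    manifest <- vapply(seq_len(n), function(i) {
      paste(subject_ids[i], as.character(labels[i]),
            file.path("images", paste0(subject_ids[i], ".tsv")), sep = "\t")
    }, "")
    writeLines(c("subject_id\tlabel\tpath", manifest),
               file.path(out_dir, "manifest.tsv"))
  }

  set <- labeled_image_set(images, labels, subject_ids)
  cv_seed <- derive_seed(config$seed, "cross-validation")
  seed_log$cross_validation <- cv_seed
  res <- cross_validate(set, k = config$cv_k,
                        iterations = config$cv_iterations,
                        cfg = config$cnn, seed = cv_seed)
  if (persist) {
    write_results_json(list(
      mean_accuracy = res$mean_accuracy,
      fold_accuracies = res$fold_results$accuracy,
      stopped_epochs = res$fold_results$stopped_epoch,
      k = res$k, iterations = res$iterations,
      seeds = seed_log,
      r_version = as.character(getRversion())),
      file.path(out_dir, "results.json"))
  }
  attr(res, "image_set") <- set
  res
}
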