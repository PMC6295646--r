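# broom-style tidiers and plot methods for the tabular result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a cross-validation result
#'
#' One row per fold per iteration, with the held-out accuracy and the epoch
#' at which training stopped.
#'
#' @param x a `cv_result` from [cross_validate()] or [run_pipeline()].
#' @param ... unused.
#' @return a tibble.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$fold_results

#' One-row summary of a cross-validation result
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return a tibble with `mean_accuracy`, `sd_accuracy`, `k`, `iterations`,
#'   `n_folds`.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean_accuracy,
                 sd_accuracy = stats::sd(x$fold_results$accuracy),
                 k = x$k, iterations = x$iterations,
                 n_folds = nrow(x$fold_results))
}

#' Tidy a training history
#'
#' @param x a `train_history` from [train_cnn()].
#' @param ... unused.
#' @return the per-epoch metrics tibble.
#' @method tidy train_history
#' @export
tidy.train_history <- function(x, ...) x$metrics

#' Plot fold accuracies
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- object$fold_results
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold),
                                   y = .data$accuracy)) +
    ggplot2::geom_point(ggplot2::aes(color = factor(.data$iteration)),
                        size = 2) +
    ggplot2::geom_hline(yintercept = object$mean_accuracy, linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "fold", y = "held-out accuracy", color = "iteration") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Training/validation loss and validation accuracy per epoch.
#'
#' @param object a `train_history`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot train_history
#' @export
autoplot.train_history <- function(object, ...) {
  m <- object$metrics
  long <- tibble::tibble(
    epoch = rep(m$epoch, 3L),
    metric = rep(c("train_loss", "val_loss", "val_acc"), each = nrow(m)),
    value = c(m$train_loss, m$val_loss, m$val_acc))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1L) +
    ggplot2::theme_minimal()
}
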