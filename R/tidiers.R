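#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a training history
#'
#' @param x A `metaug_history`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_f1`.
#' @exportS3Method generics::tidy
tidy.metaug_history <- function(x, ...) x$epochs

#' One-row summary of a training history
#'
#' @param x A `metaug_history`.
#' @param ... Unused.
#' @return Tibble with `n_epochs`, `best_epoch`, `best_validation_f1`,
#'   `final_train_loss`.
#' @exportS3Method generics::glance
glance.metaug_history <- function(x, ...) {
  tibble::tibble(
    n_epochs = nrow(x$epochs),
    best_epoch = x$best_epoch,
    best_validation_f1 = x$best_validation_f1,
    final_train_loss = if (nrow(x$epochs)) x$epochs$train_loss[nrow(x$epochs)]
                       else NA_real_
  )
}

#' @exportS3Method generics::tidy
tidy.metaug_fit <- function(x, ...) tidy(x$history)

#' @exportS3Method generics::glance
glance.metaug_fit <- function(x, ...) glance(x$history)

#' Tidy a multi-seed sweep
#'
#' @param x A `metaug_sweep`.
#' @param ... Unused.
#' @return Per-seed tibble.
#' @exportS3Method generics::tidy
tidy.metaug_sweep <- function(x, ...) x$results

#' One-row summary of a multi-seed sweep
#'
#' @param x A `metaug_sweep`.
#' @param ... Unused.
#' @return Tibble with `n_seeds`, `mean_f1`, `sd_f1`, `best_f1`.
#' @exportS3Method generics::glance
glance.metaug_sweep <- function(x, ...) {
  tibble::tibble(n_seeds = nrow(x$results), mean_f1 = x$mean,
                 sd_f1 = x$sd, best_f1 = x$best)
}

#' @exportS3Method generics::tidy
tidy.metaug_selection <- function(x, ...) {
  tibble::tibble(report_id = x$selected_report_ids, strategy = x$strategy)
}

#' @exportS3Method generics::glance
glance.metaug_selection <- function(x, ...) {
  tibble::tibble(strategy = x$strategy,
                 n_selected = length(x$selected_report_ids),
                 replication_factor = x$replication_factor)
}

#' @exportS3Method generics::tidy
tidy.metaug_benchmark <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.metaug_benchmark <- function(x, ...) {
  tidyr::pivot_wider(x$summary[, c("arm", "mean_f1")],
                     names_from = "arm", values_from = "mean_f1")
}

#' Plot a training history
#'
#' Training loss and validation F1 per epoch, with the selected best
#' epoch marked.
#'
#' @param object A `metaug_history` (or `metaug_fit`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.metaug_history <- function(object, ...) {
  df <- tidyr::pivot_longer(object$epochs, c("train_loss", "val_f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training loss and validation F1") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.metaug_fit <- function(object, ...) autoplot(object$history, ...)

#' Plot a multi-seed sweep
#'
#' @param object A `metaug_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.metaug_sweep <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = factor(.data$seed), y = .data$test_f1)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$mean, linetype = 2) +
    ggplot2::labs(x = "seed", y = "test F1",
                  title = sprintf("Mean F1 %.3f (sd %.3f), best %.3f",
                                  object$mean, object$sd, object$best)) +
    ggplot2::theme_minimal()
}

#' Plot a directional benchmark
#'
#' Test F1 per arm and seed.
#'
#' @param object A `metaug_benchmark` from [da_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.metaug_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$arm, y = .data$f1)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$seed)), size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4) +
    ggplot2::labs(x = NULL, y = "test F1", colour = "seed",
                  title = "Augmentation benchmark (per-seed test F1)") +
    ggplot2::theme_minimal()
}
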