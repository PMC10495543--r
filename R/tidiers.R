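# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a model fit into its training history
#'
#' @param x A `readformer_fit`.
#' @param ... Unused.
#' @return The history tibble (step, epoch, train/validation loss, per-level
#'   validation accuracy).
#' @export
tidy.readformer_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a model fit
#'
#' @param x A `readformer_fit`.
#' @param ... Unused.
#' @return A one-row tibble: steps run, best step, best validation loss,
#'   wall time and parameter count.
#' @export
glance.readformer_fit <- function(x, ...) {
  tibble::tibble(steps = x$steps, best_step = x$best_step,
                 best_val_loss = x$best_val_loss,
                 wall_time_s = x$wall_time, n_params = n_params(x$model))
}

#' Tidy a metrics report into per-class rows
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return The per-class tibble.
#' @export
tidy.metrics_report <- function(x, ...) {
  x$per_class
}

#' One-row summary of a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return A one-row tibble with `precision_<level>` / `recall_<level>`
#'   columns.
#' @export
glance.metrics_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$overall[, c("level", "precision", "recall")],
    names_from = "level", values_from = c("precision", "recall"))
  wide
}

#' Tidy a simulated taxonomy
#'
#' @param x A `sim_taxonomy`.
#' @param ... Unused.
#' @return Tibble of genomes (`species_id`, `genus_id`, `length`).
#' @export
tidy.sim_taxonomy <- function(x, ...) {
  x$genomes[, c("species_id", "genus_id", "length")]
}

#' Plot training history
#'
#' @param object A `readformer_fit`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss over optimization steps.
#' @export
autoplot.readformer_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history[, c("step", "train_loss",
                                              "val_loss")],
                           -"step", names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$step, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_step, linetype = "dashed") +
    ggplot2::labs(x = "optimization step", y = "cross-entropy loss",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an abundance profile
#'
#' @param object An `abundance_profile`.
#' @param ... Unused.
#' @return A ggplot of per-class read fractions, faceted by level.
#' @export
autoplot.abundance_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$class_id,
                                       y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~level, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "read fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
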