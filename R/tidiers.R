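# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.smmf_fit <- function(x, ...) x$history

#' @export
glance.smmf_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h), best_epoch = x$best_epoch,
                 train_loss = h$train_loss[nrow(h)],
                 val_loss = h$val_loss[nrow(h)],
                 val_accuracy = h$val_accuracy[nrow(h)])
}

#' @export
tidy.smmf_cv <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.smmf_cv <- function(x, ...) {
  s <- attr(x, "summary")
  tidyr::pivot_wider(s, names_from = "metric", values_from = c("mean", "var"),
                     names_glue = "{metric}_{.value}")
}

#' @export
tidy.smmf_experiment <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.smmf_experiment <- function(x, ...) attr(x, "summary")

#' @export
autoplot.smmf_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.smmf_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::any_of(c("accuracy", "f1", "auc")),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$fold), y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "fold", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.smmf_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::any_of(c("accuracy", "f1", "auc")),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$arm, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a 2-D embedding
#' @param embedding Tibble from [tsne_embed()].
#' @export
plot_embedding <- function(embedding) {
  ggplot2::ggplot(embedding,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = factor(.data$label))) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(colour = "class") +
    ggplot2::theme_minimal()
}
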