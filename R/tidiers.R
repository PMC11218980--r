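#' Tidy a training fit
#'
#' @param x A `vit_fit` from [vit_train()].
#' @param ... Unused.
#' @return The per-epoch history tibble (`epoch`, `train_loss`,
#'   `train_acc`, `test_loss`, `test_acc`).
#' @export
tidy.vit_fit <- function(x, ...) x$history

#' One-row fit summary
#'
#' @param x A `vit_fit`.
#' @param ... Unused.
#' @return A one-row tibble: best epoch, best test accuracy, final
#'   train/test loss and accuracy, parameter count.
#' @export
glance.vit_fit <- function(x, ...) {
  h <- x$history
  last <- h[nrow(h), ]
  tibble::tibble(epochs = nrow(h), best_epoch = x$best_epoch,
                 best_test_acc = max(h$test_acc),
                 train_loss = last$train_loss, train_acc = last$train_acc,
                 test_loss = last$test_loss, test_acc = last$test_acc,
                 n_params = vit_param_count(x$model))
}

#' Tidy a confusion matrix
#'
#' @param x A [confusion_matrix()].
#' @param ... Unused.
#' @return Long tibble with `truth`, `predicted`, `n`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  as.data.frame(unclass(x)) |>
    tibble::rownames_to_column("truth") |>
    tidyr::pivot_longer(-"truth", names_to = "predicted", values_to = "n") |>
    tibble::as_tibble()
}

#' One-row confusion-matrix summary
#'
#' @param x A [confusion_matrix()].
#' @param ... Unused.
#' @return One-row tibble with `n`, `accuracy`, macro `precision`,
#'   `recall`, `f1` and the accuracy's 95% interval.
#' @export
glance.confusion_matrix <- function(x, ...) {
  rep <- metric_report(x)
  ov <- rep[rep$class == "overall", ]
  mac <- rep[rep$class == "macro", ]
  tibble::tibble(n = ov$n, accuracy = ov$accuracy,
                 precision = mac$precision, recall = mac$recall, f1 = mac$f1,
                 ci_low = ov$ci_low, ci_high = ov$ci_high)
}

#' Plot training curves
#'
#' Accuracy and loss per epoch for the training and test sets.
#'
#' @param object A `vit_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vit_fit <- function(object, ...) {
  long <- object$history |>
    tidyr::pivot_longer(-"epoch", names_to = c("set", "metric"),
                        names_sep = "_", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a precision-recall curve
#'
#' @param object A [pr_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a heat map
#'
#' @param object A [confusion_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy.confusion_matrix(object),
                  ggplot2::aes(x = .data$predicted, y = .data$truth,
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' Plot per-block attention maps
#'
#' @param maps List of matrices from [attention_maps()].
#' @return A ggplot object, one facet per encoder block.
#' @export
plot_attention_maps <- function(maps) {
  df <- purrr::imap_dfr(maps, function(m, i) {
    tibble::tibble(block = i,
                   row = rep(seq_len(nrow(m)), times = ncol(m)),
                   col = rep(seq_len(ncol(m)), each = nrow(m)),
                   w = as.vector(m))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$w)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(ggplot2::vars(.data$block)) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "attention") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
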