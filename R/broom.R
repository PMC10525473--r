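# Tidiers and autoplot methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted classifier's training history
#'
#' @param x An `mlp_fit`.
#' @param ... Unused.
#' @return A tibble in long form: `epoch`, `metric` (`loss` or `accuracy`),
#'   `split` (`train` or `val`), `value`.
#' @method tidy mlp_fit
#' @export
tidy.mlp_fit <- function(x, ...) {
  if (nrow(x$history) == 0) {
    return(tibble::tibble(epoch = integer(), metric = character(),
                          split = character(), value = numeric()))
  }
  x$history |>
    tidyr::pivot_longer(-"epoch", names_to = "series", values_to = "value") |>
    tidyr::separate_wider_delim("series", "_", names = c("split", "metric"))
}

#' One-row summary of a fitted classifier
#'
#' @param x An `mlp_fit`.
#' @param ... Unused.
#' @return A tibble with the architecture, parameter count, epochs, final
#'   train/validation accuracy and (when computed) held-out test accuracy.
#' @method glance mlp_fit
#' @export
glance.mlp_fit <- function(x, ...) {
  last <- if (nrow(x$history) > 0) x$history[nrow(x$history), ] else NULL
  tibble::tibble(
    architecture = paste(x$spec$layer_sizes, collapse = "-"),
    n_parameters = n_parameters(x$spec),
    epochs = x$epochs,
    train_accuracy = if (!is.null(last)) last$train_accuracy else NA_real_,
    val_accuracy = if (!is.null(last) && !is.null(last$val_accuracy))
      last$val_accuracy else NA_real_,
    test_accuracy = x$test_accuracy %||% NA_real_
  )
}

#' Tidy the cycle records of a generation loop
#'
#' @param x A `shuffle_loop`.
#' @param ... Unused.
#' @return The per-cycle records tibble: `cycle`, `P`, `B`, train/val/test
#'   accuracy and snapshot path.
#' @method tidy shuffle_loop
#' @export
tidy.shuffle_loop <- function(x, ...) x$records

#' One-row summary of a generation loop
#'
#' @param x A `shuffle_loop`.
#' @param ... Unused.
#' @return A tibble with the number of cycles run, the best cycle, its
#'   test accuracy, and the dataset size.
#' @method glance shuffle_loop
#' @export
glance.shuffle_loop <- function(x, ...) {
  tibble::tibble(
    cycles = nrow(x$records),
    best_cycle = x$best_cycle,
    best_test_accuracy = x$best_test_accuracy,
    n_records = nrow(x$best_dataset)
  )
}

#' Plot a generation loop's accuracy and window-parameter traces
#'
#' @param object A `shuffle_loop`.
#' @param which `"accuracy"` for the per-cycle train/validation/test
#'   accuracies, `"params"` for the `P` and `B` traces.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shuffle_loop
#' @export
autoplot.shuffle_loop <- function(object, which = c("accuracy", "params"), ...) {
  which <- match.arg(which)
  rec <- object$records
  if (which == "accuracy") {
    long <- rec |>
      dplyr::select("cycle", "train_accuracy", "val_accuracy", "test_accuracy") |>
      tidyr::pivot_longer(-"cycle", names_to = "series", values_to = "accuracy") |>
      dplyr::mutate(series = sub("_accuracy$", "", .data$series))
    ggplot2::ggplot(long, ggplot2::aes(.data$cycle, .data$accuracy,
                                       colour = .data$series)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "cycle", y = "accuracy", colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    long <- rec |>
      dplyr::select("cycle", "P", "B") |>
      tidyr::pivot_longer(-"cycle", names_to = "parameter", values_to = "value")
    ggplot2::ggplot(long, ggplot2::aes(.data$cycle, .data$value)) +
      ggplot2::geom_step() +
      ggplot2::facet_wrap(~parameter, ncol = 1, scales = "free_y") +
      ggplot2::labs(x = "cycle", y = NULL) +
      ggplot2::theme_minimal()
  }
}

#' Plot per-class score histograms
#'
#' @param object A `score_histograms` result.
#' @param ... Unused.
#' @return A ggplot object with the two class histograms overlaid.
#' @method autoplot score_histograms
#' @export
autoplot.score_histograms <- function(object, ...) {
  mids <- (object$bin_edges[-1] + object$bin_edges[-length(object$bin_edges)]) / 2
  long <- tibble::tibble(
    score = rep(mids, 2),
    count = c(object$class0_counts, object$class1_counts),
    class = rep(c("healthy", "diabetic"), each = length(mids))
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$score, .data$count,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "identity", alpha = 0.55, width = diff(object$bin_edges)[1]) +
    ggplot2::labs(x = "summed feature score", y = "patients", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a classifier's training curves
#'
#' @param object An `mlp_fit`.
#' @param ... Unused.
#' @return A ggplot object, accuracy and loss per epoch.
#' @method autoplot mlp_fit
#' @export
autoplot.mlp_fit <- function(object, ...) {
  long <- tidy.mlp_fit(object)
  if (nrow(long) == 0) stop("no training history to plot", call. = FALSE)
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
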