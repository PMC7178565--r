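#' Tidy a trained model's history
#'
#' @param x A `urnet_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch (`epoch`, `loss`).
#' @method tidy urnet_fit
#' @export
tidy.urnet_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a trained model
#'
#' @param x A `urnet_fit`.
#' @param ... Unused.
#' @return Tibble with variant, parameter count, training size and
#'   final loss.
#' @method glance urnet_fit
#' @export
glance.urnet_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$model$config$variant,
    n_params = n_params(x$model),
    n_windows = x$n_windows,
    epochs = x$epochs,
    batch_size = x$batch_size,
    learning_rate = x$learning_rate,
    final_loss = x$history$loss[nrow(x$history)]
  )
}

#' @rdname tidy.urnet_fit
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  x$per_read
}

#' @rdname glance.urnet_fit
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  s <- x$summary
  out <- tibble::tibble(n_reads = x$n_reads, n_unaligned = x$n_unaligned)
  for (i in seq_len(nrow(s))) {
    out[[paste0("mean_", s$metric[i])]] <- s$mean[i]
    out[[paste0("sd_", s$metric[i])]] <- s$sd[i]
  }
  out
}

#' Training-curve plot
#'
#' @param object A `urnet_fit`.
#' @param ... Unused.
#' @return A ggplot of mean window loss per epoch.
#' @method autoplot urnet_fit
#' @export
autoplot.urnet_fit <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "mean window loss",
                  title = sprintf("%s training curve", object$model$config$variant)) +
    ggplot2::theme_minimal()
}

#' Signal-and-segmentation plot for a simulated read
#'
#' Draws the raw samples coloured by gold base with segment boundaries,
#' the view used to inspect what the segmentation network must learn.
#'
#' @param object A `simulated_read`.
#' @param max_samples Truncate the view to this many samples.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot simulated_read
#' @export
autoplot.simulated_read <- function(object, max_samples = 1500L, ...) {
  n <- min(length(object$signal), max_samples)
  df <- tibble::tibble(
    sample = seq_len(n) - 1L,
    current = object$signal[seq_len(n)],
    base = substr(int_to_alias(object$mask[seq_len(n)]), 1L, 1L)
  )
  bounds <- object$segments$start[object$segments$start < n]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$current,
                                   colour = .data$base)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::geom_vline(xintercept = bounds, linewidth = 0.1, alpha = 0.3) +
    ggplot2::labs(x = "sample", y = "normalized current",
                  title = object$read_id) +
    ggplot2::theme_minimal()
}

#' Homopolymer run-length histogram plot
#'
#' @param sequences Character vector of nucleotide sequences.
#' @param max_length Right-truncate runs at this length for display.
#' @return A ggplot bar chart of run-length counts per base.
#' @export
plot_homopolymer_histogram <- function(sequences, max_length = 10L) {
  h <- dplyr::bind_rows(lapply(sequences, homopolymer_histogram)) |>
    dplyr::group_by(.data$base, .data$length) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::filter(.data$length <= max_length)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$length, y = .data$count,
                                  fill = .data$base)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_x_continuous(breaks = seq_len(max_length)) +
    ggplot2::labs(x = "homopolymer length (bp)", y = "count") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
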