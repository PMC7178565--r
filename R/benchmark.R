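#' Compare architecture variants on the same synthetic data
#'
#' Trains every requested variant on the same training windows under
#' each seed (seeds drive weight initialization and shuffling) and
#' reports held-out window NED. The scaled-down analog of comparing
#' network architectures by NED on a fixed test set.
#'
#' @param train_data,eval_data `window_set`s (see [make_dataset()]).
#' @param variants Character vector among `"unet"`, `"gru3"`,
#'   `"unet_gru3"`, `"urnet"`.
#' @param seeds Integer vector of training seeds.
#' @param preset,rnn_units,n_levels,filters,kernel_size,pool_factors
#'   Architecture settings shared by all variants (see [urnet_config()]).
#' @param epochs,batch_size,learning_rate Training settings.
#' @param verbose Print progress.
#' @return Tibble with one row per variant: `variant`, `mean_ned`
#'   (mean over seeds of the per-seed mean window NED), `sd_ned` (sd of
#'   window NED pooled over seeds) and `n_seeds`. The per-seed detail is
#'   attached as attribute `"by_seed"`.
#' @export
benchmark_variants <- function(train_data, eval_data,
                               variants = c("unet", "gru3", "unet_gru3", "urnet"),
                               seeds = c(1L, 2L, 3L), preset = "tiny",
                               n_levels = 3L, filters = NULL, kernel_size = 11L,
                               pool_factors = c(2L, 3L, 5L), rnn_units = NULL,
                               epochs = 3L, batch_size = 32L, learning_rate = 1e-3,
                               verbose = FALSE) {
  variants <- match.arg(variants, several.ok = TRUE)
  L <- train_data$window_length
  detail <- list()
  for (v in variants) {
    for (s in seeds) {
      args <- list(variant = v, preset = preset, n_levels = n_levels,
                   kernel_size = kernel_size, pool_factors = pool_factors)
      if (!is.null(filters)) args$filters <- filters
      if (!is.null(rnn_units)) args$rnn_units <- rnn_units
      cfg <- do.call(urnet_config, args)
      model <- build_model(cfg, window_length = L, seed = s)
      if (verbose) message(sprintf("training %s (seed %d, %d params)", v, s, n_params(model)))
      fit <- train_model(model, train_data, epochs = epochs,
                         batch_size = batch_size, learning_rate = learning_rate,
                         seed = s)
      neds <- evaluate_windows(fit, eval_data)$ned
      detail[[length(detail) + 1L]] <-
        tibble::tibble(variant = v, seed = s, mean_ned = mean(neds),
                       sd_ned = stats::sd(neds), n_windows = length(neds))
    }
  }
  by_seed <- dplyr::bind_rows(detail)
  out <- by_seed |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(
      mean_ned = mean(.data$mean_ned),
      # per-window sd pooled over seeds, the analog of a test-set std column
      sd_ned = sqrt(sum((.data$n_windows - 1L) * .data$sd_ned^2) /
                      sum(.data$n_windows - 1L)),
      n_seeds = dplyr::n(), .groups = "drop")
  out <- out[match(variants, out$variant), ]
  attr(out, "by_seed") <- by_seed
  out
}
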