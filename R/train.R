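#' Train a segmentation network
#'
#' Minimizes the combined dice + cross-entropy objective with Adam over
#' mini-batches of fixed-length signal windows and their gold alias
#' label masks. Batch-norm running statistics are updated during
#' training and used at inference. Deterministic for a fixed seed.
#'
#' @param model A [build_model()] result.
#' @param data A `window_set` from [make_dataset()], or a list with
#'   `signal` (L x n matrix) and `labels` (L x n integer matrix).
#' @param epochs Training epochs.
#' @param batch_size Windows per Adam step.
#' @param learning_rate Adam step size.
#' @param alpha,beta Loss interpolation weights (defaults 1 and 1).
#' @param seed Seed for shuffling (weight init is seeded at
#'   [build_model()] time).
#' @param verbose Print per-epoch mean loss.
#' @return An object of class `urnet_fit`: the trained `model` plus a
#'   `history` tibble with per-epoch mean window loss.
#' @export
#' @examples
#' \donttest{
#' ds <- make_dataset(4, 200, window_length = 60, seed = 1)
#' m <- build_model(urnet_config("unet", preset = "tiny", n_levels = 2,
#'                               pool_factors = c(2, 3)),
#'                  window_length = 60, seed = 1)
#' fit <- train_model(m, ds, epochs = 1, batch_size = 4, seed = 1)
#' fit$history
#' }
train_model <- function(model, data, epochs = 3L, batch_size = 32L,
                        learning_rate = 1e-3, alpha = 1, beta = 1,
                        seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "urnet_model"))
  signal <- data$signal; labels <- data$labels
  if (is.null(signal) || is.null(labels) || ncol(signal) == 0L) {
    stop_segcall("training dataset is empty", class = "segcall_error_invalid")
  }
  if (!all(dim(signal) == dim(labels))) {
    stop_segcall("signal and labels dimensions differ", class = "segcall_error_invalid")
  }
  L <- nrow(signal); n <- ncol(signal)
  if (L != model$window_length) {
    stop_segcall(sprintf("window length %d does not match model window length %d",
                         L, model$window_length), class = "segcall_error_invalid")
  }
  set.seed(as.integer(seed))

  opt <- adam_state(model$params, learning_rate)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    total <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n)]
      X <- array(signal[, idx], c(L, 1L, length(idx)))
      fwd <- urnet_forward(model, X, train = TRUE)
      model$state <- fwd$state
      lg <- loss_and_grad(fwd$logits, labels[, idx, drop = FALSE], alpha, beta)
      grads <- urnet_backward(model, fwd, lg$dlogits)
      upd <- adam_step(opt, model$params, grads)
      model$params <- upd$params; opt <- upd$opt
      total <- total + lg$loss
    }
    history[ep] <- total / n
    if (verbose) message(sprintf("epoch %d: mean window loss %.4f", ep, history[ep]))
  }
  structure(list(model = model,
                 history = tibble::tibble(epoch = seq_len(epochs), loss = history),
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, alpha = alpha, beta = beta,
                 seed = seed, n_windows = n),
            class = "urnet_fit")
}

#' @export
print.urnet_fit <- function(x, ...) {
  cat(sprintf("<urnet_fit> %s trained %d epochs on %d windows; final mean loss %.4f\n",
              x$model$config$variant, x$epochs, x$n_windows,
              x$history$loss[nrow(x$history)]))
  invisible(x)
}

adam_state <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zeros <- lapply(params, function(p) { p[] <- 0; p })
  list(m = zeros, v = zeros, t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + opt$eps)
  }
  list(params = params, opt = opt)
}
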