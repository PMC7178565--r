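#' Network architecture configuration
#'
#' Describes the 1D segmentation network and its ablation variants:
#' * `"unet"` — encoder of CONV–BatchNorm–ReLU blocks with max pooling,
#'   decoder of nearest-neighbour up-sampling with skip concatenations;
#'   no recurrence.
#' * `"gru3"` — three bidirectional GRU layers directly on the signal.
#' * `"unet_gru3"` — the `"unet"` body followed by three bidirectional
#'   GRU layers.
#' * `"urnet"` — `"unet_gru3"` plus a bidirectional GRU after every
#'   encoder CONV-BN-ReLU block; those recurrent outputs (not the plain
#'   convolution outputs) feed both the pooling path and the decoder
#'   skip concatenations.
#'
#' Input windows of length L map to L x 8 probability rows, so the
#' window length must be divisible by `prod(pool_factors)`.
#'
#' @param variant Architecture variant (see above).
#' @param preset `"tiny"` shrinks filters to 8/16/32 and rnn_units to 32
#'   (the test-scale configuration); `NULL` keeps the given values.
#' @param n_levels Encoder depth.
#' @param filters Convolution channels per encoder level.
#' @param kernel_size Convolution width in samples (odd).
#' @param pool_factors Per-level down-sampling factors.
#' @param rnn_units Hidden size of the final bidirectional GRU layers.
#' @param final_rnn_layers Number of final bidirectional GRU layers.
#' @param n_classes Output classes (8 alias labels).
#' @return An object of class `urnet_config`.
#' @export
#' @examples
#' urnet_config("urnet", preset = "tiny")
urnet_config <- function(variant = c("urnet", "unet", "gru3", "unet_gru3"),
                         preset = NULL, n_levels = 3L,
                         filters = c(64L, 128L, 256L), kernel_size = 11L,
                         pool_factors = c(2L, 3L, 5L), rnn_units = 128L,
                         final_rnn_layers = 3L, n_classes = 8L) {
  variant <- match.arg(variant)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("tiny", "default"))
    if (preset == "tiny") {
      filters <- c(8L, 16L, 32L)[seq_len(n_levels)]
      rnn_units <- 32L
    }
  }
  n_levels <- as.integer(n_levels)
  filters <- as.integer(filters); pool_factors <- as.integer(pool_factors)
  if (n_levels < 1L) stop_segcall("n_levels must be >= 1", class = "segcall_error_config")
  if (length(filters) != n_levels || length(pool_factors) != n_levels) {
    stop_segcall("filters and pool_factors must each have n_levels entries",
                 class = "segcall_error_config")
  }
  if (kernel_size %% 2L != 1L || kernel_size < 1L) {
    stop_segcall("kernel_size must be odd and >= 1", class = "segcall_error_config")
  }
  if (n_classes != 8L) stop_segcall("n_classes must be 8", class = "segcall_error_config")
  structure(list(variant = variant, n_levels = n_levels, filters = filters,
                 kernel_size = as.integer(kernel_size),
                 pool_factors = pool_factors, rnn_units = as.integer(rnn_units),
                 final_rnn_layers = as.integer(final_rnn_layers),
                 n_classes = 8L),
            class = "urnet_config")
}

#' @export
print.urnet_config <- function(x, ...) {
  cat(sprintf("<urnet_config> %s: %d levels, filters (%s), kernel %d, pools (%s), rnn %d x%d\n",
              x$variant, x$n_levels, paste(x$filters, collapse = ", "),
              x$kernel_size, paste(x$pool_factors, collapse = ", "),
              x$rnn_units, x$final_rnn_layers))
  invisible(x)
}

# ---- computation graph -------------------------------------------------

# plan: ordered node list; each node has id, op, inp (input ids), cout
# (output channels), optional param prefix and op attributes
build_plan <- function(cfg) {
  nodes <- list()
  add <- function(op, inp, cout, par = NULL, ...) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- c(list(id = id, op = op, inp = as.integer(inp),
                           cout = as.integer(cout), par = par), list(...))
    id
  }
  conv_block <- function(inp, cin, cout, k, name) {
    cid <- add("conv", inp, cout, par = paste0(name, "_conv"), k = k, cin = cin)
    bid <- add("bn", cid, cout, par = paste0(name, "_bn"))
    add("relu", bid, cout)
  }
  gru_layer <- function(inp, cin, units, name) {
    add("bigru", inp, 2L * units, par = paste0(name, "_gru"), cin = cin, units = units)
  }
  x <- add("input", integer(0), 1L)

  head_from <- function(inp, cin) {
    add("conv", inp, cfg$n_classes, par = "head_conv", k = 1L, cin = cin)
  }

  if (cfg$variant == "gru3") {
    cur <- x; cin <- 1L
    for (i in seq_len(cfg$final_rnn_layers)) {
      cur <- gru_layer(cur, cin, cfg$rnn_units, paste0("final", i))
      cin <- 2L * cfg$rnn_units
    }
    head_from(cur, cin)
  } else {
    cur <- x; cin <- 1L
    skips <- integer(cfg$n_levels); skip_ch <- integer(cfg$n_levels)
    for (i in seq_len(cfg$n_levels)) {
      cur <- conv_block(cur, cin, cfg$filters[i], cfg$kernel_size, paste0("enc", i))
      cin <- cfg$filters[i]
      if (cfg$variant == "urnet") {
        cur <- gru_layer(cur, cin, cfg$filters[i], paste0("enc", i))
        cin <- 2L * cfg$filters[i]
      }
      skips[i] <- cur; skip_ch[i] <- cin
      cur <- add("pool", cur, cin, f = cfg$pool_factors[i])
    }
    mid <- 2L * cfg$filters[cfg$n_levels]
    cur <- conv_block(cur, cin, mid, cfg$kernel_size, "mid"); cin <- mid
    for (i in rev(seq_len(cfg$n_levels))) {
      cur <- add("upsample", cur, cin, f = cfg$pool_factors[i])
      cur <- add("concat", c(cur, skips[i]), cin + skip_ch[i])
      cur <- conv_block(cur, cin + skip_ch[i], cfg$filters[i], cfg$kernel_size,
                        paste0("dec", i))
      cin <- cfg$filters[i]
    }
    if (cfg$variant %in% c("unet_gru3", "urnet")) {
      for (i in seq_len(cfg$final_rnn_layers)) {
        cur <- gru_layer(cur, cin, cfg$rnn_units, paste0("final", i))
        cin <- 2L * cfg$rnn_units
      }
    }
    head_from(cur, cin)
  }
  nodes
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

init_params <- function(plan) {
  params <- list(); state <- list()
  for (nd in plan) {
    if (is.null(nd$par)) next
    if (nd$op == "conv") {
      fan_in <- nd$k * nd$cin
      params[[paste0(nd$par, ".W")]] <-
        matrix(rnorm(fan_in * nd$cout, sd = sqrt(2 / fan_in)), fan_in, nd$cout)
      params[[paste0(nd$par, ".b")]] <- numeric(nd$cout)
    } else if (nd$op == "bn") {
      params[[paste0(nd$par, ".gamma")]] <- rep(1, nd$cout)
      params[[paste0(nd$par, ".beta")]] <- rep(0, nd$cout)
      state[[nd$par]] <- list(mean = rep(0, nd$cout), var = rep(1, nd$cout))
    } else if (nd$op == "bigru") {
      H <- nd$units
      params[[paste0(nd$par, ".Wf")]] <- glorot(nd$cin, 3L * H)
      params[[paste0(nd$par, ".Uf")]] <- glorot(H, 3L * H)
      params[[paste0(nd$par, ".bf")]] <- numeric(3L * H)
      params[[paste0(nd$par, ".Wb")]] <- glorot(nd$cin, 3L * H)
      params[[paste0(nd$par, ".Ub")]] <- glorot(H, 3L * H)
      params[[paste0(nd$par, ".bb")]] <- numeric(3L * H)
    }
  }
  list(params = params, state = state)
}

#' Build a segmentation network
#'
#' Instantiates the variant described by a [urnet_config()] with freshly
#' initialized parameters. The model maps `(L, 1)` signal windows to
#' `(L, 8)` per-sample class probabilities; output length always equals
#' input length.
#'
#' @param config A [urnet_config()].
#' @param window_length Window length L the model will be applied to;
#'   must be divisible by `prod(pool_factors)` for U-net variants.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `urnet_model`.
#' @export
#' @examples
#' m <- build_model(urnet_config("unet", preset = "tiny"), window_length = 30, seed = 1)
#' n_params(m)
build_model <- function(config, window_length = 300L, seed = 1L) {
  stopifnot(inherits(config, "urnet_config"))
  window_length <- as.integer(window_length)
  pp <- prod(config$pool_factors)
  if (config$variant != "gru3" && window_length %% pp != 0L) {
    stop_segcall(sprintf(
      "window length %d is not divisible by prod(pool_factors) = %d; output length would differ from input length",
      window_length, pp), class = "segcall_error_config")
  }
  set.seed(as.integer(seed))
  plan <- build_plan(config)
  ini <- init_params(plan)
  structure(list(config = config, window_length = window_length, plan = plan,
                 params = ini$params, state = ini$state),
            class = "urnet_model")
}

#' Number of trainable parameters
#' @param model A `urnet_model` or `urnet_fit`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  model <- as_urnet_model(model)
  sum(vapply(model$params, length, integer(1)))
}

as_urnet_model <- function(x) {
  if (inherits(x, "urnet_fit")) x$model
  else if (inherits(x, "urnet_model")) x
  else stop_segcall("expected a urnet_model or urnet_fit", class = "segcall_error_invalid")
}

#' @export
print.urnet_model <- function(x, ...) {
  cat(sprintf("<urnet_model> %s, window %d, %d parameters\n",
              x$config$variant, x$window_length, n_params(x)))
  invisible(x)
}

# ---- array <-> matrix helpers -----------------------------------------

# (L, C, B) array to (L*B, C) matrix, rows ordered t + (b-1)*L
arr2mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1L, 3L, 2L)), nrow = d[1L] * d[3L], ncol = d[2L])
}

mat2arr <- function(m, L, B) {
  aperm(array(m, c(L, B, ncol(m))), c(1L, 3L, 2L))
}

softmax_rows <- function(m) {
  mx <- do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
  e <- exp(m - mx)
  e / rowSums(e)
}

# ---- forward / backward executor --------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

urnet_forward <- function(model, X, train = FALSE) {
  plan <- model$plan; params <- model$params; state <- model$state
  n <- length(plan)
  outs <- vector("list", n); caches <- vector("list", n)
  for (nd in plan) {
    id <- nd$id
    out <- switch(nd$op,
      input = X,
      conv = {
        p <- nd$par
        cpp_conv1d_fw(outs[[nd$inp]], params[[paste0(p, ".W")]],
                      params[[paste0(p, ".b")]], nd$k)
      },
      bn = {
        x <- outs[[nd$inp]]; p <- nd$par
        d <- dim(x); xm <- arr2mat(x)
        if (train) {
          mu <- colMeans(xm)
          v <- colMeans(xm^2) - mu^2
          state[[p]]$mean <- BN_MOMENTUM * state[[p]]$mean + (1 - BN_MOMENTUM) * mu
          state[[p]]$var <- BN_MOMENTUM * state[[p]]$var + (1 - BN_MOMENTUM) * v
        } else {
          mu <- state[[p]]$mean; v <- state[[p]]$var
        }
        invstd <- 1 / sqrt(v + BN_EPS)
        xhat <- sweep(sweep(xm, 2L, mu, "-"), 2L, invstd, "*")
        om <- sweep(sweep(xhat, 2L, params[[paste0(p, ".gamma")]], "*"),
                    2L, params[[paste0(p, ".beta")]], "+")
        caches[[id]] <- list(xhat = xhat, invstd = invstd, train = train)
        mat2arr(om, d[1L], d[3L])
      },
      relu = {
        x <- outs[[nd$inp]]
        mask <- x > 0
        caches[[id]] <- mask
        x * mask
      },
      pool = {
        r <- cpp_maxpool_fw(outs[[nd$inp]], nd$f)
        caches[[id]] <- r$idx
        r$Y
      },
      upsample = {
        x <- outs[[nd$inp]]
        x[rep(seq_len(dim(x)[1L]), each = nd$f), , , drop = FALSE]
      },
      concat = {
        a <- outs[[nd$inp[1L]]]; b <- outs[[nd$inp[2L]]]
        da <- dim(a); db <- dim(b)
        y <- array(0, c(da[1L], da[2L] + db[2L], da[3L]))
        y[, seq_len(da[2L]), ] <- a
        y[, da[2L] + seq_len(db[2L]), ] <- b
        y
      },
      bigru = {
        p <- nd$par
        r <- cpp_bigru_fw(outs[[nd$inp]],
                          params[[paste0(p, ".Wf")]], params[[paste0(p, ".Uf")]],
                          params[[paste0(p, ".bf")]],
                          params[[paste0(p, ".Wb")]], params[[paste0(p, ".Ub")]],
                          params[[paste0(p, ".bb")]])
        caches[[id]] <- r$cache
        r$Y
      },
      stop_segcall(paste("unknown op", nd$op)))
    outs[[id]] <- out
  }
  list(logits = outs[[n]], outs = outs, caches = caches, state = state)
}

urnet_backward <- function(model, fwd, dlogits) {
  plan <- model$plan; params <- model$params
  outs <- fwd$outs; caches <- fwd$caches
  n <- length(plan)
  gout <- vector("list", n)
  gout[[n]] <- dlogits
  pg <- list()
  addg <- function(id, g) {
    gout[[id]] <<- if (is.null(gout[[id]])) g else gout[[id]] + g
  }
  for (nd in rev(plan)) {
    g <- gout[[nd$id]]
    if (is.null(g) || nd$op == "input") next
    switch(nd$op,
      conv = {
        p <- nd$par
        r <- cpp_conv1d_bw(outs[[nd$inp]], params[[paste0(p, ".W")]], g, nd$k)
        pg[[paste0(p, ".W")]] <- r$dW
        pg[[paste0(p, ".b")]] <- as.numeric(r$db)
        addg(nd$inp, r$dX)
      },
      bn = {
        p <- nd$par; cc <- caches[[nd$id]]
        d <- dim(g); gm <- arr2mat(g)
        pg[[paste0(p, ".gamma")]] <- colSums(gm * cc$xhat)
        pg[[paste0(p, ".beta")]] <- colSums(gm)
        dxhat <- sweep(gm, 2L, params[[paste0(p, ".gamma")]], "*")
        if (cc$train) {
          nn <- nrow(gm)
          dx <- sweep(dxhat, 2L, colSums(dxhat) / nn, "-")
          dx <- dx - sweep(cc$xhat, 2L, colSums(dxhat * cc$xhat) / nn, "*")
          dx <- sweep(dx, 2L, cc$invstd, "*")
        } else {
          dx <- sweep(dxhat, 2L, cc$invstd, "*")
        }
        addg(nd$inp, mat2arr(dx, d[1L], d[3L]))
      },
      relu = addg(nd$inp, g * caches[[nd$id]]),
      pool = {
        Lin <- dim(outs[[nd$inp]])[1L]
        addg(nd$inp, cpp_maxpool_bw(caches[[nd$id]], g, Lin))
      },
      upsample = {
        d <- dim(g); Lo <- d[1L] %/% nd$f
        gm <- matrix(g, nrow = d[1L])
        ds <- rowsum(gm, group = rep(seq_len(Lo), each = nd$f))
        addg(nd$inp, array(ds, c(Lo, d[2L], d[3L])))
      },
      concat = {
        ca <- plan[[nd$inp[1L]]]$cout
        addg(nd$inp[1L], g[, seq_len(ca), , drop = FALSE])
        addg(nd$inp[2L], g[, -seq_len(ca), , drop = FALSE])
      },
      bigru = {
        p <- nd$par
        r <- cpp_bigru_bw(outs[[nd$inp]],
                          params[[paste0(p, ".Wf")]], params[[paste0(p, ".Uf")]],
                          params[[paste0(p, ".Wb")]], params[[paste0(p, ".Ub")]],
                          caches[[nd$id]], g)
        pg[[paste0(p, ".Wf")]] <- r$dWf
        pg[[paste0(p, ".Uf")]] <- r$dUf
        pg[[paste0(p, ".bf")]] <- as.numeric(r$dbf)
        pg[[paste0(p, ".Wb")]] <- r$dWb
        pg[[paste0(p, ".Ub")]] <- r$dUb
        pg[[paste0(p, ".bb")]] <- as.numeric(r$dbb)
        addg(nd$inp, r$dX)
      })
  }
  pg
}

#' Per-sample class probabilities for signal windows
#'
#' Runs the network in inference mode (batch-norm running statistics)
#' over windows of signal and returns softmax probabilities.
#'
#' @param model A `urnet_model` or `urnet_fit`.
#' @param signal Matrix with one window per column (L rows), or a
#'   numeric vector for a single window.
#' @param batch_size Windows per forward pass.
#' @return Array of dim `(L, 8, n_windows)`; every row distribution
#'   sums to 1.
#' @export
predict_probs <- function(model, signal, batch_size = 64L) {
  model <- as_urnet_model(model)
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1L)
  L <- nrow(signal); n <- ncol(signal)
  out <- array(0, c(L, 8L, n))
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    X <- array(signal[, i:j], c(L, 1L, j - i + 1L))
    fwd <- urnet_forward(model, X, train = FALSE)
    lm <- arr2mat(fwd$logits)
    out[, , i:j] <- mat2arr(softmax_rows(lm), L, j - i + 1L)
    i <- j + 1L
  }
  out
}

#' Basecall individual windows (no merging)
#'
#' Argmax labels per sample (ties broken toward the lowest label index),
#' collapsed into a sequence per window. Used for window-level NED
#' evaluation against gold window sequences.
#'
#' @inheritParams predict_probs
#' @return Character vector of basecalled sequences, one per window.
#' @export
basecall_windows <- function(model, signal, batch_size = 64L) {
  probs <- predict_probs(model, signal, batch_size = batch_size)
  vapply(seq_len(dim(probs)[3L]), function(i) {
    lab <- max.col(probs[, , i], ties.method = "first")
    collapse_mask(lab)$sequence
  }, character(1))
}
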