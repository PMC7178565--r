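#' Training objective: dice similarity plus categorical cross-entropy
#'
#' For one window the dice similarity between the predicted probability
#' matrix `p` and the one-hot gold matrix `g` is
#' `DL = 2 * sum(p * g) / (sum(g) + sum(p))` (a small additive epsilon
#' guards empty inputs); with softmax rows the denominator equals twice
#' the window length. The cross-entropy is `CE = -sum(g * log(p))`: the
#' quantity is used in its minimizable (negated) form, and the dice
#' similarity enters the combined objective as `1 - DL`, so the combined
#' loss `alpha * CE + beta * (1 - DL)` is zero exactly at a perfect hard
#' prediction and positive otherwise. `alpha = beta = 1` by default.
#'
#' @param p Numeric L x 8 matrix of row-stochastic probabilities.
#' @param g Gold labels: an L x 8 one-hot matrix, or a length-L vector
#'   of alias labels/codes.
#' @param alpha Weight of the cross-entropy term (>= 0).
#' @param beta Weight of the dice term (>= 0); not both zero.
#' @return `dice_term()` a similarity in \[0, 1\]; `ce_term()` a
#'   non-negative scalar; `combined_loss()` their weighted combination.
#' @name loss
#' @examples
#' g <- one_hot(alias_encode("ACG"))
#' dice_term(g, g)       # 1
#' ce_term(g, g)         # 0
#' combined_loss(g, g)   # 0
NULL

DICE_EPS <- 1e-6
LOG_EPS <- 1e-7

as_gold_matrix <- function(g, p) {
  if (is.matrix(g)) {
    if (!all(dim(g) == dim(p))) {
      stop_segcall("p and g shapes differ", class = "segcall_error_invalid")
    }
    g
  } else {
    gm <- one_hot(g)
    if (nrow(gm) != nrow(p)) {
      stop_segcall("p and g shapes differ", class = "segcall_error_invalid")
    }
    gm
  }
}

#' @rdname loss
#' @export
dice_term <- function(p, g) {
  g <- as_gold_matrix(g, p)
  (2 * sum(p * g) + DICE_EPS) / (sum(g) + sum(p) + DICE_EPS)
}

#' @rdname loss
#' @export
ce_term <- function(p, g) {
  g <- as_gold_matrix(g, p)
  -sum(g * log(pmax(p, LOG_EPS)))
}

#' @rdname loss
#' @export
combined_loss <- function(p, g, alpha = 1, beta = 1) {
  if (alpha < 0 || beta < 0 || (alpha == 0 && beta == 0)) {
    stop_segcall("alpha and beta must be >= 0 and not both 0",
                 class = "segcall_error_invalid")
  }
  alpha * ce_term(p, g) + beta * (1 - dice_term(p, g))
}

# batched loss over logits with analytic gradient.
# logits: (L, 8, B) array; labels: L x B integer matrix of alias codes.
# Loss is summed over the batch (per-window CE + per-window dice),
# matching the training objective; gradient is w.r.t. the logits.
loss_and_grad <- function(logits, labels, alpha = 1, beta = 1) {
  d <- dim(logits); L <- d[1L]; B <- d[3L]
  P <- softmax_rows(arr2mat(logits))
  gl <- as.integer(labels)                       # row r = t + (b-1)*L
  idx <- cbind(seq_len(L * B), gl)
  pick <- P[idx]
  ce <- -sum(log(pmax(pick, LOG_EPS)))
  S <- colSums(matrix(pick, L, B))               # per-window overlap
  Sp <- colSums(matrix(rowSums(P), L, B))        # = L per window
  den <- L + Sp + DICE_EPS
  DL <- (2 * S + DICE_EPS) / den
  loss <- alpha * ce + beta * sum(1 - DL)

  G <- matrix(0, L * B, 8L)
  G[idx] <- 1
  den_r <- rep(den, each = L)
  DL_r <- rep(DL, each = L)
  u <- -beta * (2 * G - DL_r) / den_r            # dLoss/dP from dice part
  dz_dice <- P * (u - rowSums(u * P))
  dlog <- alpha * (P - G) + dz_dice
  list(loss = loss, ce = ce, dice = DL, dlogits = mat2arr(dlog, L, B))
}

#' Numerical-versus-analytic gradient agreement
#'
#' Compares the backpropagated gradient of the combined loss with a
#' central-difference numerical gradient on a random subset of
#' parameter coordinates. A quality-control utility for the network's
#' gradient machinery.
#'
#' @param model A `urnet_model`.
#' @param signal L x B matrix of signal windows.
#' @param labels L x B integer matrix of gold alias codes.
#' @param alpha,beta Loss weights.
#' @param n_coords Number of parameter coordinates to probe.
#' @param h Central-difference step.
#' @param seed Seed for coordinate sampling.
#' @return Tibble with one row per probed coordinate: parameter name,
#'   analytic and numerical derivative, and relative error
#'   `|a - n| / max(1e-8, |a| + |n|)`.
#' @export
gradient_check <- function(model, signal, labels, alpha = 1, beta = 1,
                           n_coords = 60L, h = 1e-5, seed = 1L) {
  stopifnot(inherits(model, "urnet_model"))
  L <- nrow(signal); B <- ncol(signal)
  X <- array(signal, c(L, 1L, B))
  loss_of <- function(m) {
    fwd <- urnet_forward(m, X, train = TRUE)
    loss_and_grad(fwd$logits, labels, alpha, beta)$loss
  }
  fwd <- urnet_forward(model, X, train = TRUE)
  lg <- loss_and_grad(fwd$logits, labels, alpha, beta)
  pg <- urnet_backward(model, fwd, lg$dlogits)

  set.seed(as.integer(seed))
  sizes <- vapply(model$params, length, integer(1))
  flat_n <- sum(sizes)
  coords <- sort(sample.int(flat_n, min(n_coords, flat_n)))
  bounds <- cumsum(sizes)
  rows <- lapply(coords, function(ci) {
    pi <- which(ci <= bounds)[1L]
    off <- ci - c(0L, bounds)[pi]
    nm <- names(model$params)[pi]
    mp <- model; mm <- model
    mp$params[[nm]][off] <- mp$params[[nm]][off] + h
    mm$params[[nm]][off] <- mm$params[[nm]][off] - h
    num <- (loss_of(mp) - loss_of(mm)) / (2 * h)
    ana <- if (nm %in% names(pg)) pg[[nm]][off] else 0
    tibble::tibble(param = nm, analytic = ana, numerical = num,
                   rel_error = abs(ana - num) / max(1e-8, abs(ana) + abs(num)))
  })
  dplyr::bind_rows(rows)
}
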