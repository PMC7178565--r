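#' Normalize a raw signal by median shift and MAD scale
#'
#' `norm = (raw - shift) / scale` with `shift = median(raw)` and
#' `scale = median(|raw - shift|)`. The MAD carries no consistency
#' factor: the printed formula is applied literally. Shift and scale are
#' computed per read.
#'
#' @param samples Non-empty numeric vector of raw current values.
#' @return List with `samples` (normalized signal), `shift` and `scale`.
#' @export
#' @examples
#' normalize_signal(c(1, 2, 3, 4, 100))
normalize_signal <- function(samples) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop_segcall("signal must be a non-empty numeric vector", class = "segcall_error_invalid")
  }
  shift <- median(samples)
  scale <- median(abs(samples - shift))
  if (scale == 0) {
    stop_segcall("degenerate signal: median absolute deviation is zero",
                 class = "segcall_error_degenerate")
  }
  list(samples = (samples - shift) / scale, shift = shift, scale = scale)
}

#' Split a normalized signal into non-overlapping training windows
#'
#' Windows start at offsets 0, L, 2L, ...; the trailing partial window
#' is dropped. Any window containing a normalized value larger than
#' `filter_threshold` is excluded (the signed value by default; set
#' `filter_abs = TRUE` for the symmetric variant).
#'
#' @param signal Normalized numeric signal.
#' @param mask Integer or character alias label mask, same length.
#' @param window_length Window length L in samples.
#' @param filter_threshold Outlier threshold (default 10).
#' @param filter_abs Filter on `abs(value)` instead of the signed value.
#' @return List with `signal` (L x n matrix), `labels` (integer L x n
#'   matrix) and `offsets` (0-based window starts after filtering).
#' @export
window_train <- function(signal, mask, window_length, filter_threshold = 10,
                         filter_abs = FALSE) {
  window_length <- as.integer(window_length)
  if (is.na(window_length) || window_length < 1L) {
    stop_segcall("window_length must be >= 1", class = "segcall_error_invalid")
  }
  mask <- alias_to_int(mask)
  if (length(signal) != length(mask)) {
    stop_segcall("signal and mask lengths differ", class = "segcall_error_invalid")
  }
  n_win <- length(signal) %/% window_length
  if (n_win == 0L) {
    return(list(signal = matrix(numeric(0), window_length, 0),
                labels = matrix(integer(0), window_length, 0),
                offsets = integer(0)))
  }
  used <- n_win * window_length
  sig <- matrix(signal[seq_len(used)], nrow = window_length)
  lab <- matrix(mask[seq_len(used)], nrow = window_length)
  offs <- (seq_len(n_win) - 1L) * window_length
  vals <- if (filter_abs) abs(sig) else sig
  keep <- apply(vals, 2L, max) <= filter_threshold
  list(signal = sig[, keep, drop = FALSE],
       labels = lab[, keep, drop = FALSE],
       offsets = offs[keep])
}

#' Plan overlapping inference windows over a read
#'
#' Offsets run 0, s, 2s, ... while `offset + L <= N`; if the last such
#' window ends before the read does, one tail window anchored at `N - L`
#' is appended so the read end is covered. Consecutive windows overlap
#' by `L - s` samples. The interior window count matches the
#' floor((N - L) / s) sliding-window count; the anchored tail adds at
#' most one window beyond it.
#'
#' @param n Read length N in samples (>= L).
#' @param window_length Window length L.
#' @param step Step s between window starts (>= 1; < L for overlap).
#' @return Integer vector of 0-based window offsets.
#' @export
#' @examples
#' window_infer(1000, 300, 290)
window_infer <- function(n, window_length, step) {
  n <- as.integer(n); L <- as.integer(window_length); s <- as.integer(step)
  if (is.na(s) || s < 1L) stop_segcall("step must be >= 1", class = "segcall_error_invalid")
  if (is.na(L) || L < 1L) stop_segcall("window_length must be >= 1", class = "segcall_error_invalid")
  if (is.na(n) || n < L) {
    stop_segcall(sprintf("read too short: %d samples < window length %d", n, L),
                 class = "segcall_error_short_read")
  }
  offs <- seq.int(0L, n - L, by = s)
  if (offs[length(offs)] + L < n) offs <- c(offs, n - L)
  offs
}
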