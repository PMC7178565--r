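#' Simulate a random nucleotide sequence
#'
#' Draws an i.i.d. sequence with `P(G) = P(C) = gc_fraction / 2` and
#' `P(A) = P(T) = (1 - gc_fraction) / 2`.
#'
#' @param length Number of bases (>= 1).
#' @param gc_fraction Target GC content in \[0, 1\].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A single nucleotide string.
#' @export
#' @examples
#' simulate_sequence(20, seed = 1)
simulate_sequence <- function(length, gc_fraction = 0.5, seed = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) {
    stop_segcall("length must be >= 1", class = "segcall_error_invalid")
  }
  if (gc_fraction < 0 || gc_fraction > 1) {
    stop_segcall("gc_fraction must be in [0, 1]", class = "segcall_error_invalid")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
}

#' Simulate one nanopore-like read
#'
#' For each base, draws a dwell (number of samples, >= 1, mean modulated
#' by the drift schedule) and emits that many Gaussian samples around the
#' pore model's level for the base's k-mer context (edge contexts are
#' clamped). Signals are generated directly in normalized units. The
#' returned read carries the gold per-sample alias label mask and the
#' per-base segmentation, so collapsing the mask reproduces the sequence
#' exactly.
#'
#' @param sequence Non-empty nucleotide string over `{A, C, G, T}`.
#' @param pore A [pore_model()].
#' @param dwell A [dwell_params()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param read_id Identifier stored with the read.
#' @return An object of class `simulated_read`: a list with `read_id`,
#'   `signal` (numeric, normalized units), `sequence`, `dwells`,
#'   `mask` (integer alias codes, one per sample) and `segments`
#'   (tibble `start`, `end`, `base`; 0-based half-open sample coords).
#' @export
#' @examples
#' rd <- simulate_read(simulate_sequence(30, seed = 1), seed = 2)
#' length(rd$signal) == sum(rd$dwells)
simulate_read <- function(sequence, pore = pore_model(), dwell = dwell_params(),
                          seed = NULL, read_id = "read") {
  ch <- seq_chars(sequence)
  n <- length(ch)
  if (n == 0L) stop_segcall("sequence must be non-empty", class = "segcall_error_invalid")
  stopifnot(inherits(pore, "pore_model"), inherits(dwell, "dwell_params"))
  if (!is.null(seed)) set.seed(as.integer(seed))

  contexts <- kmer_contexts(ch, pore$k)
  levels <- unname(pore$levels[contexts])

  dwells <- integer(n)
  pos <- 0
  for (i in seq_len(n)) {
    eff <- dwell$mean_dwell *
      (1 + dwell$drift_amplitude * sin(2 * pi * pos / dwell$drift_period))
    dwells[i] <- draw_dwell(dwell, eff)
    pos <- pos + dwells[i]
  }

  total <- sum(dwells)
  signal <- rnorm(total, mean = rep(levels, times = dwells), sd = pore$noise_sd)

  labels <- alias_encode(sequence)
  mask <- alias_to_int(rep(labels, times = dwells))
  ends <- cumsum(dwells)
  segments <- tibble::tibble(
    start = as.integer(ends - dwells),
    end = as.integer(ends),
    base = ch
  )
  structure(list(read_id = read_id, signal = signal, sequence = sequence,
                 dwells = dwells, mask = mask, segments = segments),
            class = "simulated_read")
}

# k-mer context string for each base, edges clamped to the sequence
kmer_contexts <- function(ch, k) {
  if (k == 1L) return(ch)
  n <- length(ch)
  left <- (k - 1L) %/% 2L
  idx <- outer(seq_len(n) - left, 0:(k - 1L), "+")
  idx[idx < 1L] <- 1L
  idx[idx > n] <- n
  apply(matrix(ch[idx], nrow = n), 1L, paste, collapse = "")
}

#' @export
print.simulated_read <- function(x, ...) {
  cat(sprintf("<simulated_read> %s: %d bases, %d samples (mean dwell %.2f)\n",
              x$read_id, nchar(x$sequence), length(x$signal),
              length(x$signal) / nchar(x$sequence)))
  invisible(x)
}

#' Simulate a set of reads
#'
#' @param n_reads Number of reads (>= 1).
#' @param read_length Bases per read.
#' @param gc_fraction GC content of the simulated sequences.
#' @inheritParams simulate_read
#' @param seed Integer seed controlling the whole set.
#' @return List of [simulate_read()] objects with ids `read_0001`, ...
#' @export
simulate_read_set <- function(n_reads, read_length, pore = pore_model(),
                              dwell = dwell_params(), gc_fraction = 0.5, seed = NULL) {
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads < 1L) {
    stop_segcall("n_reads must be >= 1", class = "segcall_error_invalid")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  lapply(seq_len(n_reads), function(i) {
    sq <- simulate_sequence(read_length, gc_fraction)
    simulate_read(sq, pore = pore, dwell = dwell,
                  read_id = sprintf("read_%04d", i))
  })
}

#' Re-express a normalized signal in raw device-like units
#'
#' Applies an affine map `scale * x + shift` so the median/MAD
#' normalization path can be exercised on simulator output.
#'
#' @param signal Numeric signal in normalized units.
#' @param scale,shift Affine parameters (device-unit-like).
#' @return Numeric signal in raw-like units.
#' @export
raw_ify <- function(signal, scale = 14, shift = 80) {
  signal * scale + shift
}

#' Build a windowed training dataset from simulated reads
#'
#' Simulates `n_reads` reads, normalizes each signal by its median and
#' median absolute deviation, splits it into non-overlapping windows of
#' `window_length` samples with aligned gold label masks (the trailing
#' partial window is dropped) and discards any window containing a
#' normalized value above the outlier threshold.
#'
#' @inheritParams simulate_read_set
#' @param window_length Samples per training window (default 300).
#' @param filter_threshold Windows containing a normalized value larger
#'   than this are excluded (default 10).
#' @param keep_reads Also return the simulated reads.
#' @return An object of class `window_set`: list with `signal` (matrix,
#'   `window_length` rows, one column per window), `labels` (integer
#'   matrix of alias codes, same shape), `meta` (tibble: `read_id`,
#'   `offset`), `window_length`, and optionally `reads`.
#' @export
#' @examples
#' ds <- make_dataset(2, 120, window_length = 100, seed = 1)
#' dim(ds$signal)
make_dataset <- function(n_reads, read_length, pore = pore_model(),
                         dwell = dwell_params(), window_length = 300L,
                         gc_fraction = 0.5, filter_threshold = 10,
                         seed = NULL, keep_reads = FALSE) {
  window_length <- as.integer(window_length)
  if (is.na(window_length) || window_length < 1L) {
    stop_segcall("window_length must be >= 1", class = "segcall_error_invalid")
  }
  reads <- simulate_read_set(n_reads, read_length, pore = pore, dwell = dwell,
                             gc_fraction = gc_fraction, seed = seed)
  out <- windows_from_reads(reads, window_length, filter_threshold = filter_threshold)
  if (keep_reads) out$reads <- reads
  out
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d samples from %d reads\n",
              ncol(x$signal), x$window_length, length(unique(x$meta$read_id))))
  invisible(x)
}

#' Gold window sequences of a window set
#'
#' Decodes each window's gold label mask into its nucleotide sequence
#' (collapse + alias decode), the reference for window-level NED.
#'
#' @param ds A [make_dataset()] result.
#' @return Character vector, one sequence per window.
#' @export
window_gold_sequences <- function(ds) {
  stopifnot(inherits(ds, "window_set"))
  vapply(seq_len(ncol(ds$labels)), function(j) {
    collapse_mask(ds$labels[, j])$sequence
  }, character(1))
}
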