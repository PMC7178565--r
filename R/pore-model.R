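#' Pore model: expected current level per k-mer context
#'
#' Maps every k-mer over `{A, C, G, T}` to a mean normalized current
#' level plus a Gaussian noise scale. Levels live in normalized-signal
#' units (typically within \[-2, 2\]). The default 1-mer model places the
#' four bases at well-separated levels so that small networks can learn
#' the mapping at desk scale; larger `k` yields context-dependent levels
#' for harder benchmarks.
#'
#' For `k > 1` with `levels = NULL`, the level of a k-mer is a weighted
#' mean of its bases' 1-mer levels (centre base weight 2, neighbours 1),
#' which produces context blur without any claim of physical fidelity.
#'
#' @param k Context width (positive integer).
#' @param levels Optional named numeric vector with exactly `4^k`
#'   entries, one per k-mer (names are the k-mers).
#' @param noise_sd Gaussian standard deviation of sample noise, shared
#'   across k-mers (normalized units, > 0).
#' @return An object of class `pore_model`.
#' @export
#' @examples
#' pore_model()
#' pore_model(k = 3, noise_sd = 0.2)
pore_model <- function(k = 1L, levels = NULL, noise_sd = 0.15) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop_segcall("k must be >= 1", class = "segcall_error_invalid")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0) {
    stop_segcall("noise_sd must be a single value > 0", class = "segcall_error_invalid")
  }
  kmers <- all_kmers(k)
  base_levels <- c(A = -1.0, C = -0.33, G = 0.33, T = 1.0)
  if (is.null(levels)) {
    if (k == 1L) {
      levels <- setNames(base_levels[kmers], kmers)
    } else {
      w <- rep(1, k); w[(k + 1L) %/% 2L] <- 2
      w <- w / sum(w)
      levels <- vapply(strsplit(kmers, "", fixed = TRUE), function(ch) {
        sum(base_levels[ch] * w)
      }, numeric(1))
      names(levels) <- kmers
    }
  } else {
    if (length(levels) != length(kmers) || is.null(names(levels)) ||
        !setequal(names(levels), kmers)) {
      stop_segcall(sprintf("levels must contain exactly %d named k-mer entries", 4^k),
                   class = "segcall_error_invalid")
    }
    levels <- levels[kmers]
  }
  structure(list(k = k, levels = levels, noise_sd = noise_sd), class = "pore_model")
}

all_kmers <- function(k) {
  if (k == 1L) return(BASES)
  grid <- do.call(expand.grid, c(rep(list(BASES), k), stringsAsFactors = FALSE))
  # first column varies slowest so ordering is lexicographic
  apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste, collapse = "")
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf("<pore_model> k = %d, %d k-mer levels in [%.2f, %.2f], noise_sd = %.3g\n",
              x$k, length(x$levels), min(x$levels), max(x$levels), x$noise_sd))
  invisible(x)
}

#' Dwell-time model: samples emitted per base
#'
#' Describes how many raw current samples each base produces while it
#' occupies the pore, with an optional slow sinusoidal modulation of the
#' mean that emulates translocation-speed changes over a read. Every
#' sampled dwell is at least 1.
#'
#' Distributions: `"geometric"` draws `1 + Geom(1/mean_dwell)` (mean
#' `mean_dwell`, heavy right tail, the default, emulating the strongly
#' uneven per-base durations of real squiggles); `"nbinom"` draws
#' `1 + NegBinom(mu = mean_dwell - 1, size = nb_size)` (tighter when
#' `nb_size` is large); `"fixed"` emits exactly `round(mean_dwell)`
#' samples per base (deterministic; used for easy end-to-end checks).
#'
#' @param mean_dwell Expected samples per base (> 1). The default 9
#'   corresponds to roughly 450 bases/s at 4 kHz sampling.
#' @param distribution One of `"geometric"`, `"nbinom"`, `"fixed"`.
#' @param drift_amplitude Relative modulation of the mean dwell over
#'   time (>= 0, < 1); 0 disables drift.
#' @param drift_period Samples per modulation cycle (> 0).
#' @param nb_size Negative-binomial size (dispersion) parameter.
#' @return An object of class `dwell_params`.
#' @export
#' @examples
#' dwell_params()
#' dwell_params(9, "fixed", drift_amplitude = 0)
dwell_params <- function(mean_dwell = 9, distribution = c("geometric", "nbinom", "fixed"),
                         drift_amplitude = 0.3, drift_period = 2000, nb_size = 10) {
  distribution <- match.arg(distribution)
  if (!is.numeric(mean_dwell) || mean_dwell <= 1) {
    stop_segcall("mean_dwell must be > 1", class = "segcall_error_invalid")
  }
  if (drift_amplitude < 0 || drift_amplitude >= 1) {
    stop_segcall("drift_amplitude must be in [0, 1)", class = "segcall_error_invalid")
  }
  if (drift_period <= 0) stop_segcall("drift_period must be > 0", class = "segcall_error_invalid")
  structure(list(mean_dwell = mean_dwell, distribution = distribution,
                 drift_amplitude = drift_amplitude, drift_period = drift_period,
                 nb_size = nb_size),
            class = "dwell_params")
}

#' @export
print.dwell_params <- function(x, ...) {
  cat(sprintf("<dwell_params> %s, mean %.3g samples/base, drift %.2g (period %.5g samples)\n",
              x$distribution, x$mean_dwell, x$drift_amplitude, x$drift_period))
  invisible(x)
}

# draw one dwell (>= 1 samples) given the current effective mean
draw_dwell <- function(dw, eff_mean) {
  eff_mean <- max(eff_mean, 1 + 1e-6)
  switch(dw$distribution,
    geometric = 1L + rgeom(1L, prob = 1 / eff_mean),
    nbinom    = 1L + rnbinom(1L, size = dw$nb_size, mu = eff_mean - 1),
    fixed     = max(1L, as.integer(round(eff_mean)))
  )
}
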