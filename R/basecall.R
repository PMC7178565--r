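#' Basecall one read
#'
#' Runs the full inference pipeline on a normalized signal: plan
#' overlapping windows ([window_infer()]), predict per-sample label
#' probabilities for each window, soft-merge the overlaps
#' ([soft_merge()]), collapse runs of identical labels into bases and
#' segments ([collapse_mask()]), and decode the alias labels.
#'
#' @param model A `urnet_model` or `urnet_fit`.
#' @param signal Normalized numeric signal of length >= `window_length`.
#' @param window_length Window length L (default 300).
#' @param step Step s between window starts (default 290).
#' @param weighting Overlap weighting passed to [soft_merge()].
#' @param batch_size Windows per forward pass.
#' @return List with `sequence` (basecall string), `segments` (tibble
#'   `start`, `end`, `base`; 0-based half-open sample coordinates) and
#'   `track` (the [soft_merge()] result).
#' @export
basecall_read <- function(model, signal, window_length = 300L, step = 290L,
                          weighting = "crossfade", batch_size = 64L) {
  model <- as_urnet_model(model)
  n <- length(signal)
  offs <- window_infer(n, window_length, step)
  wins <- vapply(offs, function(o) signal[(o + 1L):(o + window_length)],
                 numeric(window_length))
  probs <- predict_probs(model, wins, batch_size = batch_size)
  preds <- lapply(seq_along(offs), function(i) {
    list(offset = offs[i], probs = probs[, , i])
  })
  track <- soft_merge(preds, n, weighting = weighting)
  col <- collapse_mask(track$labels)
  list(sequence = col$sequence, segments = col$segments, track = track)
}

#' Basecall a set of reads
#'
#' Applies [basecall_read()] to each read; reads shorter than the window
#' length are reported as skipped rather than failing the run.
#'
#' @param model A `urnet_model` or `urnet_fit`.
#' @param reads List of numeric signals, or of `simulated_read`s (their
#'   `$signal` is used); names or `read_id`s become read identifiers.
#' @inheritParams basecall_read
#' @return Tibble with one row per read: `read_id`, `n_samples`,
#'   `called` (FALSE when skipped as too short), `sequence`, and a
#'   list-column `segments`.
#' @export
basecall_reads <- function(model, reads, window_length = 300L, step = 290L,
                           weighting = "crossfade", batch_size = 64L) {
  model <- as_urnet_model(model)
  ids <- read_ids(reads)
  rows <- lapply(seq_along(reads), function(i) {
    sig <- read_signal(reads[[i]])
    res <- tryCatch(
      basecall_read(model, sig, window_length, step, weighting, batch_size),
      segcall_error_short_read = function(e) NULL
    )
    if (is.null(res)) {
      tibble::tibble(read_id = ids[i], n_samples = length(sig), called = FALSE,
                     sequence = NA_character_, segments = list(NULL))
    } else {
      tibble::tibble(read_id = ids[i], n_samples = length(sig), called = TRUE,
                     sequence = res$sequence, segments = list(res$segments))
    }
  })
  dplyr::bind_rows(rows)
}

read_signal <- function(r) {
  if (inherits(r, "simulated_read")) r$signal else as.numeric(r)
}

read_ids <- function(reads) {
  ids <- vapply(seq_along(reads), function(i) {
    r <- reads[[i]]
    if (inherits(r, "simulated_read")) r$read_id
    else if (!is.null(names(reads)) && nzchar(names(reads)[i])) names(reads)[i]
    else sprintf("read_%04d", i)
  }, character(1))
  make.unique(ids)
}
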