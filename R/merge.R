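#' Soft-merge overlapping window predictions over a read
#'
#' Each covering window contributes its per-sample class-probability
#' rows, weighted by a linear cross-fade: across the overlap of length V
#' between consecutive windows, the earlier window's weight ramps from 1
#' down to 0 and the later window's from 0 up to 1 (at overlap position
#' `v = 0..V-1` the weights are `(V - v)/V` and `v/V`). Positions covered
#' by a single window keep that window's row unchanged. Where the
#' anchored tail window creates deeper than pairwise coverage, the
#' per-window weights are renormalized to sum to one. The winning label
#' at each sample is the argmax of the merged vector, ties broken by the
#' fixed label order (lowest index wins). `weighting = "uniform"` gives
#' all covering windows equal weight instead.
#'
#' @param predictions List of window predictions, each a list with
#'   `offset` (0-based start sample) and `probs` (L x 8 matrix).
#'   Order does not matter; windows are sorted by offset internally.
#' @param read_length Total read length N; the windows must cover
#'   `[0, N)` without gaps.
#' @param weighting `"crossfade"` (default) or `"uniform"`.
#' @return An object of class `merged_track`: list with `labels`
#'   (integer alias codes, length N), `score` (merged probability of the
#'   winning label) and `probs` (N x 8 merged matrix).
#' @export
soft_merge <- function(predictions, read_length,
                       weighting = c("crossfade", "uniform")) {
  weighting <- match.arg(weighting)
  read_length <- as.integer(read_length)
  if (!length(predictions)) {
    stop_segcall("no window predictions supplied", class = "segcall_error_invalid")
  }
  offs <- vapply(predictions, function(p) as.integer(p$offset), integer(1))
  ord <- order(offs)
  predictions <- predictions[ord]; offs <- offs[ord]
  Ls <- vapply(predictions, function(p) nrow(p$probs), integer(1))

  # coverage check: sorted windows must tile [0, N) without gaps
  if (offs[1L] != 0L || max(offs + Ls) < read_length) {
    stop_segcall("windows do not cover the read", class = "segcall_error_coverage")
  }
  reach <- cummax(offs + Ls)
  if (length(offs) > 1L && any(offs[-1L] > reach[-length(reach)])) {
    stop_segcall("coverage gap between windows", class = "segcall_error_coverage")
  }

  m <- length(predictions)
  acc <- matrix(0, read_length, 8L)
  wacc <- numeric(read_length)
  for (j in seq_len(m)) {
    L <- Ls[j]
    w <- rep(1, L)
    if (weighting == "crossfade") {
      if (j > 1L) {
        vprev <- min(L, max(0L, offs[j - 1L] + Ls[j - 1L] - offs[j]))
        if (vprev > 0L) {
          ramp_up <- (seq_len(vprev) - 1L) / vprev
          w[seq_len(vprev)] <- pmin(w[seq_len(vprev)], ramp_up)
        }
      }
      if (j < m) {
        vnext <- min(L, max(0L, offs[j] + Ls[j] - offs[j + 1L]))
        if (vnext > 0L) {
          ramp_down <- (vnext - (seq_len(vnext) - 1L)) / vnext
          at <- L - vnext + seq_len(vnext)
          w[at] <- pmin(w[at], ramp_down)
        }
      }
    }
    pos <- offs[j] + seq_len(L)
    acc[pos, ] <- acc[pos, ] + predictions[[j]]$probs * w
    wacc[pos] <- wacc[pos] + w
  }
  # degenerate all-zero weight (possible only at exact ramp endpoints
  # under unusual window plans): fall back to an unweighted mean there
  zero <- wacc <= 1e-12
  if (any(zero)) {
    for (j in seq_len(m)) {
      pos <- offs[j] + seq_len(Ls[j])
      hit <- zero[pos]
      if (any(hit)) {
        acc[pos[hit], ] <- acc[pos[hit], ] + predictions[[j]]$probs[hit, , drop = FALSE]
        wacc[pos[hit]] <- wacc[pos[hit]] + 1
      }
    }
  }
  merged <- acc / wacc
  labels <- max.col(merged, ties.method = "first")
  structure(list(labels = labels,
                 score = merged[cbind(seq_len(read_length), labels)],
                 probs = merged),
            class = "merged_track")
}

#' @export
print.merged_track <- function(x, ...) {
  cat(sprintf("<merged_track> %d samples, %d collapsed bases\n",
              length(x$labels), length(rle(x$labels)$lengths)))
  invisible(x)
}
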