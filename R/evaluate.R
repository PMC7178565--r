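#' Levenshtein edit distance
#'
#' Unit-cost insertion/deletion/substitution distance between two
#' strings, computed by dynamic programming (base R's generalized
#' Levenshtein routine).
#'
#' @param a,b Single strings.
#' @return Non-negative integer.
#' @export
#' @examples
#' edit_distance("ACGT", "ACG")
edit_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  as.integer(adist(a, b))
}

#' Normalized edit distance (NED)
#'
#' Edit distance between call and gold sequence divided by the gold
#' length (set `normalize = "max"` to divide by the longer of the two).
#'
#' @param pred Predicted sequence.
#' @param gold Gold sequence (non-empty for gold normalization).
#' @param normalize `"gold"` (default) or `"max"`.
#' @return Non-negative rate (0 for identical strings).
#' @export
#' @examples
#' ned("ACG", "ACGT")
ned <- function(pred, gold, normalize = c("gold", "max")) {
  normalize <- match.arg(normalize)
  denom <- switch(normalize,
    gold = nchar(gold),
    max = max(nchar(pred), nchar(gold)))
  if (denom == 0L) {
    stop_segcall("gold sequence must be non-empty", class = "segcall_error_invalid")
  }
  edit_distance(pred, gold) / denom
}

#' Alignment error counts of a read against a reference
#'
#' Semi-global alignment (read global, reference local: reference flanks
#' are free) with unit mismatch and gap costs, traced back with
#' deterministic tie-breaking (match over mismatch over deletion over
#' insertion at equal cost). `M` counts matched bases, `U` mismatches,
#' `I` insertions (read bases absent from the reference) and `D`
#' deletions (reference bases absent from the read);
#' `M + U + I = nchar(read)` always holds.
#'
#' @param read,reference Non-empty nucleotide strings.
#' @return Named list with `M`, `U`, `I`, `D`, and the aligned reference
#'   interval `ref_start`/`ref_end` (0-based half-open).
#' @export
#' @examples
#' align_counts("ACGT", "ACGTACGT")
align_counts <- function(read, reference) {
  stopifnot(is.character(read), is.character(reference))
  if (nchar(read) == 0L || nchar(reference) == 0L) {
    stop_segcall("read and reference must be non-empty", class = "segcall_error_invalid")
  }
  as.list(cpp_align_counts(read, reference))
}

#' Read accuracy and identity from alignment counts
#'
#' `read_accuracy` is `M / (M + U + I + D)`; `read_identity` is
#' `M / ref_span`, where `ref_span` is the number of reference bases the
#' read is scored against (typically the reference length).
#'
#' @param counts A list with `M`, `U`, `I`, `D` (e.g. [align_counts()]).
#' @param ref_span Positive reference base count for the identity
#'   denominator.
#' @return A rate in \[0, 1\].
#' @export
#' @examples
#' read_accuracy(list(M = 90, U = 4, I = 3, D = 3))
read_accuracy <- function(counts) {
  denom <- counts$M + counts$U + counts$I + counts$D
  if (denom <= 0) stop_segcall("undefined metric: zero alignment counts",
                               class = "segcall_error_invalid")
  counts$M / denom
}

#' @rdname read_accuracy
#' @export
read_identity <- function(counts, ref_span) {
  if (ref_span <= 0) stop_segcall("ref_span must be > 0", class = "segcall_error_invalid")
  counts$M / ref_span
}

#' Assembly identity and relative length summaries
#'
#' `AI` is the mean per-contig accuracy and `RL` the mean ratio of
#' predicted to reference length. A contig whose aligned span is less
#' than half its component length is treated as unaligned and
#' contributes an accuracy of 0 (supply `aligned_spans` and
#' `component_lengths` to apply the rule; contigs already screened can
#' be passed directly).
#'
#' @param per_contig_ra Numeric vector of per-contig accuracy rates.
#' @param pred_lengths,ref_lengths Equal-length positive integer
#'   vectors of predicted and reference lengths.
#' @param aligned_spans,component_lengths Optional equal-length vectors
#'   enforcing the half-length unaligned rule.
#' @return List with `AI` and `RL`, both rates (multiply by 100 for the
#'   conventional percentage form).
#' @export
#' @examples
#' assembly_summary(c(0.97, 0.99, 0.98), c(100, 100, 100), c(100, 100, 100))
assembly_summary <- function(per_contig_ra, pred_lengths, ref_lengths,
                             aligned_spans = NULL, component_lengths = NULL) {
  n <- length(per_contig_ra)
  if (n == 0L || length(pred_lengths) != n || length(ref_lengths) != n) {
    stop_segcall("inputs must be equal-length non-empty vectors",
                 class = "segcall_error_invalid")
  }
  ra <- per_contig_ra
  if (!is.null(aligned_spans) && !is.null(component_lengths)) {
    ra[aligned_spans < component_lengths / 2] <- 0
  }
  list(AI = mean(ra), RL = mean(pred_lengths / ref_lengths))
}

#' Homopolymer run-length histogram
#'
#' Counts every maximal run of identical bases; single nucleotides count
#' as length-1 homopolymers, so run lengths times counts sum to the
#' sequence length.
#'
#' @param sequence Nucleotide string over `{A, C, G, T}` (may be empty).
#' @return Tibble with columns `base`, `length`, `count`.
#' @export
#' @examples
#' homopolymer_histogram("AAACCT")
homopolymer_histogram <- function(sequence) {
  ch <- seq_chars(sequence)
  if (length(ch) == 0L) {
    return(tibble::tibble(base = character(0), length = integer(0), count = integer(0)))
  }
  r <- rle(ch)
  tibble::tibble(base = r$values, length = r$lengths) |>
    dplyr::count(.data$base, .data$length, name = "count") |>
    dplyr::arrange(.data$base, .data$length)
}

#' Evaluate basecalls against truth sequences
#'
#' Aligns each call to its own truth sequence, computes NED, read
#' accuracy and identity, and error rates normalized both by read and by
#' reference length (both normalizations are reported since either
#' convention is found in practice). A read whose matched bases cover
#' less than half of the read (identity below 50%) is flagged unaligned
#' and excluded from the aggregate means, the desk-scale surrogate for
#' reads a production aligner would fail to map.
#'
#' @param calls Character vector of basecalled sequences.
#' @param truths Character vector of gold/reference sequences, same
#'   length and order.
#' @param read_ids Optional identifiers.
#' @return An object of class `metrics_report`: list with `per_read`
#'   (tibble of per-read metrics) and `summary` (tibble of aggregate
#'   mean/sd over aligned reads plus the unaligned count).
#' @export
evaluate_reads <- function(calls, truths, read_ids = NULL) {
  stopifnot(length(calls) == length(truths))
  if (is.null(read_ids)) read_ids <- sprintf("read_%04d", seq_along(calls))
  rows <- lapply(seq_along(calls), function(i) {
    cl <- calls[i]; tr <- truths[i]
    cn <- align_counts(cl, tr)
    ref_len <- nchar(tr)
    aligned <- cn$M >= 0.5 * nchar(cl)
    tibble::tibble(
      read_id = read_ids[i],
      read_length = nchar(cl), ref_length = ref_len,
      ned = ned(cl, tr),
      M = cn$M, U = cn$U, I = cn$I, D = cn$D,
      read_accuracy = read_accuracy(cn),
      read_identity = read_identity(cn, ref_len),
      mismatch_rate_read = cn$U / nchar(cl),
      insertion_rate_read = cn$I / nchar(cl),
      deletion_rate_read = cn$D / nchar(cl),
      mismatch_rate_ref = cn$U / ref_len,
      insertion_rate_ref = cn$I / ref_len,
      deletion_rate_ref = cn$D / ref_len,
      aligned = aligned
    )
  })
  per_read <- dplyr::bind_rows(rows)
  ok <- dplyr::filter(per_read, .data$aligned)
  summary <- tibble::tibble(
    metric = c("ned", "read_accuracy", "read_identity"),
    mean = c(mean(ok$ned), mean(ok$read_accuracy), mean(ok$read_identity)),
    sd = c(stats::sd(ok$ned), stats::sd(ok$read_accuracy), stats::sd(ok$read_identity))
  )
  structure(list(per_read = per_read, summary = summary,
                 n_unaligned = sum(!per_read$aligned), n_reads = nrow(per_read)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d reads (%d unaligned)\n", x$n_reads, x$n_unaligned))
  print(x$summary)
  invisible(x)
}

#' Window-level NED of a model on a held-out window set
#'
#' Basecalls each window independently (argmax + collapse) and computes
#' NED against the gold window sequence.
#'
#' @param model A `urnet_model` or `urnet_fit`.
#' @param ds A `window_set` with gold labels.
#' @param batch_size Windows per forward pass.
#' @return Tibble with one row per window (`read_id`, `offset`, `ned`).
#' @export
evaluate_windows <- function(model, ds, batch_size = 64L) {
  stopifnot(inherits(ds, "window_set"))
  calls <- basecall_windows(model, ds$signal, batch_size = batch_size)
  gold <- window_gold_sequences(ds)
  tibble::tibble(read_id = ds$meta$read_id, offset = ds$meta$offset,
                 ned = mapply(ned, calls, gold, USE.NAMES = FALSE))
}

#' Duration-ambiguity lower bound on homopolymer NED
#'
#' Inside a homopolymer the pore current is constant up to noise, so
#' under a context width of 1 the only evidence for the run length is
#' the total dwell duration. This computes the Bayes-optimal expected
#' edit errors per base for run-length-from-duration inference — the
#' posterior-median estimator under the dwell distribution and the run
#' length prior implied by an i.i.d. sequence — which lower-bounds the
#' NED achievable by any basecaller on such data. With heavy-tailed
#' (geometric) dwells the bound is substantial; with deterministic
#' dwells it is 0.
#'
#' @param dwell A [dwell_params()] (drift is ignored: modulating the
#'   mean does not change the per-run ambiguity materially).
#' @param gc_fraction GC content of the sequence model; with symmetric
#'   base usage the run-continuation probability of base b is P(b).
#' @param max_run Truncation of the run-length prior.
#' @param max_t Truncation of the duration distribution.
#' @return Expected minimum NED contribution (errors per gold base).
#' @export
#' @examples
#' dwell_ambiguity_floor(dwell_params(9, "geometric"))
#' dwell_ambiguity_floor(dwell_params(9, "fixed"))
dwell_ambiguity_floor <- function(dwell, gc_fraction = 0.5, max_run = 30L,
                                  max_t = 3000L) {
  stopifnot(inherits(dwell, "dwell_params"))
  # average over the four bases' continuation probabilities
  pb <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
          (1 - gc_fraction) / 2)
  floor_for <- function(q) {   # q = P(run continues)
    if (q <= 0) return(0)
    prior <- (1 - q) * q^(0:(max_run - 1L))
    prior <- prior / sum(prior)
    tt <- seq_len(max_t)
    lik <- vapply(seq_len(max_run), function(k) {
      switch(dwell$distribution,
        geometric = stats::dnbinom(tt - k, size = k, prob = 1 / dwell$mean_dwell),
        nbinom = {
          # sum of k iid (1 + NB(mu, size)) = k + NB(k*mu?, ...) only for
          # shared prob; use the additive-size property of NB(size, prob)
          p <- dwell$nb_size / (dwell$nb_size + dwell$mean_dwell - 1)
          stats::dnbinom(tt - k, size = k * dwell$nb_size, prob = p)
        },
        fixed = as.numeric(tt == k * max(1L, as.integer(round(dwell$mean_dwell)))))
    }, numeric(max_t))
    post <- sweep(lik, 2L, prior, "*")
    rs <- rowSums(post)
    keep <- rs > 0
    post[keep, ] <- post[keep, , drop = FALSE] / rs[keep]
    khat <- apply(post, 1L, function(pr) {
      if (all(pr == 0)) return(1L)
      which(cumsum(pr) >= 0.5)[1L]
    })
    err <- sum(vapply(seq_len(max_run), function(k) {
      prior[k] * sum(lik[, k] * abs(khat - k))
    }, numeric(1)))
    ek <- sum(prior * seq_len(max_run))
    c(err = err, ek = ek)
  }
  res <- vapply(pb, floor_for, numeric(2))
  # weight each base's runs by how often runs of that base occur
  run_rate <- pb * (1 - pb)            # prop. to runs of base b per position
  wb <- run_rate / sum(run_rate)
  sum(wb * res["err", ]) / sum(wb * res["ek", ])
}
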