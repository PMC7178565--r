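#' Write and read simulated read sets
#'
#' Serializes a list of simulated reads (signal, sequence, per-sample
#' alias mask and segment table per read) to a JSON container, with an
#' optional FASTA of the reference sequences alongside.
#'
#' @param reads List of `simulated_read` objects.
#' @param path Output JSON path.
#' @param fasta Optional path for a FASTA of the reference sequences.
#' @return `path`, invisibly.
#' @export
write_read_set <- function(reads, path, fasta = NULL) {
  payload <- list(
    format = "segcall_reads",
    version = 1L,
    reads = lapply(reads, function(r) {
      list(read_id = r$read_id, sequence = r$sequence,
           signal = r$signal, mask = r$mask,
           segments = as.list(r$segments))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(fasta)) {
    seqs <- setNames(vapply(reads, `[[`, character(1), "sequence"),
                     vapply(reads, `[[`, character(1), "read_id"))
    write_fasta(seqs, fasta)
  }
  invisible(path)
}

#' @rdname write_read_set
#' @export
read_read_set <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "segcall_reads")) {
    stop_segcall("not a segcall read-set file", class = "segcall_error_io")
  }
  rd <- payload$reads
  lapply(seq_len(nrow(rd)), function(i) {
    seg <- rd$segments[i, ]
    dwells <- diff(c(0L, as.integer(unlist(seg$end))))
    structure(list(read_id = rd$read_id[i], signal = as.numeric(rd$signal[[i]]),
                   sequence = rd$sequence[i], dwells = dwells,
                   mask = as.integer(rd$mask[[i]]),
                   segments = tibble::tibble(start = as.integer(unlist(seg$start)),
                                             end = as.integer(unlist(seg$end)),
                                             base = as.character(unlist(seg$base)))),
              class = "simulated_read")
  })
}

#' FASTA and FASTQ writers/readers
#'
#' Thin wrappers around Biostrings for the sequence formats the
#' basecaller touches. FASTQ output carries a uniform placeholder
#' quality (no quality model is calibrated).
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @param path Output path.
#' @param quality_char Placeholder per-base quality character.
#' @return `path` (writers) or a named character vector (reader).
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname write_fasta
#' @export
write_fastq <- function(sequences, path, quality_char = "I") {
  x <- Biostrings::DNAStringSet(sequences)
  q <- Biostrings::BStringSet(vapply(nchar(sequences), function(n) {
    paste(rep(quality_char, n), collapse = "")
  }, character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Write per-base signal segments as BED-like TSV
#'
#' Columns `read_id`, `start`, `end`, `base` with 0-based half-open
#' sample coordinates (signal-sample space, not genomic).
#'
#' @param segments Tibble with those columns (e.g. [basecall_reads()]
#'   segments bound with their read ids).
#' @param path Output path.
#' @export
write_segments_bed <- function(segments, path) {
  stopifnot(all(c("read_id", "start", "end", "base") %in% names(segments)))
  write.table(segments[, c("read_id", "start", "end", "base")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Save and load trained models
#'
#' JSON checkpoint holding the architecture configuration, all
#' parameter tensors and the batch-norm running statistics at full
#' precision.
#'
#' @param model A `urnet_model` or `urnet_fit`.
#' @param path Checkpoint path (JSON).
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored `urnet_model`.
#' @export
save_model <- function(model, path) {
  model <- as_urnet_model(model)
  payload <- list(
    format = "segcall_model", version = 1L,
    config = unclass(model$config),
    window_length = model$window_length,
    params = lapply(model$params, function(p) {
      list(dim = if (is.matrix(p)) dim(p) else length(p), data = as.vector(p))
    }),
    state = model$state
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "segcall_model")) {
    stop_segcall("not a segcall model checkpoint", class = "segcall_error_io")
  }
  cfg <- do.call(urnet_config, payload$config[c("variant", "n_levels", "filters",
                                               "kernel_size", "pool_factors",
                                               "rnn_units", "final_rnn_layers",
                                               "n_classes")])
  model <- build_model(cfg, window_length = payload$window_length, seed = 1L)
  stopifnot(setequal(names(model$params), names(payload$params)))
  for (nm in names(model$params)) {
    entry <- payload$params[[nm]]
    dm <- as.integer(unlist(entry$dim))
    dat <- as.numeric(unlist(entry$data))
    model$params[[nm]] <- if (length(dm) == 2L) matrix(dat, dm[1L], dm[2L]) else dat
  }
  for (nm in names(model$state)) {
    model$state[[nm]] <- list(mean = as.numeric(unlist(payload$state[[nm]]$mean)),
                              var = as.numeric(unlist(payload$state[[nm]]$var)))
  }
  model
}

#' Build training windows from existing reads
#'
#' The windowing half of [make_dataset()] for reads that were simulated
#' earlier or loaded from disk: normalize each read, cut non-overlapping
#' windows with aligned gold masks, drop the remainder and filter
#' outlier windows.
#'
#' @param reads List of `simulated_read` objects.
#' @param window_length Samples per window.
#' @param filter_threshold Outlier threshold (default 10).
#' @return A `window_set` (see [make_dataset()]).
#' @export
windows_from_reads <- function(reads, window_length = 300L, filter_threshold = 10) {
  sig_cols <- list(); lab_cols <- list(); meta <- list()
  for (rd in reads) {
    nm <- normalize_signal(rd$signal)
    w <- window_train(nm$samples, rd$mask, window_length,
                      filter_threshold = filter_threshold)
    if (ncol(w$signal) == 0L) next
    sig_cols[[length(sig_cols) + 1L]] <- w$signal
    lab_cols[[length(lab_cols) + 1L]] <- w$labels
    meta[[length(meta) + 1L]] <- tibble::tibble(read_id = rd$read_id, offset = w$offsets)
  }
  if (!length(sig_cols)) {
    return(structure(list(signal = matrix(numeric(0), window_length, 0),
                          labels = matrix(integer(0), window_length, 0),
                          meta = tibble::tibble(read_id = character(0), offset = integer(0)),
                          window_length = as.integer(window_length)),
                     class = "window_set"))
  }
  structure(list(signal = do.call(cbind, sig_cols),
                 labels = do.call(cbind, lab_cols),
                 meta = dplyr::bind_rows(meta),
                 window_length = as.integer(window_length)),
            class = "window_set")
}
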