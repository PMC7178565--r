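#' The alias label alphabet
#'
#' Eight per-sample segmentation labels: each nucleotide exists in two
#' phases so that adjacent identical bases in a homopolymer carry
#' different labels and survive run-collapse. The vector order
#' `A1 < A2 < C1 < C2 < G1 < G2 < T1 < T2` is the fixed total order used
#' for one-hot indexing and for deterministic argmax tie-breaking.
#'
#' @return Character vector of the 8 labels in their fixed order.
#' @export
#' @examples
#' alias_alphabet()
alias_alphabet <- function() {
  c("A1", "A2", "C1", "C2", "G1", "G2", "T1", "T2")
}

BASES <- c("A", "C", "G", "T")

# split a DNA string into single characters, validating the alphabet
seq_chars <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) return(character(0))
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(ch %in% BASES)) {
    bad <- unique(ch[!ch %in% BASES])
    stop_segcall(
      paste0("sequence contains non-ACGT characters: ", paste(bad, collapse = ", ")),
      class = "segcall_error_alphabet"
    )
  }
  ch
}

#' Encode a nucleotide sequence into alias labels
#'
#' Within each maximal homopolymer run the phase alternates 1, 2, 1, 2, ...
#' starting at 1, and resets to 1 at every base change, so `"AAAAA"`
#' becomes `A1 A2 A1 A2 A1`. Bases outside runs are all phase 1.
#'
#' @param sequence A single string over `{A, C, G, T}`.
#' @return Character vector of alias labels, one per base.
#' @seealso [alias_decode()], [collapse_mask()]
#' @export
#' @examples
#' alias_encode("AAAAA")
#' alias_encode("ACGT")
alias_encode <- function(sequence) {
  ch <- seq_chars(sequence)
  if (length(ch) == 0L) return(character(0))
  r <- rle(ch)
  phase <- unlist(lapply(r$lengths, function(l) rep_len(c(1L, 2L), l)), use.names = FALSE)
  paste0(ch, phase)
}

#' Decode alias labels back to a nucleotide sequence
#'
#' Drops the phase digit from each label. Inverse of [alias_encode()]
#' composed with any per-sample expansion/collapse.
#'
#' @param labels Character vector of alias labels, or integer codes 1..8.
#' @return A single nucleotide string.
#' @export
#' @examples
#' alias_decode(c("A1", "A2", "A1", "A2", "A1"))
alias_decode <- function(labels) {
  labels <- as_alias_chr(labels)
  if (length(labels) == 0L) return("")
  paste(substr(labels, 1L, 1L), collapse = "")
}

#' Convert between alias labels and their integer codes
#'
#' Codes 1..8 follow the fixed label order (`A1` is 1, `T2` is 8); the
#' same order indexes one-hot columns and breaks argmax ties.
#'
#' @param labels Character vector of alias labels.
#' @param codes Integer vector with values in 1..8.
#' @return `alias_to_int()` returns integer codes; `int_to_alias()` labels.
#' @export
alias_to_int <- function(labels) {
  if (is.numeric(labels)) {
    codes <- as.integer(labels)
  } else {
    codes <- match(labels, alias_alphabet())
  }
  if (length(codes) && (anyNA(codes) || any(codes < 1L | codes > 8L))) {
    stop_segcall("invalid alias labels", class = "segcall_error_alphabet")
  }
  codes
}

#' @rdname alias_to_int
#' @export
int_to_alias <- function(codes) {
  alias_alphabet()[alias_to_int(codes)]
}

as_alias_chr <- function(labels) {
  if (is.numeric(labels)) int_to_alias(labels) else {
    alias_to_int(labels) # validates
    as.character(labels)
  }
}

#' Collapse a per-sample label mask into basecalls and segments
#'
#' Maximal runs of identical alias labels become single labels; each
#' run's half-open sample interval becomes one segment carrying the
#' label's base. This is the post-processing step that turns the
#' network's per-sample mask into a sequence plus its segmentation.
#'
#' @param mask Character vector of alias labels or integer codes 1..8,
#'   one per signal sample.
#' @return A list with `labels` (collapsed alias labels), `sequence`
#'   (decoded nucleotide string) and `segments`, a tibble with 0-based
#'   half-open columns `start`, `end` and `base`.
#' @export
#' @examples
#' collapse_mask(c("A1", "A1", "A2", "A2", "A2", "C1"))
collapse_mask <- function(mask) {
  mask <- as_alias_chr(mask)
  if (length(mask) == 0L) {
    return(list(
      labels = character(0), sequence = "",
      segments = tibble::tibble(start = integer(0), end = integer(0), base = character(0))
    ))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  labels <- r$values
  list(
    labels = labels,
    sequence = alias_decode(labels),
    segments = tibble::tibble(
      start = as.integer(starts),
      end = as.integer(ends),
      base = substr(labels, 1L, 1L)
    )
  )
}

#' Expand collapsed labels into a per-sample mask
#'
#' Repeats label `i` `dwells[i]` times; the inverse of [collapse_mask()]
#' whenever consecutive labels differ. Used by the simulator to paint
#' gold masks and by tests of the collapse round trip.
#'
#' @param labels Character alias labels or integer codes.
#' @param dwells Positive integer vector, same length as `labels`.
#' @return Character vector of per-sample alias labels.
#' @export
#' @examples
#' expand_labels(c("A1", "A2"), c(2, 3))
expand_labels <- function(labels, dwells) {
  labels <- as_alias_chr(labels)
  dwells <- as.integer(dwells)
  if (length(labels) != length(dwells)) {
    stop_segcall("labels and dwells must have equal length", class = "segcall_error_invalid")
  }
  if (length(dwells) && any(dwells < 1L)) {
    stop_segcall("all dwells must be >= 1", class = "segcall_error_invalid")
  }
  rep(labels, times = dwells)
}

#' One-hot encode a label mask
#'
#' @param mask Alias labels (character) or integer codes 1..8.
#' @return A `length(mask)` by 8 matrix of 0/1, columns in the fixed
#'   label order; every row sums to 1.
#' @export
one_hot <- function(mask) {
  codes <- alias_to_int(mask)
  m <- matrix(0, nrow = length(codes), ncol = 8L,
              dimnames = list(NULL, alias_alphabet()))
  if (length(codes)) m[cbind(seq_along(codes), codes)] <- 1
  m
}
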