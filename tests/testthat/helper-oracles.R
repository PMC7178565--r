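# Independent reference implementations used only as test oracles.

# memoized recursive Levenshtein, independent of the package path
oracle_edit <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste0(i, ",", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- min(rec(i - 1L, j - 1L) + (av[i] != bv[j]),
             rec(i - 1L, j) + 1L,
             rec(i, j - 1L) + 1L)
    memo[[key]] <- v
    v
  }
  rec(length(av), length(bv))
}

# brute-force semi-global cost: best global edit distance of the read
# against any substring of the reference (free reference flanks)
oracle_semiglobal_cost <- function(read, ref) {
  m <- nchar(ref)
  best <- nchar(read) + m
  for (a in 1:(m + 1L)) {
    for (b in (a - 1L):m) {
      sub <- if (b < a) "" else substr(ref, a, b)
      best <- min(best, as.integer(adist(read, sub)))
    }
  }
  best
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
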