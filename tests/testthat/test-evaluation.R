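test_that("edit distance matches a recursive oracle and is a metric", {
  expect_equal(edit_distance("ACGT", "ACGT"), 0L)
  expect_equal(edit_distance("ACGT", "ACG"), 1L)
  expect_equal(edit_distance("", "ACGT"), 4L)
  set.seed(51)
  strs <- replicate(25, random_dna(sample(0:8, 1)))
  for (i in 1:40) {
    a <- sample(strs, 1); b <- sample(strs, 1); c <- sample(strs, 1)
    expect_equal(edit_distance(a, b), oracle_edit(a, b))
    expect_equal(edit_distance(a, b), edit_distance(b, a))
    expect_equal(edit_distance(a, a), 0L)
    expect_lte(edit_distance(a, c), edit_distance(a, b) + edit_distance(b, c))
  }
})

test_that("NED normalizes the edit distance by the gold length", {
  expect_equal(ned("ACGT", "ACGT"), 0)
  expect_equal(ned("ACG", "ACGT"), 0.25)
  expect_equal(ned("", "ACGT"), 1)
  expect_equal(ned("ACG", "ACGT", normalize = "max"), 0.25)
  expect_error(ned("ACG", ""), class = "segcall_error_invalid")
})

test_that("semi-global alignment counts agree with the brute-force oracle", {
  r <- align_counts("ACGT", "ACGTACGT")
  expect_equal(r[c("M", "U", "I", "D")], list(M = 4L, U = 0L, I = 0L, D = 0L))
  same <- align_counts("ACGT", "ACGT")
  expect_equal(same$M, 4L)
  expect_equal(read_accuracy(same), 1)
  expect_equal(read_identity(same, 4), 1)
  set.seed(52)
  for (i in 1:60) {
    read <- random_dna(sample(1:6, 1), c("A", "C"))
    ref <- random_dna(sample(1:6, 1), c("A", "C"))
    cn <- align_counts(read, ref)
    expect_equal(cn$U + cn$I + cn$D, oracle_semiglobal_cost(read, ref))
    expect_equal(cn$M + cn$U + cn$I, nchar(read))
    expect_equal(cn$ref_end - cn$ref_start, cn$M + cn$U + cn$D)
  }
})

test_that("alignment cost matches Biostrings' semi-global optimum", {
  set.seed(53)
  for (i in 1:20) {
    read <- random_dna(sample(4:12, 1))
    ref <- random_dna(sample(4:16, 1))
    cn <- align_counts(read, ref)
    aln <- Biostrings::pairwiseAlignment(
      read, ref, type = "global-local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(0, -1),
      gapOpening = 0, gapExtension = 1)
    expect_equal(cn$U + cn$I + cn$D, -as.integer(Biostrings::score(aln)))
  }
})

test_that("read accuracy and identity follow the count formulas", {
  cn <- list(M = 90L, U = 4L, I = 3L, D = 3L)
  expect_equal(read_accuracy(cn), 0.90)
  expect_equal(read_identity(cn, 100), 0.90)
  scaled <- lapply(cn, `*`, 7L)
  expect_equal(read_accuracy(scaled), read_accuracy(cn))
  expect_error(read_accuracy(list(M = 0, U = 0, I = 0, D = 0)),
               class = "segcall_error_invalid")
})

test_that("assembly summaries average accuracy and relative length", {
  s <- assembly_summary(c(1, 0), c(10, 10), c(10, 10))
  expect_equal(s$AI, 0.5)
  expect_equal(s$RL, 1)
  expect_equal(assembly_summary(c(0.97, 0.99, 0.98), c(1, 1, 1), c(1, 1, 1))$AI, 0.98)
  # short aligned span zeroes the contig's accuracy
  z <- assembly_summary(c(0.9, 0.9), c(100, 100), c(100, 100),
                        aligned_spans = c(100, 30), component_lengths = c(100, 100))
  expect_equal(z$AI, 0.45)
  expect_error(assembly_summary(numeric(0), numeric(0), numeric(0)),
               class = "segcall_error_invalid")
})

test_that("homopolymer histograms count maximal runs including singletons", {
  h <- homopolymer_histogram("AAACCT")
  expect_equal(h, tibble::tibble(base = c("A", "C", "T"),
                                 length = c(3L, 2L, 1L),
                                 count = c(1L, 1L, 1L)))
  expect_equal(nrow(homopolymer_histogram("")), 0L)
  set.seed(54)
  for (i in 1:20) {
    x <- random_dna(sample(1:200, 1))
    h <- homopolymer_histogram(x)
    expect_equal(sum(h$length * h$count), nchar(x))
  }
})

test_that("per-read evaluation flags unalignable calls and aggregates the rest", {
  rep <- evaluate_reads(c("ACGTACGTAC", "TTTTTTTTTT"),
                        c("ACGTACGTAC", "ACGCAGCAGC"))
  expect_equal(rep$per_read$ned[1], 0)
  expect_equal(rep$per_read$read_accuracy[1], 1)
  expect_false(rep$per_read$aligned[2])
  expect_equal(rep$n_unaligned, 1L)
  expect_equal(rep$summary$mean[rep$summary$metric == "ned"], 0)
  expect_equal(nrow(tidy(rep)), 2L)
  expect_equal(glance(rep)$n_unaligned, 1L)
})

test_that("the duration-ambiguity floor responds to dwell dispersion", {
  f_geom <- dwell_ambiguity_floor(dwell_params(9, "geometric"))
  f_nb <- dwell_ambiguity_floor(dwell_params(9, "nbinom", nb_size = 50))
  f_fix <- dwell_ambiguity_floor(dwell_params(9, "fixed"))
  expect_equal(f_fix, 0)
  expect_lt(f_nb, f_geom)
  expect_gt(f_geom, 0.1)
})
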