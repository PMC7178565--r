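test_that("alias encoding alternates phases within homopolymer runs", {
  expect_equal(alias_encode("AAAAA"), c("A1", "A2", "A1", "A2", "A1"))
  expect_equal(alias_encode("ACGT"), c("A1", "C1", "G1", "T1"))
  expect_equal(alias_encode("AACCCA"), c("A1", "A2", "C1", "C2", "C1", "A1"))
  expect_equal(alias_encode(""), character(0))
  expect_error(alias_encode("ACGN"), class = "segcall_error_alphabet")
})

test_that("alias decoding drops phases and inverts encoding", {
  expect_equal(alias_decode(c("A1", "A2", "A1", "A2", "A1")), "AAAAA")
  expect_equal(alias_decode(character(0)), "")
  set.seed(11)
  for (i in 1:50) {
    x <- random_dna(sample(1:80, 1))
    expect_equal(alias_decode(alias_encode(x)), x)
  }
})

test_that("collapse merges label runs into segments covering the mask", {
  r <- collapse_mask(c("A1", "A1", "A2", "A2", "A2", "C1"))
  expect_equal(r$labels, c("A1", "A2", "C1"))
  expect_equal(r$sequence, "AAC")
  expect_equal(r$segments$start, c(0L, 2L, 5L))
  expect_equal(r$segments$end, c(2L, 5L, 6L))
  expect_equal(r$segments$base, c("A", "A", "C"))

  one <- collapse_mask(rep("T1", 300))
  expect_equal(one$labels, "T1")
  expect_equal(one$segments, tibble::tibble(start = 0L, end = 300L, base = "T"))

  empty <- collapse_mask(character(0))
  expect_equal(empty$sequence, "")
  expect_equal(nrow(empty$segments), 0L)
})

test_that("collapse output has no adjacent duplicates and conserves length", {
  set.seed(21)
  for (i in 1:30) {
    mask <- int_to_alias(sample(1:8, sample(1:200, 1), replace = TRUE))
    r <- collapse_mask(mask)
    expect_true(all(r$labels[-1] != r$labels[-length(r$labels)]) ||
                  length(r$labels) <= 1)
    expect_equal(sum(r$segments$end - r$segments$start), length(mask))
    expect_equal(r$segments$start[-1], r$segments$end[-nrow(r$segments)])
  }
})

test_that("expand repeats labels by dwell and round-trips through collapse", {
  expect_equal(expand_labels(c("A1", "A2"), c(2, 3)),
               c("A1", "A1", "A2", "A2", "A2"))
  expect_error(expand_labels(c("A1", "A2"), c(2)), class = "segcall_error_invalid")
  expect_error(expand_labels(c("A1", "A2"), c(2, 0)), class = "segcall_error_invalid")

  # adjacent identical labels merge: the failure mode aliasing prevents
  merged <- collapse_mask(expand_labels(c("A1", "A1"), c(2, 2)))
  expect_equal(merged$labels, "A1")
  expect_equal(merged$sequence, "A")

  set.seed(31)
  for (i in 1:50) {
    x <- random_dna(sample(1:60, 1))
    labs <- alias_encode(x)
    dw <- sample(1:6, length(labs), replace = TRUE)
    r <- collapse_mask(expand_labels(labs, dw))
    expect_equal(r$labels, labs)
    expect_equal(alias_decode(r$labels), x)
    expect_equal(r$segments$end - r$segments$start, dw)
  }
})

test_that("one-hot encoding uses the fixed label order and inverts by argmax", {
  m <- one_hot("A1")
  expect_equal(as.numeric(m), c(1, rep(0, 7)))
  mask <- c("T2", "A1", "G2", "C1")
  oh <- one_hot(mask)
  expect_equal(rowSums(oh), rep(1, 4))
  expect_equal(int_to_alias(max.col(oh)), mask)
  expect_equal(alias_to_int(alias_alphabet()), 1:8)
})
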