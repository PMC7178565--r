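test_that("simulate_sequence respects composition and determinism", {
  expect_true(simulate_sequence(1, gc_fraction = 0, seed = 5) %in% c("A", "T"))
  expect_error(simulate_sequence(0), class = "segcall_error_invalid")

  s <- simulate_sequence(10000, gc_fraction = 0.5, seed = 42)
  gc <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 10000))

  expect_identical(simulate_sequence(500, 0.4, seed = 7),
                   simulate_sequence(500, 0.4, seed = 7))
})

test_that("zero-noise deterministic-dwell read reproduces the pore levels", {
  pore <- pore_model(k = 1, noise_sd = 1e-9)
  dw <- dwell_params(5, "fixed", drift_amplitude = 0)
  rd <- simulate_read("A", pore = pore, dwell = dw, seed = 1)
  expect_equal(rd$signal, rep(-1, 5), tolerance = 1e-6)
  expect_equal(rd$segments, tibble::tibble(start = 0L, end = 5L, base = "A"))
  expect_equal(int_to_alias(rd$mask), rep("A1", 5))
  expect_error(simulate_read(""), class = "segcall_error_invalid")
})

test_that("simulated reads satisfy the structural invariants", {
  set.seed(9)
  for (i in 1:10) {
    sq <- simulate_sequence(sample(20:120, 1))
    rd <- simulate_read(sq, seed = i)
    expect_equal(length(rd$signal), sum(rd$dwells))
    expect_equal(length(rd$signal), length(rd$mask))
    expect_equal(rd$segments$start, c(0L, head(rd$segments$end, -1)))
    expect_equal(rd$segments$end[nrow(rd$segments)], length(rd$signal))
    # collapsing the gold mask and decoding recovers the sequence exactly
    expect_equal(collapse_mask(rd$mask)$sequence, sq)
  }
})

test_that("homopolymer masks alternate phases at segment granularity", {
  rd <- simulate_read("AAAAA", dwell = dwell_params(4, "fixed", drift_amplitude = 0),
                      seed = 2)
  expect_equal(collapse_mask(rd$mask)$labels, c("A1", "A2", "A1", "A2", "A1"))
})

test_that("near-zero noise lets a nearest-level classifier label every sample", {
  pore <- pore_model(k = 1, noise_sd = 1e-4)
  rd <- simulate_read(simulate_sequence(200, seed = 3), pore = pore, seed = 4)
  levels <- pore$levels
  called <- names(levels)[apply(abs(outer(rd$signal, levels, "-")), 1, which.min)]
  gold <- substr(int_to_alias(rd$mask), 1, 1)
  expect_equal(called, gold)
})

test_that("identical seeds give bit-identical reads and datasets", {
  a <- simulate_read_set(3, 80, seed = 12)
  b <- simulate_read_set(3, 80, seed = 12)
  expect_identical(a, b)
  da <- make_dataset(3, 150, window_length = 100, seed = 5)
  db <- make_dataset(3, 150, window_length = 100, seed = 5)
  expect_identical(da, db)
})

test_that("make_dataset windows align signal and mask and drop remainders", {
  ds <- make_dataset(4, 150, window_length = 100, seed = 8, keep_reads = TRUE)
  expect_equal(nrow(ds$signal), 100L)
  expect_equal(dim(ds$signal), dim(ds$labels))
  expected <- sum(vapply(ds$reads, function(r) length(r$signal) %/% 100L, integer(1)))
  expect_equal(ncol(ds$signal), expected)   # no window near the outlier filter here
  expect_true(all(ds$labels %in% 1:8))
})

test_that("raw-ify plus normalization round-trips to stable units", {
  rd <- simulate_read(simulate_sequence(120, seed = 6), seed = 7)
  raw <- raw_ify(rd$signal, scale = 14, shift = 80)
  nm <- normalize_signal(raw)
  expect_equal(nm$shift, median(raw))
  # affine transform cancels: normalized raw equals normalized original
  expect_equal(nm$samples, normalize_signal(rd$signal)$samples, tolerance = 1e-12)
})

test_that("wider pore contexts produce context-dependent levels", {
  p3 <- pore_model(k = 3, noise_sd = 0.2)
  expect_equal(length(p3$levels), 64L)
  expect_true(all(p3$levels >= -1 & p3$levels <= 1))
  # centre base dominates the level
  expect_gt(p3$levels[["ATA"]], p3$levels[["AAA"]])
  rd <- simulate_read(simulate_sequence(50, seed = 15), pore = p3, seed = 16)
  expect_equal(collapse_mask(rd$mask)$sequence, rd$sequence)
  expect_error(pore_model(k = 1, levels = c(A = 1, C = 0, G = 0)),
               class = "segcall_error_invalid")
  expect_error(pore_model(noise_sd = 0), class = "segcall_error_invalid")
})
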