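test_that("median/MAD normalization matches the hand-worked example", {
  r <- normalize_signal(c(1, 2, 3, 4, 100))
  expect_equal(r$shift, 3)
  expect_equal(r$scale, 1)   # median(|x - 3|) = median(2,1,0,1,97)
  expect_equal(r$samples, c(-2, -1, 0, 1, 97))
  # cross-check the shift/scale against independent median routines
  expect_equal(r$scale, median(abs(c(1, 2, 3, 4, 100) - median(c(1, 2, 3, 4, 100)))))
})

test_that("normalization is identity for centered unit-MAD input", {
  x <- c(-2, -1, 0, 1, 2)
  r <- normalize_signal(x)
  expect_equal(r$samples, x)
  expect_equal(normalize_signal(r$samples)$samples, r$samples)
})

test_that("constant signals raise a degenerate-signal error", {
  expect_error(normalize_signal(c(5, 5, 5, 5)), class = "segcall_error_degenerate")
  expect_error(normalize_signal(numeric(0)), class = "segcall_error_invalid")
})

test_that("training windows are non-overlapping with the remainder dropped", {
  sig <- rnorm(830)
  mask <- sample(1:8, 830, replace = TRUE)
  w <- window_train(sig, mask, 300)
  expect_equal(ncol(w$signal), 2L)
  expect_equal(w$offsets, c(0L, 300L))
  # concatenated windows equal the first floor(N/L)*L samples
  expect_equal(as.numeric(w$signal), sig[1:600])
  expect_equal(as.integer(w$labels), mask[1:600])

  w1 <- window_train(rnorm(300), sample(1:8, 300, TRUE), 300)
  expect_equal(ncol(w1$signal), 1L)
  expect_error(window_train(rnorm(10), sample(1:8, 9, TRUE), 5),
               class = "segcall_error_invalid")
})

test_that("the outlier filter removes windows with values above 10", {
  sig <- rep(0, 600); mask <- rep(1L, 600)
  sig[450] <- 12
  w <- window_train(sig, mask, 300)
  expect_equal(w$offsets, 0L)
  sig[450] <- 9.9
  expect_equal(window_train(sig, mask, 300)$offsets, c(0L, 300L))
  # signed rule: a large negative value passes unless filter_abs is set
  sig[450] <- -50
  expect_equal(window_train(sig, mask, 300)$offsets, c(0L, 300L))
  expect_equal(window_train(sig, mask, 300, filter_abs = TRUE)$offsets, 0L)
})

test_that("inference offsets step by s with an anchored tail window", {
  expect_equal(window_infer(1000, 300, 290), c(0L, 290L, 580L, 700L))
  expect_equal(window_infer(300, 300, 290), 0L)
  expect_equal(window_infer(590, 300, 290), c(0L, 290L))
  expect_error(window_infer(200, 300, 290), class = "segcall_error_short_read")
  expect_error(window_infer(500, 300, 0), class = "segcall_error_invalid")
})

test_that("inference windows cover every sample of the read", {
  set.seed(14)
  for (i in 1:40) {
    L <- sample(50:200, 1)
    n <- L + sample(0:700, 1)
    s <- sample(1:L, 1)
    offs <- window_infer(n, L, s)
    covered <- rep(FALSE, n)
    for (o in offs) covered[(o + 1):(o + L)] <- TRUE
    expect_true(all(covered))
    expect_true(all(diff(offs) > 0))
    expect_true(all(offs + L <= n))
    # interior count consistent with the floor((N-L)/s) sliding count
    expect_gte(length(offs), (n - L) %/% s)
    expect_lte(length(offs), (n - L) %/% s + 2L)
  }
})
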