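random_probs <- function(L) {
  p <- matrix(runif(L * 8), L, 8)
  p / rowSums(p)
}

test_that("a single covering window merges to its own argmax", {
  set.seed(41)
  p <- random_probs(50)
  tr <- soft_merge(list(list(offset = 0L, probs = p)), 50)
  expect_equal(tr$labels, max.col(p, ties.method = "first"))
  expect_equal(tr$probs, p)
})

test_that("windows agreeing on the overlap merge to the common argmax", {
  set.seed(42)
  p <- random_probs(40)
  w1 <- list(offset = 0L, probs = p[1:30, ])
  w2 <- list(offset = 10L, probs = p[11:40, ])
  tr <- soft_merge(list(w1, w2), 40)
  expect_equal(tr$probs, p, tolerance = 1e-12)
})

test_that("the two-window cross-fade matches the hand-worked example", {
  L <- 4L; V <- 2L; N <- 6L
  flat <- rep(1 / 8, 8)
  early <- matrix(flat, L, 8, byrow = TRUE)
  late <- matrix(flat, L, 8, byrow = TRUE)
  # overlap covers absolute positions 2,3 i.e. v = 0,1
  early[4, ] <- c(0.9, rep(0.1 / 7, 7))            # v = 1, favours A1
  late[2, ] <- c(rep(0.4 / 7, 2), 0.6, rep(0.4 / 7, 5))  # v = 1, favours C1
  tr <- soft_merge(list(list(offset = 0L, probs = early),
                        list(offset = 2L, probs = late)), N)
  # weights at v=1: earlier (V-v)/V = 1/2, later v/V = 1/2
  expected <- 0.5 * early[4, ] + 0.5 * late[2, ]
  expect_equal(tr$probs[4, ], expected, tolerance = 1e-12)
  expect_equal(tr$probs[4, 1], 0.5 * 0.9 + 0.5 * 0.4 / 7)
  expect_equal(tr$labels[4], 1L)                   # A1 wins the merged argmax
  # v = 0: earlier weight 1, later weight 0
  expect_equal(tr$probs[3, ], early[3, ], tolerance = 1e-12)
})

test_that("merging is invariant to the order windows are presented", {
  set.seed(43)
  wins <- list(
    list(offset = 0L, probs = random_probs(30)),
    list(offset = 25L, probs = random_probs(30)),
    list(offset = 50L, probs = random_probs(30)),
    list(offset = 55L, probs = random_probs(30))  # anchored-tail style overlap
  )
  a <- soft_merge(wins, 85)
  for (i in 1:5) {
    b <- soft_merge(sample(wins), 85)
    expect_equal(b$probs, a$probs, tolerance = 1e-12)
    expect_identical(b$labels, a$labels)
  }
})

test_that("merged rows are convex combinations of the contributing rows", {
  set.seed(44)
  wins <- list(
    list(offset = 0L, probs = random_probs(30)),
    list(offset = 20L, probs = random_probs(30)),
    list(offset = 30L, probs = random_probs(30))
  )
  tr <- soft_merge(wins, 60)
  expect_equal(rowSums(tr$probs), rep(1, 60), tolerance = 1e-9)
  for (pos in 1:60) {
    rows <- do.call(rbind, lapply(wins, function(w) {
      loc <- pos - w$offset
      if (loc >= 1 && loc <= 30) w$probs[loc, ] else NULL
    }))
    expect_true(all(tr$probs[pos, ] >= apply(rows, 2, min) - 1e-12))
    expect_true(all(tr$probs[pos, ] <= apply(rows, 2, max) + 1e-12))
  }
})

test_that("non-overlapping windows reduce to concatenated argmax calls", {
  set.seed(45)
  p1 <- random_probs(20); p2 <- random_probs(20)
  tr <- soft_merge(list(list(offset = 0L, probs = p1),
                        list(offset = 20L, probs = p2)), 40)
  expect_equal(tr$labels, c(max.col(p1, ties.method = "first"),
                            max.col(p2, ties.method = "first")))
})

test_that("coverage gaps are rejected", {
  set.seed(46)
  expect_error(
    soft_merge(list(list(offset = 0L, probs = random_probs(10)),
                    list(offset = 15L, probs = random_probs(10))), 25),
    class = "segcall_error_coverage")
  expect_error(
    soft_merge(list(list(offset = 0L, probs = random_probs(10))), 12),
    class = "segcall_error_coverage")
})

test_that("argmax ties break toward the lowest label index", {
  p <- matrix(1 / 8, 5, 8)
  tr <- soft_merge(list(list(offset = 0L, probs = p)), 5)
  expect_equal(tr$labels, rep(1L, 5))
})
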