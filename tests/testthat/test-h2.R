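test_that("H2' hits its analytic extremes", {
  expect_equal(h2_selectivity(rbind(c(5, 0), c(0, 5))), 1)
  # outer-product (independence) table: extreme generalization
  expect_equal(h2_selectivity(matrix(1, 2, 2)), 0)
  r <- c(4, 2); cc <- c(3, 3)
  expect_equal(h2_selectivity(outer(r, cc) / 6, integer = FALSE,
                              method = "heuristic"), 0)
  # unit marginals: bounds coincide, degenerate guard returns 0
  expect_equal(h2_selectivity(diag(2)), 0)
})

test_that("entropy bounds match the exhaustive enumeration oracle", {
  b <- h2_bounds(c(5, 5), c(5, 5))
  expect_equal(b$h2_min, log(2))
  o <- h2_bounds_oracle(c(5, 5), c(5, 5))
  expect_equal(b$h2_max, unname(o["max"]))

  set.seed(31)
  for (i in 1:25) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    m <- matrix(0, nr, nc)
    m[sample(length(m), min(8, length(m)))] <- stats::rmultinom(
      1, sample(3:8, 1), rep(1, min(8, length(m))))
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    rt <- rowSums(m); ct <- colSums(m)
    b <- h2_bounds(rt, ct, method = "exhaustive")
    o <- h2_bounds_oracle(rt, ct)
    expect_equal(b$h2_min, unname(o["min"]), tolerance = 1e-12)
    expect_equal(b$h2_max, unname(o["max"]), tolerance = 1e-12)
  }
})

test_that("H2' of a small matrix agrees with exhaustive-search bounds", {
  m <- rbind(c(2, 1), c(1, 0))
  o <- h2_bounds_oracle(rowSums(m), colSums(m))
  expected <- (o["max"] - entropy_oracle(m)) / (o["max"] - o["min"])
  expect_equal(h2_selectivity(m), unname(expected), tolerance = 1e-9)
})

test_that("H2' bounds are ordered and selectivity lies in [0, 1]", {
  set.seed(13)
  for (i in 1:20) {
    m <- matrix(rpois(35, 2), 5, 7)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    b <- h2_bounds(rowSums(m), colSums(m))
    expect_lte(b$h2_min, b$h2_max + 1e-12)
    h <- h2_selectivity(m)
    expect_gte(h, 0); expect_lte(h, 1)
  }
})

test_that("continuous-bound H2' is invariant to scaling all weights", {
  set.seed(17)
  for (i in 1:15) {
    m <- matrix(rpois(12, 3), 3, 4)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    h1 <- h2_selectivity(m, integer = FALSE, method = "heuristic")
    for (k in c(2, 5)) {
      expect_equal(h2_selectivity(k * m, integer = FALSE, method = "heuristic"),
                   h1, tolerance = 1e-12)
    }
  }
})

test_that("mismatched marginal totals are rejected", {
  expect_error(h2_bounds(c(2, 2), c(1, 1)), "equal sums")
  expect_error(h2_selectivity(matrix(0, 2, 2)), "all-zero")
})
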