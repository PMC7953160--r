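test_that("equal counts at equal depth give a zero statistic exactly", {
  st <- gfold_statistic(1000, 1e6, 1000, 1e6, seed = 11)
  expect_identical(st$gfold, 0)
  expect_equal(st$raw_log2fc, 0)
})

test_that("the statistic is conservative and tracks the oracle", {
  ## 8-fold raw change: raw_log2fc close to 3, statistic penalized into [1, 3)
  st <- gfold_statistic(800, 1e6, 100, 1e6, seed = 7)
  expect_equal(st$raw_log2fc, log2(801 / 101), tolerance = 1e-12)
  expect_gte(st$gfold, 1)
  expect_lt(st$gfold, 3)
  expect_equal(st$gfold, gfold_oracle(800, 1e6, 100, 1e6), tolerance = 0.05)

  ## zero count stays finite (flat-prior posterior keeps the rate positive)
  st0 <- gfold_statistic(0, 1e6, 50, 1e6, seed = 7)
  expect_true(is.finite(st0$gfold))
  expect_lt(st0$gfold, 0)
  expect_equal(st0$gfold, gfold_oracle(0, 1e6, 50, 1e6), tolerance = 0.05)
})

test_that("the statistic approaches the raw fold change as counts grow", {
  ## true 4x change; both counts >= 500
  st <- gfold_statistic(2000, 1e6, 500, 1e6, seed = 3)
  expect_lte(abs(st$gfold - st$raw_log2fc), 0.2)
  gaps <- sapply(c(1e4, 1e5, 1e6), function(n) {
    st <- gfold_statistic(4 * n, 1e8, n, 1e8, seed = 3)
    abs(st$gfold - st$raw_log2fc)
  })
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 0.01)
})

test_that("shrinkage: the penalized statistic never exceeds the raw change", {
  grid <- c(0, 1, 5, 20, 100, 500, 2000, 10000)
  for (ca in grid) for (cb in c(0, 10, 1000)) {
    st <- gfold_statistic(ca, 1e6, cb, 1e6, seed = 5)
    expect_lte(abs(st$gfold), abs(st$raw_log2fc) + 0.1,
               label = sprintf("|gfold| at (%d, %d)", ca, cb))
  }
})

test_that("antisymmetry and monotonicity hold within Monte-Carlo tolerance", {
  ab <- gfold_statistic(900, 1e6, 150, 1e6, seed = 13)$gfold
  ba <- gfold_statistic(150, 1e6, 900, 1e6, seed = 13)$gfold
  expect_equal(ab, -ba, tolerance = 0.05)
  g <- sapply(c(50, 100, 200, 400, 800, 1600), function(ca)
    gfold_statistic(ca, 1e6, 200, 1e6, seed = 21)$gfold)
  expect_true(all(diff(g) >= -0.05))
})

test_that("the statistic is deterministic given the seed", {
  a <- gfold_statistic(123, 2e6, 456, 3e6, seed = 42)
  b <- gfold_statistic(123, 2e6, 456, 3e6, seed = 42)
  expect_identical(a, b)
  ## and does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(gfold_statistic(10, 1e6, 20, 1e6, seed = 9))
  expect_identical(runif(1), before)
})

test_that("input validation rejects impossible counts and libraries", {
  expect_error(gfold_statistic(-1, 1e6, 5, 1e6, seed = 1), "non-negative")
  expect_error(gfold_statistic(5, 0, 5, 1e6, seed = 1), "positive")
})

test_that("differential-expression calls use the printed two-fold thresholds", {
  expect_identical(call_de(c(1.2, 1, 0.99, 0, -0.5, -1, -3)),
                   c(1L, 1L, 0L, 0L, 0L, -1L, -1L))
  expect_error(call_de(NaN), "non-finite")
  expect_error(call_de(Inf), "non-finite")
})
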