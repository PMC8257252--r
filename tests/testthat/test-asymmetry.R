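test_that("the asymmetry index follows its defining algebra", {
  expect_equal(asymmetryIndex(5, 5), 0)
  expect_equal(asymmetryIndex(3, 1), -1)   # leftward: negative
  expect_true(is.na(asymmetryIndex(0, 0)))
  expect_error(asymmetryIndex(-1, 2), "non-negative")
  ## antisymmetry and range, property-tested
  set.seed(42)
  L <- rexp(500); R <- rexp(500)
  expect_equal(asymmetryIndex(L, R), -asymmetryIndex(R, L))
  expect_true(all(abs(asymmetryIndex(L, R)) <= 2))
})

test_that("sign-flip p-values match exhaustive enumeration", {
  set.seed(8)
  for (n in c(3, 5, 8)) {
    x <- round(rnorm(n, 0.3, 1), 2)
    vt <- vertexwiseTest(matrix(x, n, 1), nPerm = 2^n, seed = 1)
    expect_equal(vt$p, oracleSignFlipP(x))
  }
})

test_that("degenerate vertex data follow the stated policies", {
  ## all AIs zero: p = 1, d = 0
  vt0 <- vertexwiseTest(matrix(0, 6, 1), nPerm = 100, seed = 1)
  expect_equal(vt0$p, 1)
  expect_equal(vt0$d, 0)
  ## all AIs equal +0.3, n = 10, exhaustive: only the two constant-sign
  ## flips reach |t| = Inf
  vt <- vertexwiseTest(matrix(0.3, 10, 1), nPerm = 1024, seed = 1)
  expect_equal(vt$p, 2 / 1024)
  expect_equal(vt$d, Inf)
  ## Cohen's d for {1, 3} is sqrt(2)
  vt2 <- vertexwiseTest(matrix(c(1, 3), 2, 1), nPerm = 4, seed = 1)
  expect_equal(vt2$d, sqrt(2))
})

test_that("missing AIs are dropped pairwise and excluded from the FDR family", {
  ai <- cbind(c(0.3, 0.4, 0.2, 0.5), c(NA, NA, NA, NA),
              c(0.1, NA, 0.2, 0.3))
  vt <- vertexwiseTest(ai, nPerm = 16, seed = 1)
  expect_true(is.na(vt$p[2]))
  expect_identical(vt$n[c(1, 3)], c(4L, 3L))
  expect_identical(sum(!is.na(vt$q)), 2L)
})

test_that("Monte Carlo permutation p is valid and bounded below", {
  set.seed(5)
  x <- rnorm(15, 1, 0.1)   # strong effect: p should hit the floor
  vt <- vertexwiseTest(matrix(x, 15, 1), nPerm = 999, seed = 3)
  expect_equal(vt$p, 1 / 1000)
  expect_true(vt$p >= 1 / (999 + 1))
})

test_that("signed-rank test matches enumeration and handles edge cases", {
  expect_equal(pairedSignedRank(1:5, c(2, 3, 4, 5, 7))$p, 2 / 32)
  ## identical pairs: all zeros discarded, warning, p = 1
  expect_warning(r0 <- pairedSignedRank(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_equal(r0$p, 1)
  expect_equal(r0$W, 0)
  ## swapping L and R leaves the two-sided p unchanged
  set.seed(10)
  L <- rexp(9); R <- rexp(9)
  expect_equal(pairedSignedRank(L, R)$p, pairedSignedRank(R, L)$p)
})

test_that("exact signed-rank p agrees with wilcox.test on tie-free data", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    L <- rnorm(n); R <- rnorm(n)
    ours <- pairedSignedRank(L, R)
    ref <- suppressWarnings(stats::wilcox.test(R, L, paired = TRUE,
                                               exact = TRUE))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-n signed-rank uses a tie-corrected normal approximation", {
  set.seed(12)
  n <- 30
  L <- rnorm(n); R <- rnorm(n, 0.4)
  ours <- pairedSignedRank(L, R)
  ref <- stats::wilcox.test(R, L, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_identical(ours$method, "normal")
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("multiple-comparison corrections follow their formulas", {
  expect_equal(bonferroniAdjust(0.01, m = 5), 0.05)
  expect_equal(bonferroniAdjust(0.5, m = 44), 1)
  expect_equal(bonferroniAdjust(c(0.2, 0.6), m = 2), c(0.4, 1))
  expect_error(bonferroniAdjust(1.2), "\\[0, 1\\]")
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.3), 0.3)
  expect_equal(bhFdr(rep(0.07, 6)), rep(0.07, 6))
  expect_identical(bhFdr(numeric(0)), numeric(0))
})

test_that("corrections are ordered: raw <= BH <= Bonferroni", {
  set.seed(13)
  p <- runif(40)
  q <- bhFdr(p)
  b <- bonferroniAdjust(p)
  expect_true(all(q >= p))
  expect_true(all(b >= q))
  expect_true(all(q >= p / length(p)))
})

test_that("regional means reduce targets per subject and hemisphere", {
  L <- rbind(c(0.2, 0.4, 1), c(0, 0.5, 1))
  R <- rbind(c(0.4, 0.2, 1), c(1, 0.5, 0))
  rv <- regionValues(L, R, 1:2)
  expect_equal(rv$L, c(0.3, 0.25))
  expect_equal(rv$R, c(0.3, 0.75))
  expect_equal(regionValues(L, R, 2)$L, c(0.4, 0.5))
  expect_error(regionValues(L, R, integer(0)), "empty region")
})
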