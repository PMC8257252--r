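test_that("normalization applies log1p then max-division", {
  m <- matrix(c(0, 9, 99), 1)
  expect_equal(normalizeProfile(m), matrix(c(0, 0.5, 1), 1))
  ## output max is exactly 1 for any non-zero input
  set.seed(1)
  r <- matrix(rexp(60), 6)
  expect_equal(max(normalizeProfile(r)), 1)
})

test_that("normalization handles degenerate and invalid input", {
  z <- matrix(0, 2, 3)
  expect_warning(out <- normalizeProfile(z), "all-zero")
  expect_equal(out, z)
  neg <- matrix(c(1, -2, 3, 4), 2)
  expect_error(normalizeProfile(neg), "row 2, column 1")
})

test_that("normalization is idempotent on profile objects", {
  p <- ConnectivityProfile(matrix(c(0, 9, 99, 3), 2), "s01", "L")
  n1 <- normalizeProfile(p)
  n2 <- normalizeProfile(n1)
  expect_true(n1@normalized)
  expect_identical(profileMatrix(n1), profileMatrix(n2))
})

test_that("smoothing matches the explicit doubly stochastic operator", {
  chain <- list(2L, c(1L, 3L), 2L)
  x <- matrix(c(1, 0, 0), 3, 1)
  ## d_max = 3: W = [[2/3,1/3,0],[1/3,1/3,1/3],[0,1/3,2/3]]
  expect_equal(smoothProfile(x, chain, 1L),
               matrix(c(2 / 3, 1 / 3, 0), 3, 1))
  ## rounds = 0 is the identity; constant input is a fixed point
  expect_identical(smoothProfile(x, chain, 0L), x)
  cst <- matrix(5, 3, 4)
  expect_equal(smoothProfile(cst, chain, 3L), cst)
})

test_that("smoothing preserves column sums under symmetric adjacency", {
  set.seed(7)
  M <- 10
  A <- matrix(rbinom(M * M, 1, 0.3), M, M)
  A <- (A + t(A)) > 0
  diag(A) <- FALSE
  adj <- lapply(seq_len(M), function(i) which(A[i, ]))
  x <- matrix(rexp(M * 5), M)
  sm <- smoothProfile(x, adj, 4L)
  expect_equal(colSums(sm), colSums(x))
  expect_error(smoothProfile(x, lapply(1:10, function(i) 99L), 1L),
               "unknown seed index")
})

test_that("population maps average, threshold strictly, and track support", {
  pm <- populationMap(list(c(0.4, 0.9, 0), c(0.8, 0.1, 0)), threshold = 0.5)
  expect_equal(mapValues(pm), c(0.6, 0, 0))   # 0.5 mean zeroed (strict >)
  expect_identical(mapSupport(pm), 1L)
  ## threshold 0: support is exactly the strictly positive entries
  pm0 <- populationMap(list(c(0, 0.2, 0.7)), threshold = 0)
  expect_identical(mapSupport(pm0), c(2L, 3L))
  expect_equal(mapValues(pm0), c(0, 0.2, 0.7))
  ## saturating threshold empties the map
  pmx <- populationMap(list(c(0.4, 0.9)), threshold = 2)
  expect_identical(mapSupport(pmx), integer(0))
  expect_equal(mapValues(pmx), c(0, 0))
})

test_that("population map commutes with subject reordering and checks shapes", {
  profs <- list(c(0.1, 0.5, 0.9), c(0.4, 0.2, 0.6), c(0.3, 0.3, 0.3))
  a <- populationMap(profs, 0.3)
  b <- populationMap(rev(profs), 0.3)
  expect_equal(mapValues(a), mapValues(b))
  expect_error(populationMap(list(1:3, 1:4), 0.1), "mixed shapes")
  pL <- ConnectivityProfile(matrix(0.5, 1, 2), "s", "L", normalized = TRUE)
  expect_error(populationMap(list(pL), 0.1, hemisphere = "R"),
               "hemisphere")
})

test_that("the group mask is the symmetric union of supports", {
  mk <- function(v, thr) populationMap(list(v), thr)
  a <- mk(c(1, 1, 0, 0), 0.5)
  b <- mk(c(0, 1, 1, 0), 0.5)
  expect_identical(groupMask(a, b), c(1L, 2L, 3L))
  expect_identical(groupMask(a, b), groupMask(b, a))
  empty <- mk(c(0, 0, 0, 0), 0.5)
  expect_identical(groupMask(a, empty), mapSupport(a))
  expect_error(groupMask(a, mk(c(1, 0), 0.5)), "length")
})
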