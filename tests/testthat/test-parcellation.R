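test_that("seed similarity is Pearson correlation with degenerate-row policy", {
  s <- seedSimilarity(rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1)))
  m <- similarityMatrix(s)
  expect_equal(m[1, 2], 1)
  expect_equal(m[1, 3], -1)
  expect_warning(sc <- seedSimilarity(rbind(c(1, 1, 1), c(1, 2, 3),
                                            c(0, 1, 5))),
                 "constant")
  mc <- similarityMatrix(sc)
  expect_equal(mc[1, 2], 0)
  expect_equal(mc[1, 3], 0)
  expect_equal(diag(mc), rep(1, 3))
  expect_error(seedSimilarity(matrix(1, 1, 3)), "at least 2")
})

test_that("group similarity averages element-wise and preserves structure", {
  a <- seedSimilarity(rbind(c(1, 2, 3), c(3, 1, 2)))
  one <- groupSimilarity(list(a))
  expect_equal(similarityMatrix(one), similarityMatrix(a))
  expect_identical(one@level, "group")
  m1 <- new("SimilarityMatrix", mat = rbind(c(1, 0.2), c(0.2, 1)),
            level = "subject")
  m2 <- new("SimilarityMatrix", mat = rbind(c(1, 0.6), c(0.6, 1)),
            level = "subject")
  g <- similarityMatrix(groupSimilarity(list(m1, m2)))
  expect_equal(g[1, 2], 0.4)
  expect_equal(g, t(g))
  expect_equal(diag(g), rep(1, 2))
})

test_that("spectral parcellation recovers well-separated blocks", {
  m <- matrix(-0.2, 10, 10)
  m[1:5, 1:5] <- 1; m[6:10, 6:10] <- 1
  sim <- new("SimilarityMatrix", mat = m, level = "group")
  p <- spectralParcellate(sim, 2, seed = 0)
  expect_identical(parcelLabels(p), rep(c(1L, 2L), each = 5))
  ## stable under a different k-means seed on this well-separated case
  p2 <- spectralParcellate(sim, 2, seed = 12345)
  expect_identical(parcelLabels(p), parcelLabels(p2))
  ## saturation: k = M gives every seed its own cluster
  pM <- spectralParcellate(sim, 10, seed = 0)
  expect_identical(parcelLabels(pM), 1:10)
  expect_error(spectralParcellate(sim, 1, seed = 0), "'k'")
  expect_error(spectralParcellate(sim, 11, seed = 0), "'k'")
})

test_that("parcellation is invariant under common seed permutation", {
  fx <- blockSimilarityFixture(M = 60, k = 3, seed = 4)
  p <- spectralParcellate(fx$sim, 3, seed = 0)
  set.seed(9)
  perm <- sample(60)
  simP <- new("SimilarityMatrix",
              mat = similarityMatrix(fx$sim)[perm, perm], level = "group")
  pP <- spectralParcellate(simP, 3, seed = 0)
  expect_identical(parcelLabels(pP),
                   canonicalRelabel(parcelLabels(p)[perm]))
})

test_that("label matching recovers permutations and maximizes overlap", {
  res <- matchLabels(c(1, 1, 2, 2), c(2, 2, 1, 1))
  expect_identical(res$mapping, c(2L, 1L))
  expect_equal(res$totalOverlap, 1)
  expect_equal(res$dice, c(1, 1))
  a <- c(1, 2, 3, 1, 2, 3)
  expect_identical(matchLabels(a, a)$mapping, 1:3)
  expect_no_error(matchLabels(c(1, 2), c(2, 1)))
  expect_error(matchLabels(c(1, 1, 2), c(1, 2, 3)), "unequal k")
})

test_that("matched overlap equals the brute-force maximum for k <= 5", {
  set.seed(21)
  for (rep in 1:25) {
    k <- sample(2:5, 1)
    n <- sample(8:20, 1)
    a <- canonicalRelabel(c(seq_len(k), sample(k, n - k, replace = TRUE)))
    b <- canonicalRelabel(c(seq_len(k), sample(k, n - k, replace = TRUE)))
    expect_equal(matchLabels(a, b)$totalOverlap, oracleBestOverlap(a, b))
  }
})

test_that("adjusted Rand index matches the contingency-table formula", {
  set.seed(3)
  for (rep in 1:20) {
    a <- sample(3, 15, replace = TRUE)
    b <- sample(4, 15, replace = TRUE)
    expect_equal(adjustedRand(a, b), oracleARI(a, b))
  }
  expect_equal(adjustedRand(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
})

test_that("the k scan scores identical structure at 1 and flags noisy groups", {
  ## identical 4-block similarity in every group: consistency 1 at k = 4
  fx <- blockSimilarityFixture(M = 80, k = 4, noiseSd = 0, seed = 1)
  groups <- list(a = fx$sim, b = fx$sim, c = fx$sim)
  scan <- scanK(groups, kRange = 2:6, tau = 0.8, seed = 0)
  expect_equal(unname(scanScores(scan)[["4"]]), 1)
  ## a pure-noise group depresses the consistency at every k
  noisy <- blockSimilarityFixture(M = 80, k = 4, within = 0.2,
                                  noiseSd = 0.2, seed = 2)$sim
  scanN <- scanK(list(a = fx$sim, b = fx$sim, c = noisy),
                 kRange = 2:6, tau = 0.8, seed = 0)
  expect_true(all(scanScores(scanN) < scanScores(scan) + 1e-12))
  expect_error(scanK(list(), 2:4), "empty")
})

test_that("chosen k follows the max-k-above-tau rule with argmax fallback", {
  fx <- concordantGroupFixture(nGroups = 3, M = 120, seed = 2)
  scan <- scanK(fx$sims, kRange = 2:8, tau = 0.8, seed = 0)
  expect_true(scan@reachedTau)
  expect_identical(chosenK(scan), 4L)
  ## incoherent groups never reach tau: argmax fallback, flagged
  noise <- lapply(1:2, function(g)
    blockSimilarityFixture(M = 60, k = 2, within = 0.2, between = 0.2,
                           noiseSd = 0.15, seed = g)$sim)
  names(noise) <- c("a", "b")
  scanN <- scanK(noise, kRange = 2:6, tau = 0.8, seed = 0)
  expect_false(scanN@reachedTau)
  expect_identical(chosenK(scanN),
                   scanN@kValues[which.max(scanN@scores)])
})
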