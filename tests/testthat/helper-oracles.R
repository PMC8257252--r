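## Independent oracles used to validate the package's statistics.  These
## deliberately use different code paths from the implementation (explicit
## bit loops and textbook formulas rather than vectorized tricks).

## Exhaustive two-sided sign-flip p for a one-sample t test: loop over all
## 2^n sign assignments, computing each t from scratch.
oracleSignFlipP <- function(x) {
  n <- length(x)
  tOf <- function(v) {
    s <- stats::sd(v)
    if (s == 0) {
      if (mean(v) == 0) 0 else Inf * sign(mean(v))
    } else mean(v) / (s / sqrt(n))
  }
  tobs <- abs(tOf(x))
  cnt <- 0L
  for (m in 0:(2^n - 1)) {
    signs <- ifelse(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) > 0, -1, 1)
    if (abs(tOf(x * signs)) >= tobs - 1e-12) cnt <- cnt + 1L
  }
  cnt / 2^n
}

## Exact two-sided signed-rank p by looping over all 2^n sign assignments
## of the ranks (zeros already removed; midranks allowed).
oracleSignedRankP <- function(L, R) {
  d <- (R - L)
  d <- d[d != 0]
  rk <- rank(abs(d))
  n <- length(d)
  W <- sum(rk[d > 0])
  mu <- sum(rk) / 2
  dev <- abs(W - mu)
  cnt <- 0L
  for (m in 0:(2^n - 1)) {
    pos <- bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) > 0
    if (abs(sum(rk[pos]) - mu) >= dev - 1e-9) cnt <- cnt + 1L
  }
  cnt / 2^n
}

## Adjusted Rand index straight from the contingency-table formula.
oracleARI <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(ch2(tab))
  sumA <- sum(ch2(rowSums(tab)))
  sumB <- sum(ch2(colSums(tab)))
  nPairs <- ch2(sum(tab))
  expected <- sumA * sumB / nPairs
  maxIdx <- (sumA + sumB) / 2
  if (maxIdx == expected) return(1)
  (sumIJ - expected) / (maxIdx - expected)
}

## All permutations of 1..k (k <= 6), for brute-force label matching.
allPermutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in allPermutations(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

## Brute-force maximum total overlap over all bijections of labels.
oracleBestOverlap <- function(a, b) {
  k <- max(a)
  best <- -Inf
  for (p in allPermutations(k)) {
    ov <- sum(unlist(p)[a] == b)
    if (ov > best) best <- ov
  }
  best / length(a)
}

## A tiny species spec for fast unit tests.
tinySpec <- function(nSubjects = 4, noiseSd = 0, asymEffects = NULL,
                     volumeAI = c(0, 0), volumeNoiseSd = 0,
                     scalingExponent = c(1.2, 1.2),
                     scalingIntercept = log(c(2, 2)),
                     gmvRange = c(1e3, 1e3)) {
  SpeciesSpec("tiny", nSubjects = nSubjects, nSeeds = 6, nTargets = 8,
              kTrue = 2,
              clusterProfiles = rbind(c(9, 9, 9, 9, 1, 1, 1, 20),
                                      c(1, 1, 1, 1, 9, 9, 9, 20)),
              asymEffects = asymEffects, noiseSd = noiseSd,
              scalingExponent = scalingExponent,
              scalingIntercept = scalingIntercept,
              volumeAI = volumeAI, gmvRange = gmvRange,
              volumeNoiseSd = volumeNoiseSd)
}
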