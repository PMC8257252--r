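#' Hemispheric asymmetry index
#'
#' \code{AI = 2 (R - L) / (R + L)}: negative values indicate leftward
#' asymmetry (left larger), positive values rightward.  The index is
#' antisymmetric in its arguments and confined to [-2, 2]; units with
#' \code{L + R = 0} carry no information and are missing-coded (\code{NA}).
#'
#' @param L,R non-negative left / right measurements (vectorized).
#' @return numeric vector of AIs in [-2, 2], \code{NA} where
#'   \code{L + R = 0}.
#' @examples
#' asymmetryIndex(3, 1)   # -1: leftward
#' asymmetryIndex(5, 5)   # 0
#' @export
asymmetryIndex <- function(L, R) {
  if (any(L < 0, na.rm = TRUE) || any(R < 0, na.rm = TRUE))
    stop("asymmetry index requires non-negative inputs")
  s <- L + R
  out <- ifelse(s == 0, NA_real_, 2 * (R - L) / s)
  as.numeric(out)
}

## All 2^n sign vectors as a (2^n x n) +/-1 matrix (exhaustive flips).
allSignFlips <- function(n) {
  stopifnot(n <= 20L)
  g <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  dimnames(g) <- NULL
  g
}

## Sign-flip t statistics for flip matrix S (B x n) and data matrix X
## (n x V).  Uses the identity that sum(x^2) is flip-invariant, so only the
## flipped sums are needed.  Near-zero variances are clamped to 0 so that
## all-equal data yield |t| = Inf consistently across flips.
signFlipT <- function(S, X) {
  n <- nrow(X)
  sums <- S %*% X                       # B x V
  ssq <- colSums(X^2)                   # V
  m <- sums / n
  v <- (rep(ssq, each = nrow(S)) - n * m^2) / (n - 1)
  tol <- 1e-12 * max(1, max(ssq) / n)
  v[v < tol] <- 0
  t <- m / sqrt(v / n)
  t[m == 0 & v == 0] <- 0
  t
}

#' Vertex-wise sign-flip permutation tests of asymmetry
#'
#' One-sample t tests of per-subject asymmetry indices against zero at every
#' unit (vertex) of an analysis mask, with two-sided p-values from the
#' sign-flip null: all \code{2^n} flips are enumerated when
#' \code{2^n <= nPerm}; otherwise \code{nPerm} Monte Carlo flips are drawn,
#' the identity flip is always counted, and
#' \code{p = (1 + #(|t*| >= |t|)) / (1 + nPerm)} (so \code{p >= 1/(nPerm+1)}
#' and the estimator is valid).  Benjamini-Hochberg q-values are computed
#' across the mask (all-missing units are excluded from the family), and
#' Cohen's d (\code{mean / sample sd}) is reported per unit.
#'
#' @param ai subjects x units matrix of asymmetry indices (\code{NA}
#'   allowed; missing values are dropped per unit).
#' @param mask integer indices of the units to test (default: all).
#' @param nPerm number of permutations (default 5000).
#' @param seed RNG seed for Monte Carlo flips.
#' @param alpha significance level for the \code{significant} flag
#'   (q < alpha).
#' @return data.frame with one row per masked unit: \code{unit}, \code{n},
#'   \code{ai_mean}, \code{statistic} (t), \code{p}, \code{q}, \code{d},
#'   \code{significant}.
#' @export
vertexwiseTest <- function(ai, mask = seq_len(ncol(ai)), nPerm = 5000L,
                           seed = 0L, alpha = 0.05) {
  ai <- as.matrix(ai)
  nPerm <- as.integer(nPerm)
  stopifnot(nrow(ai) >= 2L, nPerm >= 1L)
  if (any(mask < 1L) || any(mask > ncol(ai)))
    stop("mask indices outside the unit range")
  res <- data.frame(unit = mask, n = NA_integer_, ai_mean = NA_real_,
                    statistic = NA_real_, p = NA_real_, q = NA_real_,
                    d = NA_real_)
  ## group masked units by missingness pattern so each group is vectorized
  patterns <- apply(!is.na(ai[, mask, drop = FALSE]), 2,
                    function(ok) paste(as.integer(ok), collapse = ""))
  for (pat in unique(patterns)) {
    cols <- mask[patterns == pat]
    keep <- strsplit(pat, "")[[1]] == "1"
    n <- sum(keep)
    rows <- match(cols, mask)
    if (n < 2L) next                      # all-missing or single obs
    X <- ai[keep, cols, drop = FALSE]
    m <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    tobs <- ifelse(sdv == 0, ifelse(m == 0, 0, Inf * sign(m)),
                   m / (sdv / sqrt(n)))
    if (2^n <= nPerm) {
      S <- allSignFlips(n)
      T <- signFlipT(S, X)
      p <- colMeans(abs(T) >= rep(abs(tobs), each = nrow(S)) - 1e-12)
    } else {
      S <- withSeed(seed, matrix(sample(c(1, -1), nPerm * n, replace = TRUE),
                                 nPerm, n))
      T <- signFlipT(S, X)
      cnt <- colSums(abs(T) >= rep(abs(tobs), each = nPerm) - 1e-12)
      p <- (1 + cnt) / (1 + nPerm)
    }
    p[sdv == 0 & m == 0] <- 1
    res$n[rows] <- n
    res$ai_mean[rows] <- m
    res$statistic[rows] <- tobs
    res$p[rows] <- p
    res$d[rows] <- ifelse(sdv == 0, ifelse(m == 0, 0, Inf * sign(m)),
                          m / sdv)
  }
  ok <- !is.na(res$p)
  res$q[ok] <- bhFdr(res$p[ok])
  res$significant <- !is.na(res$q) & res$q < alpha
  res
}

#' Per-subject regional connectivity means
#'
#' Averages connectivity over a region's target indices, separately per
#' hemisphere and subject — the ROI-wise / tract-wise reduction feeding the
#' signed-rank tests.
#'
#' @param valsL,valsR subjects x targets matrices of left / right
#'   connectivity (e.g. per-subject cluster fingerprints).
#' @param region non-empty integer index set over targets.
#' @return data.frame with per-subject columns \code{L} and \code{R}.
#' @export
regionValues <- function(valsL, valsR, region) {
  region <- as.integer(region)
  if (!length(region)) stop("empty region")
  if (any(region < 1L) || any(region > ncol(valsL)))
    stop("region indices outside the target range")
  stopifnot(identical(dim(valsL), dim(valsR)))
  data.frame(
    L = rowMeans(valsL[, region, drop = FALSE]),
    R = rowMeans(valsR[, region, drop = FALSE]))
}

#' Paired Wilcoxon signed-rank test (exact for small n)
#'
#' Two-sided signed-rank test of \code{R - L} differences.  Zero
#' differences are discarded by default (classical handling; their count is
#' reported) or down-weighted via the Pratt method.  The null distribution
#' is enumerated exactly over all \code{2^n} sign assignments of the ranks
#' when the remaining \code{n <= exactLimit} (ties in ranks are handled by
#' the enumeration); otherwise a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param L,R equal-length (>= 2) numeric vectors of paired left / right
#'   values.
#' @param zeroPolicy \code{"discard"} (classical) or \code{"pratt"}.
#' @param exactLimit largest n for exact enumeration (default 12).
#' @return list with \code{W} (sum of positive-difference ranks), \code{p}
#'   (two-sided), \code{nUsed}, \code{nZero}, \code{method}.
#' @examples
#' pairedSignedRank(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 7))$p  # 2/32
#' @export
pairedSignedRank <- function(L, R, zeroPolicy = c("discard", "pratt"),
                             exactLimit = 12L) {
  zeroPolicy <- match.arg(zeroPolicy)
  stopifnot(length(L) == length(R), length(L) >= 2L)
  d <- R - L
  zero <- d == 0
  nZero <- sum(zero)
  if (all(zero)) {
    warning("all paired differences are zero; p = 1")
    return(list(W = 0, p = 1, nUsed = 0L, nZero = nZero,
                method = "degenerate"))
  }
  if (zeroPolicy == "discard") {
    d <- d[!zero]
    rk <- rank(abs(d))
  } else {
    rkAll <- rank(abs(d))                 # zeros share the lowest ranks
    rk <- rkAll[!zero]
    d <- d[!zero]
  }
  n <- length(d)
  W <- sum(rk[d > 0])
  mu <- sum(rk) / 2
  if (n <= exactLimit) {
    dev <- abs(W - mu)
    devs <- enumerateRankSums(rk) - mu
    p <- mean(abs(devs) >= dev - 1e-9)
    method <- "exact"
  } else {
    sigma2 <- sum(rk^2) / 4
    if (sigma2 == 0) return(list(W = W, p = 1, nUsed = n, nZero = nZero,
                                 method = "degenerate"))
    z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)
    if (W == mu) z <- 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(W = W, p = p, nUsed = n, nZero = nZero, method = method)
}

## All 2^n sums of rank subsets: the exact signed-rank null support.
enumerateRankSums <- function(rk) {
  n <- length(rk)
  stopifnot(n <= 20L)
  sums <- 0
  for (r in rk) sums <- c(sums, sums + r)   # incremental subset sums
  sums
}

#' Bonferroni adjustment with explicit family size
#'
#' \code{p_adj = min(1, p * m)}; the family size \code{m} may exceed the
#' number of p-values supplied (e.g. subregions x regions x species).
#'
#' @param p p-values in [0, 1].
#' @param m family size (defaults to \code{length(p)}).
#' @return adjusted p-values.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("'m' must be at least length(p)")
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate q-values, monotone in the p-value ordering
#' and capped at 1.
#'
#' @param p p-values in [0, 1].
#' @return q-values (empty input gives an empty vector).
#' @export
bhFdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' One-sample Cohen's d
#'
#' \code{mean(x) / sd(x)} with the sample (n - 1) standard deviation.
#'
#' @param x numeric vector (\code{NA} dropped).
#' @return standardized effect size.
#' @export
cohensD <- function(x) {
  x <- x[!is.na(x)]
  s <- stats::sd(x)
  m <- mean(x)
  if (s == 0) return(if (m == 0) 0 else Inf * sign(m))
  m / s
}
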