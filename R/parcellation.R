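#' Seed-by-seed similarity of connectivity profiles
#'
#' Pearson cross-correlation between every pair of seed rows of a
#' (normalized) connectivity matrix — the similarity structure that drives
#' the parcellation.  Constant rows carry no profile information: they get
#' correlation 0 to every other seed and 1 to themselves, with a warning.
#'
#' @param x seeds x targets matrix or \linkS4class{ConnectivityProfile}
#'   with at least 2 seed rows.
#' @param ... unused.
#' @return a subject-level \linkS4class{SimilarityMatrix}.
#' @examples
#' seedSimilarity(rbind(c(1, 2, 3), c(3, 2, 1)))
#' @rdname seedSimilarity
#' @export
setMethod("seedSimilarity", "matrix", function(x, ...) {
  M <- nrow(x)
  if (M < 2L) stop("at least 2 seed rows are required")
  sds <- apply(x, 1, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    warning(sum(flat), " constant seed row(s): correlation set to 0")
    r <- matrix(0, M, M)
    if (sum(!flat) >= 2L)
      r[!flat, !flat] <- stats::cor(t(x[!flat, , drop = FALSE]))
    else if (sum(!flat) == 1L) r[!flat, !flat] <- 1
  } else {
    r <- stats::cor(t(x))
  }
  diag(r) <- 1
  r <- (r + t(r)) / 2
  new("SimilarityMatrix", mat = r, level = "subject")
})

#' @rdname seedSimilarity
#' @export
setMethod("seedSimilarity", "ConnectivityProfile",
          function(x, ...) seedSimilarity(x@mat))

#' Group-average similarity matrix
#'
#' Element-wise mean of subject-level similarity matrices; averaging
#' preserves symmetry, the unit diagonal and the [-1, 1] range.
#'
#' @param mats non-empty list of \linkS4class{SimilarityMatrix} of equal
#'   dimension.
#' @return a group-level \linkS4class{SimilarityMatrix}.
#' @export
groupSimilarity <- function(mats) {
  if (!length(mats)) stop("at least one similarity matrix is required")
  ms <- lapply(mats, function(m) {
    stopifnot(is(m, "SimilarityMatrix"))
    m@mat
  })
  d <- unique(vapply(ms, nrow, integer(1)))
  if (length(d) != 1L) stop("similarity matrices have mismatched shapes")
  avg <- Reduce(`+`, ms) / length(ms)
  new("SimilarityMatrix", mat = avg, level = "group")
}

#' Spectral parcellation of the seed region
#'
#' Normalized-Laplacian spectral clustering of a group similarity matrix.
#' Correlations are mapped to non-negative affinities (default the monotone
#' shift \code{(r + 1) / 2}; alternatively clipping negatives at 0), the
#' k leading eigenvectors of the symmetrically normalized affinity are
#' row-normalized, and k-means (fixed seed, \code{nstart} restarts) labels
#' the seeds.  Labels are canonically relabelled: cluster 1 contains the
#' lowest seed index, labels ascend by first occurrence, making output
#' deterministic and diffable.
#'
#' @param sim group-level \linkS4class{SimilarityMatrix}.
#' @param k number of clusters, \code{2 <= k <= M}.
#' @param seed RNG seed for k-means.
#' @param affinity \code{"shift"} ((r+1)/2) or \code{"clip"} (max(r, 0)).
#' @param nstart k-means restarts (at least 10 are used).
#' @param profile optional normalized connectivity matrix (or
#'   \linkS4class{ConnectivityProfile}) used to compute per-cluster mean
#'   fingerprints.
#' @return a \linkS4class{Parcellation}.
#' @export
spectralParcellate <- function(sim, k, seed = 0L,
                               affinity = c("shift", "clip"),
                               nstart = 10L, profile = NULL) {
  stopifnot(is(sim, "SimilarityMatrix"))
  if (sim@level != "group")
    stop("spectral parcellation expects a group-level similarity matrix")
  affinity <- match.arg(affinity)
  r <- sim@mat
  M <- nrow(r)
  k <- as.integer(k)
  if (k < 2L || k > M) stop("'k' must lie in [2, ", M, "]")
  if (!all(is.finite(r))) stop("similarity matrix has non-finite entries")
  if (k == M) {
    labels <- seq_len(M)
  } else {
    A <- if (affinity == "shift") (r + 1) / 2 else pmax(r, 0)
    d <- rowSums(A)
    d[d == 0] <- 1
    S <- A / sqrt(d) / rep(sqrt(d), each = M)
    S <- (S + t(S)) / 2
    ev <- eigen(S, symmetric = TRUE)
    emb <- ev$vectors[, seq_len(k), drop = FALSE]
    len <- sqrt(rowSums(emb^2))
    len[len == 0] <- 1
    emb <- emb / len
    km <- withSeed(seed,
      stats::kmeans(emb, centers = k, nstart = max(10L, as.integer(nstart)),
                    iter.max = 100L))
    labels <- km$cluster
  }
  labels <- canonicalRelabel(labels)
  fp <- matrix(numeric(0), 0, 0)
  if (!is.null(profile)) {
    pm <- if (is(profile, "ConnectivityProfile")) profile@mat else profile
    fp <- clusterFingerprints(pm, labels, k)
  }
  new("Parcellation", labels = as.integer(labels), k = k,
      fingerprints = fp,
      provenance = list(k = k, seed = as.integer(seed),
                        affinity = affinity, nstart = max(10L, nstart)))
}

#' Canonical relabelling of cluster labels
#'
#' Relabels so that the cluster containing the lowest index becomes 1 and
#' labels ascend in order of first occurrence.
#'
#' @param labels integer label vector.
#' @return relabelled integer vector.
#' @export
canonicalRelabel <- function(labels) {
  match(labels, unique(labels))
}

#' Per-cluster mean connectivity fingerprints
#'
#' @param mat seeds x targets connectivity matrix.
#' @param labels cluster label per seed.
#' @param k number of clusters.
#' @return k x targets matrix of cluster-mean connectivity.
#' @export
clusterFingerprints <- function(mat, labels, k = max(labels)) {
  stopifnot(nrow(mat) == length(labels))
  out <- matrix(NA_real_, k, ncol(mat))
  for (c in seq_len(k))
    out[c, ] <- colMeans(mat[labels == c, , drop = FALSE])
  out
}

## O(n^3) Hungarian algorithm (shortest augmenting paths with potentials),
## minimizing total cost; deterministic loop order makes ties reproducible
## (lowest label pair wins).  Sized for k <= a few dozen clusters.
hungarianAssign <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)   # columns 0..n at index j+1
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j + 1L] <- minv[j + 1L] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) assign[p[j + 1L]] <- j
  assign
}

#' Optimal one-to-one matching of cluster labels
#'
#' Builds the k x k label co-occurrence (contingency) table of two
#' parcellations over the same seeds and finds the bijective label mapping
#' maximizing total overlap (Hungarian method; ties resolved toward the
#' lowest label pair).  Needed to compare parcellations across hemispheres
#' or groups before scoring their consistency.
#'
#' @param a,b \linkS4class{Parcellation}s with equal k over the same seeds,
#'   or plain integer label vectors.
#' @return list with \code{mapping} (integer vector: label \code{i} of
#'   \code{a} maps to \code{mapping[i]} of \code{b}), \code{dice}
#'   (Dice-style overlap per matched pair), and \code{totalOverlap}
#'   (fraction of seeds agreeing under the mapping).
#' @examples
#' matchLabels(c(1, 1, 2, 2), c(2, 2, 1, 1))
#' @export
matchLabels <- function(a, b) {
  la <- if (is(a, "Parcellation")) a@labels else as.integer(a)
  lb <- if (is(b, "Parcellation")) b@labels else as.integer(b)
  ka <- max(la); kb <- max(lb)
  if (ka != kb) stop("parcellations have unequal k (", ka, " vs ", kb, ")")
  if (length(la) != length(lb)) stop("parcellations cover different seeds")
  k <- ka
  tab <- as.matrix(table(factor(la, seq_len(k)), factor(lb, seq_len(k))))
  cost <- max(tab) - tab
  mapping <- hungarianAssign(cost)
  matched <- tab[cbind(seq_len(k), mapping)]
  sizesA <- tabulate(la, k)
  sizesB <- tabulate(lb, k)
  dice <- 2 * matched / (sizesA + sizesB[mapping])
  list(mapping = mapping, dice = dice,
       totalOverlap = sum(matched) / length(la))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected partition agreement (1 = identical up to relabelling);
#' thin wrapper around \code{mclust::adjustedRandIndex}.
#'
#' @param a,b label vectors or \linkS4class{Parcellation}s.
#' @return the ARI (can be negative for worse-than-chance agreement).
#' @export
adjustedRand <- function(a, b) {
  la <- if (is(a, "Parcellation")) a@labels else a
  lb <- if (is(b, "Parcellation")) b@labels else b
  mclust::adjustedRandIndex(la, lb)
}

#' Scan cluster numbers and select k by cross-group consistency
#'
#' For each k in \code{kRange}, parcellate every group's similarity matrix
#' and score the consistency of the resulting partitions as the mean
#' pairwise adjusted Rand index after optimal label matching (negative
#' means are clamped to 0).  The chosen k is the maximum k whose score
#' reaches \code{tau}; when no k does, the argmax-score k is returned and
#' flagged.  This operationalizes selecting the largest cluster number
#' with a topological organization coherent across groups.
#'
#' @param groupSims named list (>= 2) of group-level
#'   \linkS4class{SimilarityMatrix} with index-corresponded seeds.
#' @param kRange integer vector of candidate k (default 2:12).
#' @param tau consistency threshold in [0, 1] (default 0.8).
#' @param seed k-means seed, shared across groups and k.
#' @param affinity passed to [spectralParcellate()].
#' @return a \linkS4class{KScanResult}.
#' @export
scanK <- function(groupSims, kRange = 2:12, tau = 0.8, seed = 0L,
                  affinity = c("shift", "clip")) {
  affinity <- match.arg(affinity)
  if (!length(groupSims)) stop("empty group map")
  if (length(groupSims) < 2L)
    stop("at least two groups are required to score consistency")
  M <- unique(vapply(groupSims, function(s) nrow(s@mat), integer(1)))
  if (length(M) != 1L) stop("groups have mismatched seed counts")
  kRange <- sort(as.integer(kRange))
  if (min(kRange) < 2L || max(kRange) > M)
    stop("'kRange' must lie within [2, ", M, "]")
  scores <- vapply(kRange, function(k) {
    parcs <- lapply(groupSims, spectralParcellate, k = k, seed = seed,
                    affinity = affinity)
    pairs <- utils::combn(length(parcs), 2)
    ari <- apply(pairs, 2, function(ij)
      adjustedRand(parcs[[ij[1]]], parcs[[ij[2]]]))
    max(0, mean(ari))
  }, numeric(1))
  ok <- scores >= tau
  chosen <- if (any(ok)) max(kRange[ok]) else kRange[which.max(scores)]
  new("KScanResult", kValues = kRange, scores = scores,
      chosenK = as.integer(chosen), tau = as.numeric(tau),
      reachedTau = any(ok))
}

#' Write a parcellation or k-scan result to plain text
#'
#' Parcellations are written as two-column TSV (\code{seed_id},
#' \code{label}) plus a JSON provenance sidecar; scan results as TSV
#' (\code{k}, \code{score}) plus JSON.
#'
#' @param x a \linkS4class{Parcellation} or \linkS4class{KScanResult}.
#' @param path output TSV path (\code{.json} sidecar written next to it).
#' @return the path, invisibly.
#' @export
writeParcellation <- function(x, path) {
  if (is(x, "Parcellation")) {
    utils::write.table(
      data.frame(seed_id = seq_along(x@labels) - 1L, label = x@labels),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(x@provenance, sub("\\.tsv$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  } else if (is(x, "KScanResult")) {
    utils::write.table(
      data.frame(k = x@kValues, score = x@scores),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(chosen_k = x@chosenK, tau = x@tau, reached_tau = x@reachedTau),
      sub("\\.tsv$", ".json", path), auto_unbox = TRUE, digits = NA)
  } else stop("unsupported object")
  invisible(path)
}

#' Block-structured similarity fixture
#'
#' A synthetic group similarity matrix with k equal contiguous seed blocks:
#' within-block correlation \code{within}, between-block \code{between},
#' plus symmetric Gaussian noise, clipped to [-1, 1] with unit diagonal.
#' The canonical benchmark for parcellation recovery (M = 400, within 0.8,
#' between 0.2, noise sd 0.1).
#'
#' @param M number of seeds.
#' @param k number of planted blocks.
#' @param within,between block correlation levels.
#' @param noiseSd sd of the symmetric additive noise.
#' @param seed RNG seed.
#' @return list with \code{sim} (a group-level
#'   \linkS4class{SimilarityMatrix}) and \code{labels} (planted block
#'   labels).
#' @export
blockSimilarityFixture <- function(M = 400L, k = 4L, within = 0.8,
                                   between = 0.2, noiseSd = 0.1,
                                   seed = 0L) {
  labels <- sort(rep_len(seq_len(k), M))
  base <- matrix(between, M, M)
  for (c in seq_len(k)) {
    idx <- which(labels == c)
    base[idx, idx] <- within
  }
  S <- withSeed(seed, {
    E <- matrix(stats::rnorm(M * M, sd = noiseSd), M, M)
    base + (E + t(E)) / sqrt(2)
  })
  S <- pmin(pmax(S, -1), 1)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  list(sim = new("SimilarityMatrix", mat = S, level = "group"),
       labels = labels)
}

#' Concordant groups with divergent finer structure
#'
#' Builds similarity matrices for several groups that share the same
#' k-block parcellation but disagree about any finer subdivision: every
#' group carries a mild internal split (correlation \code{subWithin}
#' between the two halves, still well above \code{between}) in a
#' \emph{different} block.  At the planted k all groups recover the same
#' partition; at k + 1 each group confidently splits its own block, so
#' cross-group consistency collapses — the situation in which a
#' maximum-coherent-k rule should stop at the planted k.
#'
#' @param nGroups number of groups (>= 2).
#' @param M,k,within,between,noiseSd as in [blockSimilarityFixture()].
#' @param blockProps relative block sizes (unequal by default, as real
#'   subregions are; the larger blocks host the divergent subdivisions).
#' @param subWithin correlation between the two halves of each group's
#'   subdivided block (default 0.55).
#' @param seed RNG seed (one offset per group).
#' @return list with \code{sims} (named list of group-level
#'   \linkS4class{SimilarityMatrix}) and \code{labels} (shared planted
#'   labels).
#' @export
concordantGroupFixture <- function(nGroups = 3L, M = 400L, k = 4L,
                                   within = 0.8, between = 0.2,
                                   noiseSd = 0.1,
                                   blockProps = c(0.3, 0.3, 0.3, 0.1),
                                   subWithin = 0.55, seed = 0L) {
  stopifnot(length(blockProps) == k)
  sizes <- round(blockProps / sum(blockProps) * M)
  sizes[k] <- M - sum(sizes[-k])
  labels <- rep(seq_len(k), times = sizes)
  sims <- lapply(seq_len(nGroups), function(g) {
    base <- matrix(between, M, M)
    for (c in seq_len(k)) {
      idx <- which(labels == c)
      base[idx, idx] <- within
    }
    big <- order(sizes, decreasing = TRUE)
    splitBlock <- big[((g - 1L) %% length(big)) + 1L]
    idx <- which(labels == splitBlock)
    half1 <- idx[seq_len(length(idx) %/% 2)]
    half2 <- setdiff(idx, half1)
    base[half1, half2] <- subWithin
    base[half2, half1] <- subWithin
    S <- withSeed(seed + g, {
      E <- matrix(stats::rnorm(M * M, sd = noiseSd), M, M)
      base + (E + t(E)) / sqrt(2)
    })
    S <- pmin(pmax(S, -1), 1)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    new("SimilarityMatrix", mat = S, level = "group")
  })
  names(sims) <- paste0("group", seq_len(nGroups))
  list(sims = sims, labels = labels)
}
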