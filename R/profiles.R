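#' Log-transform and max-normalize a connectivity profile
#'
#' Applies the tractogram normalization recipe: every entry \code{x} is
#' mapped to \code{log(1 + x)} (so zeros stay zero and sparsity is
#' preserved) and the whole matrix is then divided by its maximum, putting
#' all entries in [0, 1] with a maximum of exactly 1.  An all-zero matrix is
#' returned unchanged with a warning.  On a
#' \linkS4class{ConnectivityProfile} the operation is idempotent: an
#' already-normalized profile is returned as is.
#'
#' @param x a non-negative matrix, a \linkS4class{ConnectivityProfile}, or a
#'   \linkS4class{ConnAsymExperiment} (every assay is normalized).
#' @param ... unused.
#' @return an object of the same class as \code{x}, normalized.
#' @examples
#' normalizeProfile(matrix(c(0, 9, 99), 1))  # 0, 0.5, 1
#' @rdname normalizeProfile
#' @export
setMethod("normalizeProfile", "matrix", function(x, ...) {
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative connectivity at row %d, column %d",
                 bad[1], bad[2]))
  }
  y <- log1p(x)
  mx <- max(y)
  if (mx == 0) {
    warning("all-zero connectivity matrix; returned unchanged")
    return(y)
  }
  y / mx
})

#' @rdname normalizeProfile
#' @export
setMethod("normalizeProfile", "ConnectivityProfile", function(x, ...) {
  if (x@normalized) return(x)
  m <- normalizeProfile(x@mat)
  ConnectivityProfile(m, x@subjectId, x@hemisphere, normalized = TRUE)
})

#' @rdname normalizeProfile
#' @export
setMethod("normalizeProfile", "ConnAsymExperiment", function(x, ...) {
  if (isTRUE(metadata(x)$normalized)) return(x)
  for (nm in assayNames(x))
    assay(x, nm) <- normalizeProfile(assay(x, nm))
  metadata(x)$normalized <- TRUE
  x
})

## Row-stochastic, symmetric (hence doubly stochastic) one-round smoothing
## operator for a symmetric seed-adjacency list: every neighbour edge gets
## the uniform weight 1/d_max and the remainder stays on the diagonal.
## Symmetry of the operator preserves each target column's seed-sum.
.smoothingOperator <- function(adjacency, M) {
  deg <- lengths(adjacency) + 1L            # + self
  dmax <- max(deg)
  W <- matrix(0, M, M)
  for (i in seq_len(M)) {
    nb <- adjacency[[i]]
    if (length(nb)) W[i, nb] <- 1 / dmax
    W[i, i] <- 1 - length(nb) / dmax
  }
  W
}

#' Neighborhood smoothing of seed rows
#'
#' A graph analogue of metric kernel smoothing on the cortical surface:
#' \code{rounds} iterations of neighborhood averaging over seed rows, using
#' the uniform edge weight \code{1/d_max} (with the remaining mass on the
#' self-loop).  For a symmetric adjacency the operator is doubly
#' stochastic, so the sum of every target column over seeds is preserved.
#' \code{rounds = 0} is the identity.
#'
#' @param x matrix or \linkS4class{ConnectivityProfile}.
#' @param adjacency list of integer neighbour vectors, one per seed
#'   (self-loops implicit).
#' @param rounds non-negative number of averaging iterations.
#' @param ... unused.
#' @return same class as \code{x}, smoothed.
#' @rdname smoothProfile
#' @export
setMethod("smoothProfile", "matrix",
  function(x, adjacency, rounds = 0L, ...) {
    rounds <- as.integer(rounds)
    stopifnot(rounds >= 0L)
    M <- nrow(x)
    if (length(adjacency) != M)
      stop("adjacency must have one entry per seed (", M, ")")
    idx <- unlist(adjacency, use.names = FALSE)
    if (length(idx) && (any(idx < 1L) || any(idx > M)))
      stop("adjacency references an unknown seed index")
    if (rounds == 0L) return(x)
    W <- .smoothingOperator(adjacency, M)
    for (r in seq_len(rounds)) x <- W %*% x
    x
  })

#' @rdname smoothProfile
#' @export
setMethod("smoothProfile", "ConnectivityProfile",
  function(x, adjacency, rounds = 0L, ...) {
    m <- smoothProfile(x@mat, adjacency, rounds)
    ConnectivityProfile(m, x@subjectId, x@hemisphere,
                        normalized = x@normalized)
  })

#' Across-subject population connectivity map
#'
#' Averages a cluster's normalized connectivity fingerprints element-wise
#' across subjects and thresholds the mean: entries at or below
#' \code{threshold} are zeroed (strict \code{>} retained).  The surviving
#' index set (the map's support) and the fraction of originally non-zero
#' mean entries retained are recorded.  This is the population-tractogram
#' analogue used to build group masks.
#'
#' @param profiles list of numeric vectors (one per subject; a cluster's
#'   mean connectivity per target) or of single-row matrices /
#'   \linkS4class{ConnectivityProfile}s of identical shape and hemisphere.
#' @param threshold retention threshold on the group-mean scale.
#' @param hemisphere hemisphere label stored in the result.
#' @return a \linkS4class{PopulationMap}.
#' @examples
#' populationMap(list(c(0.4, 0.9), c(0.8, 0.1)), threshold = 0.5)
#' @export
populationMap <- function(profiles, threshold, hemisphere = "L") {
  stopifnot(length(profiles) >= 1L, threshold >= 0)
  vecs <- lapply(profiles, function(p) {
    if (is(p, "ConnectivityProfile")) {
      if (p@hemisphere != hemisphere)
        stop("profile hemisphere '", p@hemisphere,
             "' does not match '", hemisphere, "'")
      as.numeric(p@mat)
    } else as.numeric(p)
  })
  n <- unique(lengths(vecs))
  if (length(n) != 1L)
    stop("profiles have mixed shapes")
  avg <- Reduce(`+`, vecs) / length(vecs)
  nonzero <- sum(avg > 0)
  keep <- avg > threshold
  avg[!keep] <- 0
  new("PopulationMap", values = avg, threshold = as.numeric(threshold),
      support = which(keep), hemisphere = hemisphere,
      nSubjects = length(vecs),
      retainedFraction = if (nonzero) sum(keep) / nonzero else NaN)
}

#' Group analysis mask from left and mirrored right population maps
#'
#' The testable target set for vertex-wise asymmetry statistics: the union
#' of the supports of the left population map and the right population map
#' already expressed in mirrored (left-indexed) space.
#'
#' @param leftPop,rightPop \linkS4class{PopulationMap}s of equal length.
#' @return sorted integer index vector.
#' @export
groupMask <- function(leftPop, rightPop) {
  stopifnot(is(leftPop, "PopulationMap"), is(rightPop, "PopulationMap"))
  if (length(leftPop@values) != length(rightPop@values))
    stop("population maps have different lengths")
  sort(union(leftPop@support, rightPop@support))
}

#' Write / read a population map or mask
#'
#' Population maps are written as two-column TSV (\code{target_id},
#' \code{value}); masks as a one-column file of 0-based indices (documented
#' in the header line).
#'
#' @param map a \linkS4class{PopulationMap}.
#' @param mask integer index vector (1-based in R; written 0-based).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePopulationMap <- function(map, path) {
  utils::write.table(
    data.frame(target_id = seq_along(map@values) - 1L, value = map@values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePopulationMap
#' @export
writeMask <- function(mask, path) {
  writeLines(c("# 0-based target indices", as.character(mask - 1L)), path)
  invisible(path)
}
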