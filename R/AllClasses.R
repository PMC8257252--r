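#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assays assayNames
#'   assay assay<- rowData colData
NULL

#' Species-level simulation specification
#'
#' A \code{SpeciesSpec} fixes everything the synthetic-data generator needs
#' for one species-like group: the cohort size, the seed-region and
#' whole-brain target dimensions, the planted cluster structure of the seed
#' region, the connectional asymmetries applied to the right hemisphere, and
#' the volumetric scaling model.
#'
#' @slot name single character label (e.g. \code{"human-like"}).
#' @slot nSubjects number of subjects to simulate.
#' @slot nSeeds number of seed vertices per hemisphere (M).
#' @slot nTargets number of whole-brain target bins (N).
#' @slot kTrue planted number of seed clusters.
#' @slot blockAssignment integer vector of length \code{nSeeds} mapping each
#'   seed vertex to its planted cluster in \code{1..kTrue}.
#' @slot clusterProfiles \code{kTrue x nTargets} non-negative matrix of mean
#'   connectivity per cluster (the connectivity fingerprints rows are drawn
#'   around).
#' @slot asymEffects \code{kTrue x nTargets} positive matrix of multiplicative
#'   effects applied to right-hemisphere rows; 1 means symmetric, values > 1
#'   plant rightward (positive AI) connectional asymmetry.
#' @slot noiseSd standard deviation of the additive, truncated-at-zero
#'   Gaussian noise on connectivity rows (same units as
#'   \code{clusterProfiles}).
#' @slot scalingExponent allometric exponent per subregion (length
#'   \code{kTrue}); values > 1 plant positive allometry.
#' @slot scalingIntercept natural-log intercept per subregion of the
#'   volume-vs-GMV power law.
#' @slot volumeAI planted volumetric asymmetry index per subregion, each in
#'   the open interval (-2, 2) (the mathematical range of
#'   \code{2 (R - L) / (R + L)}).
#' @slot gmvRange length-2 numeric, min/max total gray-matter volume in mm^3;
#'   subjects are drawn log-uniformly in this range.
#' @slot volumeNoiseSd standard deviation of the per-hemisphere lognormal
#'   volume noise (log scale).
#'
#' @seealso [SpeciesSpec()], [presetSpec()], [simulateDataset()]
#' @export
setClass("SpeciesSpec",
  representation(
    name = "character",
    nSubjects = "integer",
    nSeeds = "integer",
    nTargets = "integer",
    kTrue = "integer",
    blockAssignment = "integer",
    clusterProfiles = "matrix",
    asymEffects = "matrix",
    noiseSd = "numeric",
    scalingExponent = "numeric",
    scalingIntercept = "numeric",
    volumeAI = "numeric",
    gmvRange = "numeric",
    volumeNoiseSd = "numeric"
  )
)

setValidity("SpeciesSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  for (s in c("nSubjects", "nSeeds", "nTargets", "kTrue")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 1L)
      msg <- c(msg, sprintf("'%s' must be a positive integer", s))
  }
  if (object@kTrue > object@nSeeds)
    msg <- c(msg, "'kTrue' cannot exceed 'nSeeds'")
  ba <- object@blockAssignment
  if (length(ba) != object@nSeeds)
    msg <- c(msg, "'blockAssignment' must cover all seeds")
  else if (anyNA(ba) || any(ba < 1L) || any(ba > object@kTrue))
    msg <- c(msg, "'blockAssignment' labels must lie in 1..kTrue")
  else if (length(unique(ba)) != object@kTrue)
    msg <- c(msg, "every cluster in 1..kTrue must receive at least one seed")
  if (!identical(dim(object@clusterProfiles),
                 c(object@kTrue, object@nTargets)))
    msg <- c(msg, "'clusterProfiles' must be kTrue x nTargets")
  else if (any(object@clusterProfiles < 0))
    msg <- c(msg, "'clusterProfiles' must be non-negative")
  if (!identical(dim(object@asymEffects), c(object@kTrue, object@nTargets)))
    msg <- c(msg, "'asymEffects' must be kTrue x nTargets")
  else if (any(object@asymEffects <= 0))
    msg <- c(msg, "'asymEffects' must be strictly positive")
  if (length(object@noiseSd) != 1L || is.na(object@noiseSd) ||
      object@noiseSd < 0)
    msg <- c(msg, "'noiseSd' must be a single non-negative number")
  for (s in c("scalingExponent", "scalingIntercept", "volumeAI")) {
    if (length(slot(object, s)) != object@kTrue)
      msg <- c(msg, sprintf("'%s' must have length kTrue", s))
  }
  if (length(object@scalingExponent) == object@kTrue &&
      any(object@scalingExponent <= 0))
    msg <- c(msg, "'scalingExponent' must be positive")
  if (length(object@volumeAI) == object@kTrue &&
      any(abs(object@volumeAI) >= 2))
    msg <- c(msg, "'volumeAI' must lie in the open interval (-2, 2)")
  gr <- object@gmvRange
  if (length(gr) != 2L || anyNA(gr) || gr[1] <= 0 || gr[2] < gr[1])
    msg <- c(msg, "'gmvRange' must be 0 < min <= max")
  if (length(object@volumeNoiseSd) != 1L || object@volumeNoiseSd < 0)
    msg <- c(msg, "'volumeNoiseSd' must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Multi-subject bihemispheric connectivity container
#'
#' \code{ConnAsymExperiment} extends
#' \linkS4class{SummarizedExperiment}: rows are seed vertices, columns are
#' whole-brain target bins, and each assay holds one subject-hemisphere
#' connectivity matrix (assay names \code{"<subject>_L"} /
#' \code{"<subject>_R"}).  Seed index \code{i} on the left corresponds to
#' mirrored seed index \code{i} on the right, so left and right matrices are
#' directly comparable row by row.  Simulation provenance (the
#' \linkS4class{SpeciesSpec}, RNG seed, volume table and ground truth) lives
#' in \code{metadata()}.
#'
#' @seealso [simulateDataset()], [volumeTable()], [trueLabels()]
#' @export
setClass("ConnAsymExperiment", contains = "SummarizedExperiment")

setValidity("ConnAsymExperiment", function(object) {
  msg <- character()
  an <- assayNames(object)
  if (is.null(an) || !all(grepl("_(L|R)$", an)))
    msg <- c(msg, "assay names must end in '_L' or '_R'")
  for (nm in an) {
    a <- assay(object, nm)
    if (any(a < 0)) {
      msg <- c(msg, sprintf("assay '%s' contains negative connectivity", nm))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Single-subject connectivity profile matrix
#'
#' One subject-hemisphere seed-by-target connectivity matrix, with a flag
#' recording whether the log / max-normalization step has been applied
#' (after normalization all entries lie in [0, 1]).
#'
#' @slot mat non-negative numeric matrix, seeds x targets.
#' @slot subjectId single character subject identifier.
#' @slot hemisphere \code{"L"} or \code{"R"}.
#' @slot normalized logical; \code{TRUE} once [normalizeProfile()] has run.
#' @export
setClass("ConnectivityProfile",
  representation(mat = "matrix", subjectId = "character",
                 hemisphere = "character", normalized = "logical")
)

setValidity("ConnectivityProfile", function(object) {
  msg <- character()
  if (any(object@mat < 0))
    msg <- c(msg, "connectivity entries must be non-negative")
  if (!object@hemisphere %in% c("L", "R"))
    msg <- c(msg, "'hemisphere' must be \"L\" or \"R\"")
  if (length(object@normalized) != 1L)
    msg <- c(msg, "'normalized' must be a single logical")
  else if (isTRUE(object@normalized) && length(object@mat) &&
           max(object@mat) > 1 + 1e-12)
    msg <- c(msg, "normalized profiles must have entries in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Thresholded group-mean connectivity map
#'
#' The across-subject mean of normalized connectivity values (a population
#' tractogram analogue), thresholded so that entries at or below the
#' threshold are zeroed; \code{support} records exactly the surviving
#' indices.
#'
#' @slot values numeric vector of group-mean connectivity after thresholding.
#' @slot threshold threshold used (strict: values > threshold survive).
#' @slot support integer indices of entries strictly above the threshold.
#' @slot hemisphere hemisphere label of the contributing profiles.
#' @slot nSubjects number of subjects averaged.
#' @slot retainedFraction fraction of originally non-zero entries that
#'   survived the threshold.
#' @export
setClass("PopulationMap",
  representation(values = "numeric", threshold = "numeric",
                 support = "integer", hemisphere = "character",
                 nSubjects = "integer", retainedFraction = "numeric")
)

setValidity("PopulationMap", function(object) {
  msg <- character()
  sup <- which(object@values > object@threshold)
  if (!identical(sup, object@support))
    msg <- c(msg, "'support' must equal the indices with value > threshold")
  if (any(object@values[setdiff(seq_along(object@values), sup)] != 0))
    msg <- c(msg, "thresholded entries must be exactly zero")
  if (length(msg)) msg else TRUE
})

#' Seed-by-seed connectivity-similarity matrix
#'
#' Pearson cross-correlation between the connectivity profiles of every pair
#' of seed vertices, either for one subject or averaged across subjects
#' (\code{level = "group"}).  Symmetric with unit diagonal; entries in
#' [-1, 1].
#'
#' @slot mat numeric M x M matrix.
#' @slot level \code{"subject"} or \code{"group"}.
#' @export
setClass("SimilarityMatrix",
  representation(mat = "matrix", level = "character"))

setValidity("SimilarityMatrix", function(object) {
  m <- object@mat
  msg <- character()
  if (nrow(m) != ncol(m))
    msg <- c(msg, "similarity matrix must be square")
  else {
    if (max(abs(m - t(m))) > 1e-10)
      msg <- c(msg, "similarity matrix must be symmetric within 1e-10")
    if (max(abs(diag(m) - 1)) > 1e-10)
      msg <- c(msg, "diagonal must equal 1")
    if (min(m) < -1 - 1e-10 || max(m) > 1 + 1e-10)
      msg <- c(msg, "entries must lie in [-1, 1]")
  }
  if (!object@level %in% c("subject", "group"))
    msg <- c(msg, "'level' must be \"subject\" or \"group\"")
  if (length(msg)) msg else TRUE
})

#' Parcellation of the seed region
#'
#' Integer cluster label per seed vertex for a given k, canonically
#' relabelled (cluster 1 contains the lowest seed index, labels ascend by
#' first occurrence), plus optional per-cluster mean connectivity
#' fingerprints and clustering provenance.
#'
#' @slot labels integer vector, one label in \code{1..k} per seed vertex.
#' @slot k number of clusters.
#' @slot fingerprints k x nTargets matrix of mean connectivity per cluster
#'   (0 x 0 when no profile was supplied).
#' @slot provenance list recording k, RNG seed and affinity settings.
#' @export
setClass("Parcellation",
  representation(labels = "integer", k = "integer",
                 fingerprints = "matrix", provenance = "list"))

setValidity("Parcellation", function(object) {
  msg <- character()
  if (!all(seq_len(object@k) %in% object@labels))
    msg <- c(msg, "every label in 1..k must occur at least once")
  if (any(object@labels < 1L) || any(object@labels > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (length(msg)) msg else TRUE
})

#' Cluster-number scan result
#'
#' Per-k cross-group consistency scores (mean pairwise adjusted Rand index,
#' clamped to [0, 1]) and the chosen k: the maximum k whose score reaches
#' the threshold tau, or the argmax score (flagged via \code{reachedTau})
#' when no k reaches it.
#'
#' @slot kValues integer vector of the scanned k.
#' @slot scores consistency score per k, in [0, 1].
#' @slot chosenK selected number of clusters.
#' @slot tau consistency threshold used.
#' @slot reachedTau \code{TRUE} when at least one k reached tau.
#' @export
setClass("KScanResult",
  representation(kValues = "integer", scores = "numeric",
                 chosenK = "integer", tau = "numeric",
                 reachedTau = "logical"))

setValidity("KScanResult", function(object) {
  msg <- character()
  if (length(object@scores) != length(object@kValues))
    msg <- c(msg, "'scores' and 'kValues' lengths differ")
  if (any(object@scores < 0) || any(object@scores > 1))
    msg <- c(msg, "scores must lie in [0, 1]")
  ok <- object@scores >= object@tau
  expect <- if (any(ok)) max(object@kValues[ok]) else
    object@kValues[which.max(object@scores)]
  if (object@chosenK != expect)
    msg <- c(msg, "'chosenK' violates the selection rule")
  if (length(msg)) msg else TRUE
})

#' Allometric scaling fit
#'
#' Ordinary least squares of log(volume) on log(total gray-matter volume):
#' the slope is the allometric scaling exponent (> 1: positive allometry).
#'
#' @slot slope fitted scaling exponent (dimensionless).
#' @slot intercept intercept on the natural-log volume scale.
#' @slot ci95 length-2 numeric, 95\% confidence bounds on the slope from the
#'   t distribution.
#' @slot rSquared coefficient of determination.
#' @slot n number of observations.
#' @slot residualDf residual degrees of freedom.
#' @export
setClass("AllometryFit",
  representation(slope = "numeric", intercept = "numeric", ci95 = "numeric",
                 rSquared = "numeric", n = "integer", residualDf = "integer"))

setValidity("AllometryFit", function(object) {
  msg <- character()
  if (object@n < 3L) msg <- c(msg, "at least 3 observations are required")
  if (length(object@ci95) != 2L ||
      (!anyNA(object@ci95) &&
       (object@ci95[1] > object@slope || object@ci95[2] < object@slope)))
    msg <- c(msg, "'ci95' must bracket the slope")
  if (length(msg)) msg else TRUE
})

#' Between-hemisphere slope comparison (ANCOVA interaction test)
#'
#' F-test of the \code{log(gmv) : hemisphere} interaction in the stacked
#' model \code{log(volume) ~ log(gmv) * hemisphere}; a small p-value means
#' the left and right allometric slopes differ.
#'
#' @slot slopeLeft,slopeRight per-hemisphere fitted slopes.
#' @slot fStat F statistic of the interaction term.
#' @slot pValue interaction p-value.
#' @slot df length-2 numeric (numerator, denominator df).
#' @slot degenerate \code{TRUE} when the two hemispheres carried identical
#'   data and the test is vacuous.
#' @export
setClass("SlopeComparison",
  representation(slopeLeft = "numeric", slopeRight = "numeric",
                 fStat = "numeric", pValue = "numeric", df = "numeric",
                 degenerate = "logical"))

setValidity("SlopeComparison", function(object) {
  msg <- character()
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "p-value must lie in [0, 1]")
  if (!is.na(object@fStat) && object@fStat < 0)
    msg <- c(msg, "F statistic must be non-negative")
  if (length(msg)) msg else TRUE
})
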