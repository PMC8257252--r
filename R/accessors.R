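#' Accessors for connAsym objects
#'
#' Small accessor functions exposing the slots of the package's S4 classes:
#' simulation provenance and volumes of a \linkS4class{ConnAsymExperiment},
#' labels and fingerprints of a \linkS4class{Parcellation}, values and
#' support of a \linkS4class{PopulationMap}, the matrix of a
#' \linkS4class{SimilarityMatrix}, and the scan scores / selected k of a
#' \linkS4class{KScanResult}.
#'
#' @param x the object.
#' @param subject single subject id (see \code{subjectIds(x)}).
#' @param ... unused.
#' @return the corresponding slot value; \code{profilePair()} returns a list
#'   with elements \code{L} and \code{R} of
#'   \linkS4class{ConnectivityProfile}.
#' @name accessors
NULL

#' @rdname accessors
setMethod("speciesSpec", "ConnAsymExperiment",
          function(x) metadata(x)$spec)

#' @rdname accessors
setMethod("volumeTable", "ConnAsymExperiment",
          function(x) metadata(x)$volumes)

#' @rdname accessors
setMethod("trueLabels", "ConnAsymExperiment",
          function(x) metadata(x)$groundTruth$labels)

#' @rdname accessors
setMethod("datasetSeed", "ConnAsymExperiment",
          function(x) metadata(x)$seed)

#' @rdname accessors
setMethod("subjectIds", "ConnAsymExperiment", function(x)
  unique(sub("_(L|R)$", "", assayNames(x))))

#' @rdname accessors
setMethod("profilePair", "ConnAsymExperiment",
  function(x, subject, ...) {
    stopifnot(length(subject) == 1L)
    nmL <- paste0(subject, "_L"); nmR <- paste0(subject, "_R")
    if (!all(c(nmL, nmR) %in% assayNames(x)))
      stop("missing hemisphere assay for subject '", subject, "'")
    norm <- isTRUE(metadata(x)$normalized)
    list(
      L = ConnectivityProfile(assay(x, nmL), subject, "L", normalized = norm),
      R = ConnectivityProfile(assay(x, nmR), subject, "R", normalized = norm)
    )
  })

#' @rdname accessors
setMethod("parcelLabels", "Parcellation", function(x) x@labels)

#' @rdname accessors
setMethod("fingerprints", "Parcellation", function(x) x@fingerprints)

#' @rdname accessors
setMethod("mapSupport", "PopulationMap", function(x) x@support)

#' @rdname accessors
setMethod("mapValues", "PopulationMap", function(x) x@values)

#' @rdname accessors
setMethod("similarityMatrix", "SimilarityMatrix", function(x) x@mat)

#' @rdname accessors
setMethod("chosenK", "KScanResult", function(x) x@chosenK)

#' @rdname accessors
setMethod("scanScores", "KScanResult", function(x)
  stats::setNames(x@scores, x@kValues))

#' Construct a ConnectivityProfile
#'
#' @param mat non-negative seeds x targets matrix.
#' @param subjectId subject identifier.
#' @param hemisphere \code{"L"} or \code{"R"}.
#' @param normalized whether the matrix has already been log/max-normalized.
#' @return a \linkS4class{ConnectivityProfile}.
#' @examples
#' p <- ConnectivityProfile(matrix(1:6, 2), "s01", "L")
#' @export
ConnectivityProfile <- function(mat, subjectId = "subject",
                                hemisphere = c("L", "R"),
                                normalized = FALSE) {
  hemisphere <- match.arg(hemisphere)
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  new("ConnectivityProfile", mat = mat, subjectId = as.character(subjectId),
      hemisphere = hemisphere, normalized = normalized)
}

#' Extract the matrix of a ConnectivityProfile
#' @param x a \linkS4class{ConnectivityProfile}.
#' @return its numeric matrix.
#' @export
profileMatrix <- function(x) {
  stopifnot(is(x, "ConnectivityProfile"))
  x@mat
}

setMethod("show", "SpeciesSpec", function(object) {
  cat("SpeciesSpec \"", object@name, "\"\n", sep = "")
  cat("  subjects:", object@nSubjects,
      "| seeds/hemisphere:", object@nSeeds,
      "| targets:", object@nTargets, "\n")
  cat("  planted clusters:", object@kTrue,
      "| profile noise sd:", object@noiseSd, "\n")
  cat("  asymmetric cells:", sum(object@asymEffects != 1),
      "| volumetric AI:", paste(signif(object@volumeAI, 3), collapse = ", "),
      "\n")
  cat("  scaling exponents:",
      paste(signif(object@scalingExponent, 3), collapse = ", "), "\n")
})

setMethod("show", "ConnAsymExperiment", function(object) {
  callNextMethod()
  sp <- speciesSpec(object)
  if (!is.null(sp))
    cat("species:", sp@name, "| subjects:", length(subjectIds(object)),
        "| seed:", datasetSeed(object), "\n")
})

setMethod("show", "ConnectivityProfile", function(object) {
  cat("ConnectivityProfile", object@subjectId,
      paste0("(", object@hemisphere, "):"),
      nrow(object@mat), "seeds x", ncol(object@mat), "targets;",
      if (object@normalized) "normalized" else "raw", "\n")
})

setMethod("show", "PopulationMap", function(object) {
  cat("PopulationMap over", length(object@values), "targets (",
      object@hemisphere, "), threshold", object@threshold, "\n")
  cat("  support:", length(object@support), "entries; retained fraction",
      signif(object@retainedFraction, 3), "of non-zero mean values\n")
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat("SimilarityMatrix (", object@level, " level): ",
      nrow(object@mat), " x ", ncol(object@mat), " seeds\n", sep = "")
})

setMethod("show", "Parcellation", function(object) {
  cat("Parcellation with k =", object@k, "clusters over",
      length(object@labels), "seeds\n")
  print(table(cluster = object@labels))
})

setMethod("show", "KScanResult", function(object) {
  cat("KScanResult: chosen k =", object@chosenK,
      if (object@reachedTau) "" else "(no k reached tau; argmax used)", "\n")
  print(round(stats::setNames(object@scores, object@kValues), 3))
})

setMethod("show", "AllometryFit", function(object) {
  cat(sprintf(
    "AllometryFit: slope %.4f [%.4f, %.4f], intercept %.4f, R^2 %.4f, n %d\n",
    object@slope, object@ci95[1], object@ci95[2], object@intercept,
    object@rSquared, object@n))
})

setMethod("show", "SlopeComparison", function(object) {
  cat(sprintf(
    "SlopeComparison: left %.4f vs right %.4f; F(%g, %g) = %.4g, p = %.4g%s\n",
    object@slopeLeft, object@slopeRight, object@df[1], object@df[2],
    object@fStat, object@pValue,
    if (object@degenerate) " (degenerate: identical hemispheres)" else ""))
})
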