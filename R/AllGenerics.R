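#' @rdname normalizeProfile
#' @export
setGeneric("normalizeProfile", function(x, ...)
  standardGeneric("normalizeProfile"))

#' @rdname smoothProfile
#' @export
setGeneric("smoothProfile", function(x, adjacency, rounds = 0L, ...)
  standardGeneric("smoothProfile"))

#' @rdname seedSimilarity
#' @export
setGeneric("seedSimilarity", function(x, ...)
  standardGeneric("seedSimilarity"))

#' @rdname accessors
#' @export
setGeneric("speciesSpec", function(x) standardGeneric("speciesSpec"))

#' @rdname accessors
#' @export
setGeneric("volumeTable", function(x) standardGeneric("volumeTable"))

#' @rdname accessors
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))

#' @rdname accessors
#' @export
setGeneric("datasetSeed", function(x) standardGeneric("datasetSeed"))

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("profilePair", function(x, subject, ...)
  standardGeneric("profilePair"))

#' @rdname accessors
#' @export
setGeneric("parcelLabels", function(x) standardGeneric("parcelLabels"))

#' @rdname accessors
#' @export
setGeneric("fingerprints", function(x) standardGeneric("fingerprints"))

#' @rdname accessors
#' @export
setGeneric("mapSupport", function(x) standardGeneric("mapSupport"))

#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname accessors
#' @export
setGeneric("similarityMatrix", function(x) standardGeneric("similarityMatrix"))

#' @rdname accessors
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))

#' @rdname accessors
#' @export
setGeneric("scanScores", function(x) standardGeneric("scanScores"))
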