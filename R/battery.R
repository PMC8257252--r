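## Per-subject, per-hemisphere cluster fingerprints of a normalized
## dataset: a list (one element per cluster) of subjects x targets
## matrices, separately for L and R.
.subjectFingerprints <- function(ds, labels, k) {
  subj <- subjectIds(ds)
  N <- ncol(ds)
  out <- list(L = vector("list", k), R = vector("list", k))
  for (h in c("L", "R")) {
    for (c in seq_len(k))
      out[[h]][[c]] <- matrix(NA_real_, length(subj), N,
                              dimnames = list(subj, colnames(ds)))
  }
  for (s in seq_along(subj)) {
    for (h in c("L", "R")) {
      a <- assay(ds, paste0(subj[s], "_", h))
      fp <- clusterFingerprints(a, labels, k)
      for (c in seq_len(k)) out[[h]][[c]][s, ] <- fp[c, ]
    }
  }
  out
}

#' Default battery configuration
#'
#' @param alpha significance level.
#' @param nPerm sign-flip permutations for the vertex level.
#' @param seed RNG seed for Monte Carlo flips.
#' @param threshold population-map threshold (normalized connectivity
#'   scale; customary per-species defaults are 0.5 / 0.2 / 0.3).
#' @param smoothRounds neighborhood-smoothing rounds (0 = none).
#' @param adjacency seed-adjacency list for smoothing (chain adjacency is
#'   used when smoothing is requested without one).
#' @param zeroPolicy Wilcoxon zero-difference policy.
#' @param familyMultiplier extra Bonferroni factor (e.g. number of species
#'   when correcting across species; default 1 = per-species families).
#' @param aiOn \code{"ai"} tests the asymmetry index; \code{"diff"} tests
#'   raw \code{R - L} differences at the vertex level.
#' @return configuration list for [runAsymmetryBattery()].
#' @export
batteryConfig <- function(alpha = 0.05, nPerm = 2000L, seed = 0L,
                          threshold = 0.3, smoothRounds = 0L,
                          adjacency = NULL,
                          zeroPolicy = c("discard", "pratt"),
                          familyMultiplier = 1L,
                          aiOn = c("ai", "diff")) {
  list(alpha = alpha, nPerm = as.integer(nPerm), seed = as.integer(seed),
       threshold = threshold, smoothRounds = as.integer(smoothRounds),
       adjacency = adjacency, zeroPolicy = match.arg(zeroPolicy),
       familyMultiplier = as.integer(familyMultiplier),
       aiOn = match.arg(aiOn))
}

#' Run the full asymmetry battery on one dataset
#'
#' Computes per-subject asymmetry indices and the three statistical
#' comparisons in one pass, returning a tidy table with one row per tested
#' unit:
#' \itemize{
#'   \item \strong{volumetric}: per-subregion left/right volumes, Wilcoxon
#'     signed-rank + Bonferroni (family = subregions x
#'     \code{familyMultiplier});
#'   \item \strong{vertex}: per-target AIs of each subregion's connectivity
#'     fingerprint, sign-flip permutation t tests on the group mask (union
#'     of thresholded left and mirrored right population maps) with BH-FDR
#'     across the mask and Cohen's d;
#'   \item \strong{roi} / \strong{tract}: region-mean connectivity per
#'     hemisphere, Wilcoxon signed-rank + Bonferroni (family = subregions x
#'     number of regions x \code{familyMultiplier}).
#' }
#' Profiles are normalized (log / max) and optionally smoothed before any
#' statistic is computed.
#'
#' @param ds a \linkS4class{ConnAsymExperiment} with both hemispheres per
#'   subject (volumes required for the volumetric block).
#' @param parcellation a \linkS4class{Parcellation} of the seed vertices
#'   (defaults to the planted ground-truth labels when available).
#' @param roiSets,tractSets optional named lists of target-index sets; when
#'   empty the corresponding block is omitted.
#' @param config list from [batteryConfig()].
#' @return data.frame with columns \code{level}, \code{species},
#'   \code{subregion}, \code{unit}, \code{n}, \code{ai_mean},
#'   \code{statistic}, \code{p}, \code{p_adj}, \code{d},
#'   \code{significant}.
#' @export
runAsymmetryBattery <- function(ds, parcellation = NULL, roiSets = NULL,
                                tractSets = NULL, config = batteryConfig()) {
  stopifnot(is(ds, "ConnAsymExperiment"))
  species <- if (!is.null(speciesSpec(ds))) speciesSpec(ds)@name else "data"
  subj <- subjectIds(ds)
  for (s in subj)
    if (!all(paste0(s, "_", c("L", "R")) %in% assayNames(ds)))
      stop("subject '", s, "' is missing a hemisphere")
  labels <- if (!is.null(parcellation)) parcelLabels(parcellation)
            else trueLabels(ds)
  if (is.null(labels)) stop("no parcellation and no ground-truth labels")
  k <- max(labels)
  ds <- normalizeProfile(ds)
  if (config$smoothRounds > 0L) {
    adj <- config$adjacency
    if (is.null(adj)) adj <- chainAdjacency(nrow(ds))
    for (nm in assayNames(ds))
      assay(ds, nm) <- smoothProfile(assay(ds, nm), adj,
                                     config$smoothRounds)
  }
  fps <- .subjectFingerprints(ds, labels, k)
  out <- list()

  ## --- volumetric block ---------------------------------------------------
  vols <- volumeTable(ds)
  if (!is.null(vols)) {
    volSub <- sort(unique(vols$subregion))
    mVol <- length(volSub) * config$familyMultiplier
    rows <- lapply(volSub, function(c) {
      v <- vols[vols$subregion == c, ]
      ai <- asymmetryIndex(v$left_vol, v$right_vol)
      wt <- pairedSignedRank(v$left_vol, v$right_vol,
                             zeroPolicy = config$zeroPolicy)
      data.frame(level = "volumetric", species = species, subregion = c,
                 unit = "volume", n = wt$nUsed,
                 ai_mean = mean(ai, na.rm = TRUE), statistic = wt$W,
                 p = wt$p, p_adj = NA_real_, d = cohensD(ai))
    })
    block <- do.call(rbind, rows)
    block$p_adj <- bonferroniAdjust(block$p, m = mVol)
    out$volumetric <- block
  }

  ## --- vertex block -------------------------------------------------------
  for (c in seq_len(k)) {
    FL <- fps$L[[c]]; FR <- fps$R[[c]]
    popL <- populationMap(asplit(FL, 1), config$threshold, "L")
    popR <- populationMap(asplit(FR, 1), config$threshold, "L")
    mask <- groupMask(popL, popR)
    if (!length(mask)) next
    ai <- if (config$aiOn == "ai")
      matrix(asymmetryIndex(FL, FR), nrow(FL), ncol(FL),
             dimnames = dimnames(FL))
    else FR - FL
    vt <- vertexwiseTest(ai, mask, nPerm = config$nPerm,
                         seed = config$seed + c, alpha = config$alpha)
    out[[paste0("vertex", c)]] <- data.frame(
      level = "vertex", species = species, subregion = c,
      unit = colnames(FL)[vt$unit], n = vt$n, ai_mean = vt$ai_mean,
      statistic = vt$statistic, p = vt$p, p_adj = vt$q, d = vt$d)
  }

  ## --- roi / tract blocks -------------------------------------------------
  regionBlock <- function(sets, levelName) {
    if (is.null(sets) || !length(sets)) return(NULL)
    if (is.null(names(sets)))
      names(sets) <- paste0(levelName, seq_along(sets))
    m <- k * length(sets) * config$familyMultiplier
    rows <- list()
    for (c in seq_len(k)) {
      for (rn in names(sets)) {
        rv <- regionValues(fps$L[[c]], fps$R[[c]], sets[[rn]])
        ai <- asymmetryIndex(rv$L, rv$R)
        wt <- pairedSignedRank(rv$L, rv$R, zeroPolicy = config$zeroPolicy)
        rows[[paste(c, rn)]] <- data.frame(
          level = levelName, species = species, subregion = c, unit = rn,
          n = wt$nUsed, ai_mean = mean(ai, na.rm = TRUE),
          statistic = wt$W, p = wt$p, p_adj = NA_real_, d = cohensD(ai))
      }
    }
    block <- do.call(rbind, rows)
    block$p_adj <- bonferroniAdjust(block$p, m = m)
    block
  }
  out$roi <- regionBlock(roiSets, "roi")
  out$tract <- regionBlock(tractSets, "tract")

  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$significant <- !is.na(res$p_adj) & res$p_adj < config$alpha
  res
}

#' Chain adjacency over seeds
#'
#' Simple 1-D neighbour structure (seed i adjacent to i - 1 and i + 1),
#' the default graph for neighborhood smoothing when no geometry is
#' available.
#'
#' @param M number of seeds.
#' @return list of integer neighbour vectors.
#' @export
chainAdjacency <- function(M) {
  lapply(seq_len(M), function(i)
    setdiff(intersect(c(i - 1L, i + 1L), seq_len(M)), i))
}
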