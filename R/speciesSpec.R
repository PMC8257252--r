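#' Build a species-level simulation specification
#'
#' Constructs and validates a \linkS4class{SpeciesSpec}, the complete recipe
#' the synthetic-data generator needs for one species-like cohort: planted
#' seed-cluster structure, mean connectivity fingerprints per cluster,
#' multiplicative right-hemisphere connectional asymmetries, profile noise,
#' and the volumetric power-law model (exponent, intercept, planted
#' volumetric AI, lognormal noise).
#'
#' @param name species label.
#' @param nSubjects cohort size.
#' @param nSeeds seed vertices per hemisphere (M).
#' @param nTargets whole-brain target bins (N).
#' @param kTrue planted number of clusters.
#' @param blockAssignment integer seed-to-cluster map of length
#'   \code{nSeeds}; default: contiguous equal blocks.
#' @param clusterProfiles \code{kTrue x nTargets} non-negative matrix of mean
#'   connectivity per cluster.
#' @param asymEffects \code{kTrue x nTargets} positive matrix of
#'   multiplicative right-hemisphere effects (default all 1: symmetric).
#' @param noiseSd additive truncated-at-zero profile noise sd.
#' @param scalingExponent,scalingIntercept allometric exponent and
#'   natural-log intercept per subregion (length \code{kTrue}).
#' @param volumeAI planted volumetric asymmetry index per subregion, each in
#'   (-2, 2); negative = leftward.
#' @param gmvRange min/max total gray-matter volume (mm^3).
#' @param volumeNoiseSd per-hemisphere lognormal volume noise sd (log scale).
#' @return a validated \linkS4class{SpeciesSpec}.
#' @examples
#' sp <- SpeciesSpec("toy", nSubjects = 4, nSeeds = 8, nTargets = 12,
#'                   kTrue = 2,
#'                   clusterProfiles = rbind(rep(c(9, 1), each = 6),
#'                                           rep(c(1, 9), each = 6)))
#' @seealso [presetSpec()] for the three shipped species-like presets.
#' @export
SpeciesSpec <- function(name, nSubjects, nSeeds, nTargets, kTrue,
                        blockAssignment = NULL, clusterProfiles,
                        asymEffects = NULL, noiseSd = 0,
                        scalingExponent = rep(1, kTrue),
                        scalingIntercept = rep(0, kTrue),
                        volumeAI = rep(0, kTrue),
                        gmvRange = c(1e5, 2e5),
                        volumeNoiseSd = 0) {
  kTrue <- as.integer(kTrue)
  nSeeds <- as.integer(nSeeds)
  if (kTrue > nSeeds)
    stop("invalid spec: 'kTrue' (", kTrue, ") exceeds 'nSeeds' (",
         nSeeds, ")")
  if (length(noiseSd) != 1L || is.na(noiseSd) || noiseSd < 0)
    stop("invalid spec: 'noiseSd' must be a single non-negative number")
  if (any(abs(volumeAI) >= 2))
    stop("invalid spec: 'volumeAI' must lie strictly inside (-2, 2)")
  if (is.null(blockAssignment))
    blockAssignment <- sort(rep_len(seq_len(kTrue), nSeeds))
  clusterProfiles <- as.matrix(clusterProfiles)
  if (is.null(asymEffects))
    asymEffects <- matrix(1, kTrue, as.integer(nTargets))
  new("SpeciesSpec",
      name = as.character(name),
      nSubjects = as.integer(nSubjects),
      nSeeds = nSeeds,
      nTargets = as.integer(nTargets),
      kTrue = kTrue,
      blockAssignment = as.integer(blockAssignment),
      clusterProfiles = clusterProfiles,
      asymEffects = as.matrix(asymEffects),
      noiseSd = as.numeric(noiseSd),
      scalingExponent = as.numeric(scalingExponent),
      scalingIntercept = as.numeric(scalingIntercept),
      volumeAI = as.numeric(volumeAI),
      gmvRange = as.numeric(gmvRange),
      volumeNoiseSd = as.numeric(volumeNoiseSd))
}

## Shared geometry of the three presets: 60 seeds in 4 contiguous blocks of
## 15, 300 targets.  Each cluster owns a 60-target high-connectivity band
## (value 80); targets 281:300 are a shared "anchor" carrying the global
## maximum (160) in every cluster so that per-hemisphere max-normalization
## uses the same reference and planted multiplicative effects never move the
## matrix maximum.  Baseline connectivity is 2.
.presetGeometry <- function() {
  nSeeds <- 60L; nTargets <- 300L; kTrue <- 4L
  profiles <- matrix(2, kTrue, nTargets)
  bands <- lapply(seq_len(kTrue), function(c) ((c - 1L) * 60L + 1L):(c * 60L))
  for (c in seq_len(kTrue)) profiles[c, bands[[c]]] <- 80
  profiles[, 281:300] <- 160
  list(nSeeds = nSeeds, nTargets = nTargets, kTrue = kTrue,
       profiles = profiles, bands = bands)
}

#' Shipped species-like simulation presets
#'
#' Three ready-made \linkS4class{SpeciesSpec} fixtures that mirror the
#' qualitative cross-species pattern the pipeline is designed to detect:
#' \describe{
#'   \item{\code{"macaque-like"}}{8 subjects; no connectional asymmetry
#'     (all effects 1) and no volumetric asymmetry — the null species.}
#'   \item{\code{"chimp-like"}}{27 subjects; a small number of asymmetric
#'     connections (18 targets across three clusters) and an
#'     anterior-leftward / posterior-rightward volumetric AI pattern
#'     (-0.12, -0.10, +0.10, +0.12).}
#'   \item{\code{"human-like"}}{40 subjects; widespread asymmetric
#'     connections (75 targets across all four clusters, stronger effects)
#'     and the same anterior-negative / posterior-positive volumetric sign
#'     pattern (-0.15, -0.10, +0.10, +0.15).}
#' }
#' All presets share the same planted 4-cluster seed geometry (60 seeds,
#' 300 targets) and positive-allometry exponents (1.15, 1.20, 1.25, 1.30),
#' so the parcellation and allometric stages are directly comparable across
#' species.  Connectional effects are placed inside each cluster's
#' high-connectivity band so they survive population-map thresholding.
#'
#' @param name one of \code{"macaque-like"}, \code{"chimp-like"},
#'   \code{"human-like"}.
#' @return a \linkS4class{SpeciesSpec}.
#' @examples
#' presetSpec("macaque-like")
#' @export
presetSpec <- function(name = c("macaque-like", "chimp-like", "human-like")) {
  name <- match.arg(name)
  g <- .presetGeometry()
  eff <- matrix(1, g$kTrue, g$nTargets)
  exponents <- c(1.15, 1.20, 1.25, 1.30)
  ## intercepts put a human-sized cohort's subregion volumes near 3000 mm^3
  intercepts <- log(3000) - exponents * log(650000)
  if (name == "macaque-like") {
    spec <- SpeciesSpec(name, nSubjects = 8, nSeeds = g$nSeeds,
                        nTargets = g$nTargets, kTrue = g$kTrue,
                        clusterProfiles = g$profiles, asymEffects = eff,
                        noiseSd = 10,
                        scalingExponent = exponents,
                        scalingIntercept = intercepts,
                        volumeAI = c(0, 0, 0, 0),
                        gmvRange = c(45e3, 65e3), volumeNoiseSd = 0.03)
  } else if (name == "chimp-like") {
    eff[1, g$bands[[1]][11:18]] <- 0.80   # leftward, 8 targets
    eff[2, g$bands[[2]][11:14]] <- 1.25   # rightward, 4 targets
    eff[3, g$bands[[3]][11:16]] <- 0.80   # leftward, 6 targets
    spec <- SpeciesSpec(name, nSubjects = 27, nSeeds = g$nSeeds,
                        nTargets = g$nTargets, kTrue = g$kTrue,
                        clusterProfiles = g$profiles, asymEffects = eff,
                        noiseSd = 10,
                        scalingExponent = exponents,
                        scalingIntercept = intercepts,
                        volumeAI = c(-0.12, -0.10, 0.10, 0.12),
                        gmvRange = c(150e3, 220e3), volumeNoiseSd = 0.03)
  } else {
    eff[1, g$bands[[1]][11:30]] <- 0.75   # leftward, 20 targets
    eff[2, g$bands[[2]][11:30]] <- 0.75   # leftward, 20 targets
    eff[3, g$bands[[3]][11:22]] <- 0.75   # leftward, 12 targets
    eff[3, g$bands[[3]][31:38]] <- 1.30   # rightward, 8 targets
    eff[4, g$bands[[4]][11:25]] <- 0.75   # leftward, 15 targets
    spec <- SpeciesSpec(name, nSubjects = 40, nSeeds = g$nSeeds,
                        nTargets = g$nTargets, kTrue = g$kTrue,
                        clusterProfiles = g$profiles, asymEffects = eff,
                        noiseSd = 10,
                        scalingExponent = exponents,
                        scalingIntercept = intercepts,
                        volumeAI = c(-0.15, -0.10, 0.10, 0.15),
                        gmvRange = c(550e3, 750e3), volumeNoiseSd = 0.03)
  }
  spec
}

#' Read / write a SpeciesSpec as YAML or JSON
#'
#' Round-trip serialization of a \linkS4class{SpeciesSpec}; matrices are
#' stored row-major as nested lists.  The format is chosen from the file
#' extension (\code{.yaml}/\code{.yml} or \code{.json}).
#'
#' @param spec a \linkS4class{SpeciesSpec}.
#' @param path file path.
#' @return \code{readSpeciesSpec()} returns a \linkS4class{SpeciesSpec};
#'   \code{writeSpeciesSpec()} returns \code{path} invisibly.
#' @export
writeSpeciesSpec <- function(spec, path) {
  stopifnot(is(spec, "SpeciesSpec"))
  x <- list(
    name = spec@name, n_subjects = spec@nSubjects, n_seeds = spec@nSeeds,
    n_targets = spec@nTargets, k_true = spec@kTrue,
    block_assignment = spec@blockAssignment,
    cluster_profiles = apply(spec@clusterProfiles, 1, identity,
                             simplify = FALSE),
    asym_effects = apply(spec@asymEffects, 1, identity, simplify = FALSE),
    noise_sd = spec@noiseSd,
    scaling_exponent = spec@scalingExponent,
    scaling_intercept = spec@scalingIntercept,
    volume_ai = spec@volumeAI,
    gmv_range = spec@gmvRange,
    volume_noise_sd = spec@volumeNoiseSd)
  if (grepl("\\.ya?ml$", path))
    yaml::write_yaml(x, path)
  else
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSpeciesSpec
#' @export
readSpeciesSpec <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  toMat <- function(rows) do.call(rbind, lapply(rows, unlist))
  SpeciesSpec(
    name = x$name, nSubjects = x$n_subjects, nSeeds = x$n_seeds,
    nTargets = x$n_targets, kTrue = x$k_true,
    blockAssignment = unlist(x$block_assignment),
    clusterProfiles = toMat(x$cluster_profiles),
    asymEffects = toMat(x$asym_effects),
    noiseSd = x$noise_sd,
    scalingExponent = unlist(x$scaling_exponent),
    scalingIntercept = unlist(x$scaling_intercept),
    volumeAI = unlist(x$volume_ai),
    gmvRange = unlist(x$gmv_range),
    volumeNoiseSd = x$volume_noise_sd)
}
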