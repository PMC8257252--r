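## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single numeric RNG seed is required")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate bihemispheric connectivity matrices
#'
#' Draws, for every subject and hemisphere, a seed-by-target connectivity
#' matrix emulating probabilistic-tractography output.  Row \code{i} is its
#' cluster's mean fingerprint plus additive Gaussian noise truncated at
#' zero; right-hemisphere rows are then multiplied element-wise by their
#' cluster's planted asymmetry effects, so with zero noise the right row is
#' exactly \code{effect x left row}.  Seed index \code{i} on the left
#' corresponds to mirrored index \code{i} on the right; no geometry is
#' simulated.  Identical \code{(spec, seed)} reproduce the dataset
#' bit-identically.
#'
#' @param spec a \linkS4class{SpeciesSpec}.
#' @param seed integer RNG seed.
#' @return a \linkS4class{ConnAsymExperiment} (without volumes; see
#'   [simulateDataset()] for the full dataset).
#' @examples
#' sp <- presetSpec("macaque-like")
#' ds <- generateConnectivity(sp, seed = 1)
#' @export
generateConnectivity <- function(spec, seed) {
  stopifnot(is(spec, "SpeciesSpec"))
  validObject(spec)
  M <- spec@nSeeds; N <- spec@nTargets
  mu <- spec@clusterProfiles[spec@blockAssignment, , drop = FALSE]
  effRows <- spec@asymEffects[spec@blockAssignment, , drop = FALSE]
  subj <- sprintf("s%02d", seq_len(spec@nSubjects))
  assays <- withSeed(seed, {
    out <- list()
    for (s in subj) {
      L <- pmax(mu + matrix(stats::rnorm(M * N, sd = spec@noiseSd), M, N), 0)
      R <- pmax(mu + matrix(stats::rnorm(M * N, sd = spec@noiseSd), M, N), 0) *
        effRows
      out[[paste0(s, "_L")]] <- L
      out[[paste0(s, "_R")]] <- R
    }
    out
  })
  rn <- sprintf("seed%03d", seq_len(M))
  cn <- sprintf("t%03d", seq_len(N))
  assays <- lapply(assays, function(a) { dimnames(a) <- list(rn, cn); a })
  se <- SummarizedExperiment(
    assays = assays,
    rowData = DataFrame(seed_id = seq_len(M) - 1L,
                        true_label = spec@blockAssignment,
                        row.names = rn),
    colData = DataFrame(target_id = seq_len(N) - 1L, row.names = cn))
  metadata(se)$spec <- spec
  metadata(se)$seed <- as.integer(seed)
  metadata(se)$normalized <- FALSE
  metadata(se)$groundTruth <- list(
    labels = spec@blockAssignment,
    asymEffects = spec@asymEffects,
    scalingExponent = spec@scalingExponent,
    scalingIntercept = spec@scalingIntercept,
    volumeAI = spec@volumeAI)
  new("ConnAsymExperiment", se)
}

#' Simulate total and subregion volumes with planted allometry
#'
#' Per subject the total gray-matter volume (GMV) is drawn log-uniformly in
#' \code{gmvRange}; each subregion's bilateral mean volume follows the power
#' law \code{exp(intercept) * GMV^exponent}, split between hemispheres so
#' that the asymmetry index \code{2 (R - L) / (R + L)} equals the planted
#' \code{volumeAI} exactly before noise.  Independent lognormal noise
#' (\code{volumeNoiseSd}, log scale) is then applied to each hemisphere, so
#' the observed per-subject AI fluctuates around the planted value; with
#' \code{volumeNoiseSd = 0} the planted power law and AI are recovered
#' exactly.
#'
#' @param spec a \linkS4class{SpeciesSpec}.
#' @param seed integer RNG seed.
#' @return a data.frame with columns \code{subject}, \code{gmv},
#'   \code{subregion}, \code{left_vol}, \code{right_vol} (volumes in mm^3).
#' @examples
#' vols <- generateVolumes(presetSpec("chimp-like"), seed = 1)
#' head(vols)
#' @export
generateVolumes <- function(spec, seed) {
  stopifnot(is(spec, "SpeciesSpec"))
  validObject(spec)
  if (any(spec@scalingExponent <= 0))
    stop("invalid spec: scaling exponents must be positive")
  n <- spec@nSubjects; k <- spec@kTrue
  subj <- sprintf("s%02d", seq_len(n))
  withSeed(seed, {
    gmv <- exp(stats::runif(n, log(spec@gmvRange[1]), log(spec@gmvRange[2])))
    rows <- vector("list", n * k)
    idx <- 1L
    for (s in seq_len(n)) {
      for (c in seq_len(k)) {
        vbar <- exp(spec@scalingIntercept[c]) * gmv[s]^spec@scalingExponent[c]
        ai <- spec@volumeAI[c]
        L <- vbar * (1 - ai / 2)
        R <- vbar * (1 + ai / 2)
        if (spec@volumeNoiseSd > 0) {
          L <- L * exp(stats::rnorm(1, sd = spec@volumeNoiseSd))
          R <- R * exp(stats::rnorm(1, sd = spec@volumeNoiseSd))
        }
        rows[[idx]] <- data.frame(subject = subj[s], gmv = gmv[s],
                                  subregion = c, left_vol = L,
                                  right_vol = R)
        idx <- idx + 1L
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a complete synthetic dataset
#'
#' Runs [generateConnectivity()] and [generateVolumes()] for one species
#' spec and bundles connectivity, volumes and ground truth into a single
#' \linkS4class{ConnAsymExperiment}.  Volumes are drawn from an independent
#' RNG stream seeded with \code{seed + 1}, so the connectivity matrices
#' are identical to a bare \code{generateConnectivity(spec, seed)} call.
#'
#' @param spec a \linkS4class{SpeciesSpec}.
#' @param seed integer RNG seed.
#' @return a \linkS4class{ConnAsymExperiment} with \code{volumeTable()}
#'   populated.
#' @examples
#' ds <- simulateDataset(presetSpec("macaque-like"), seed = 7)
#' ds
#' @export
simulateDataset <- function(spec, seed) {
  ds <- generateConnectivity(spec, seed)
  metadata(ds)$volumes <- generateVolumes(spec, as.integer(seed) + 1L)
  ds
}

#' Write / read a synthetic dataset as plain-text files
#'
#' The on-disk layout is one TSV per subject-hemisphere
#' (\code{connectivity_<subject>_<hemi>.tsv}; rows = seeds, columns =
#' targets, header row of target ids), one \code{volumes.tsv} (subject,
#' gmv, subregion, left_vol, right_vol) and one \code{ground_truth.json}.
#' \code{readDataset()} reconstructs a \linkS4class{ConnAsymExperiment}
#' from such a directory (without the original \linkS4class{SpeciesSpec}).
#'
#' @param ds a \linkS4class{ConnAsymExperiment}.
#' @param dir output directory (created if missing).
#' @return \code{writeDataset()} returns \code{dir} invisibly;
#'   \code{readDataset()} returns a \linkS4class{ConnAsymExperiment}.
#' @export
writeDataset <- function(ds, dir) {
  stopifnot(is(ds, "ConnAsymExperiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in assayNames(ds)) {
    f <- file.path(dir, paste0("connectivity_", nm, ".tsv"))
    utils::write.table(format(assay(ds, nm), digits = 15, trim = TRUE,
                              scientific = FALSE),
                       f, sep = "\t", quote = FALSE, col.names = NA)
  }
  vols <- volumeTable(ds)
  if (!is.null(vols))
    utils::write.table(vols, file.path(dir, "volumes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  gt <- metadata(ds)$groundTruth
  if (!is.null(gt))
    jsonlite::write_json(
      list(labels = gt$labels,
           asym_effects = apply(gt$asymEffects, 1, identity,
                                simplify = FALSE),
           scaling_exponent = gt$scalingExponent,
           scaling_intercept = gt$scalingIntercept,
           volume_ai = gt$volumeAI,
           seed = datasetSeed(ds)),
      file.path(dir, "ground_truth.json"), digits = NA)
  invisible(dir)
}

#' @rdname writeDataset
#' @export
readDataset <- function(dir) {
  files <- sort(list.files(dir, pattern = "^connectivity_.*\\.tsv$"))
  if (!length(files)) stop("no connectivity TSV files found in ", dir)
  assays <- lapply(files, function(f) {
    m <- as.matrix(utils::read.delim(file.path(dir, f), row.names = 1,
                                     check.names = FALSE))
    storage.mode(m) <- "double"
    m
  })
  names(assays) <- sub("^connectivity_(.*)\\.tsv$", "\\1", files)
  se <- SummarizedExperiment(assays = assays)
  md <- list(normalized = FALSE)
  vf <- file.path(dir, "volumes.tsv")
  if (file.exists(vf)) md$volumes <- utils::read.delim(vf)
  gf <- file.path(dir, "ground_truth.json")
  if (file.exists(gf)) {
    gt <- jsonlite::read_json(gf, simplifyVector = TRUE)
    md$groundTruth <- list(
      labels = as.integer(gt$labels),
      asymEffects = if (!is.null(gt$asym_effects))
        do.call(rbind, lapply(gt$asym_effects, unlist)),
      scalingExponent = gt$scaling_exponent,
      scalingIntercept = gt$scaling_intercept,
      volumeAI = gt$volume_ai)
    md$seed <- gt$seed
  }
  metadata(se) <- md
  new("ConnAsymExperiment", se)
}
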