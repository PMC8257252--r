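#' Default pipeline configuration
#'
#' A complete, validated configuration for [runPipeline()]: the three
#' shipped species-like presets, per-species simulation seeds and
#' population-map thresholds (0.5 / 0.2 / 0.3 on the normalized scale for
#' the human-, chimp- and macaque-like cohorts), the cluster-number scan
#' settings (k = 2..12, tau = 0.8), and the statistics settings.  Every
#' RNG consumer has an explicit seed; the whole pipeline is a pure
#' function of this list.
#'
#' @param outputDir directory for all artifacts.
#' @param baseSeed integer; per-stage seeds are small offsets of it.
#' @param nPerm sign-flip permutations at the vertex level.
#' @param kRange candidate cluster numbers.
#' @param tau cross-group consistency threshold.
#' @return a configuration list (round-trips losslessly through YAML).
#' @export
defaultPipelineConfig <- function(outputDir = "connasym-output",
                                  baseSeed = 20L, nPerm = 2000L,
                                  kRange = 2:12, tau = 0.8) {
  baseSeed <- as.integer(baseSeed)
  list(
    output_dir = outputDir,
    species = list(
      list(name = "macaque-like", preset = "macaque-like",
           seed = baseSeed + 1L, threshold = 0.3),
      list(name = "chimp-like", preset = "chimp-like",
           seed = baseSeed + 2L, threshold = 0.2),
      list(name = "human-like", preset = "human-like",
           seed = baseSeed + 3L, threshold = 0.5)),
    processing = list(smooth_rounds = 0L),
    parcellation = list(k_min = min(kRange), k_max = max(kRange),
                        tau = tau, seed = baseSeed + 10L,
                        affinity = "shift"),
    stats = list(alpha = 0.05, n_perm = as.integer(nPerm),
                 seed = baseSeed + 20L, zero_policy = "discard",
                 family_multiplier = 1L, n_rois = 11L, n_tracts = 7L),
    allometry = list(mode = "species-means"))
}

#' Read / write a pipeline configuration
#'
#' @param path YAML (or JSON) file.
#' @param config configuration list.
#' @return \code{readPipelineConfig()} returns the validated configuration
#'   list; \code{writePipelineConfig()} returns \code{path} invisibly.
#' @export
readPipelineConfig <- function(path) {
  config <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
            else jsonlite::read_json(path, simplifyVector = TRUE)
  validatePipelineConfig(config)
  config
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(config, path)
  else jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Validate a pipeline configuration before any computation
#'
#' Checks structure, ranges and — critically for reproducibility — that
#' every RNG consumer (each species simulation, the parcellation k-means,
#' the permutation tests) carries an explicit seed.
#'
#' @param config configuration list.
#' @return \code{TRUE} invisibly; otherwise an error describing the defect.
#' @export
validatePipelineConfig <- function(config) {
  fail <- function(...) stop("invalid pipeline config: ", ..., call. = FALSE)
  if (is.null(config$output_dir)) fail("'output_dir' is missing")
  if (is.null(config$species) || !length(config$species))
    fail("'species' must list at least one cohort")
  for (sp in config$species) {
    if (is.null(sp$name)) fail("a species entry has no 'name'")
    if (is.null(sp$seed)) fail("species '", sp$name, "' has no RNG seed")
    if (is.null(sp$preset) && is.null(sp$spec_file))
      fail("species '", sp$name, "' needs 'preset' or 'spec_file'")
    if (is.null(sp$threshold) || sp$threshold < 0)
      fail("species '", sp$name, "' needs a non-negative 'threshold'")
  }
  pc <- config$parcellation
  if (is.null(pc$seed)) fail("parcellation has no RNG seed")
  if (is.null(pc$k_min) || is.null(pc$k_max) || pc$k_min < 2 ||
      pc$k_max < pc$k_min)
    fail("parcellation k range must satisfy 2 <= k_min <= k_max")
  if (is.null(pc$tau) || pc$tau < 0 || pc$tau > 1)
    fail("parcellation 'tau' must lie in [0, 1]")
  st <- config$stats
  if (is.null(st$seed)) fail("stats has no RNG seed")
  if (is.null(st$alpha) || st$alpha <= 0 || st$alpha >= 1)
    fail("stats 'alpha' must lie in (0, 1)")
  if (is.null(st$n_perm) || st$n_perm < 1) fail("stats 'n_perm' must be >= 1")
  invisible(TRUE)
}

#' Evenly split targets into contiguous region sets
#'
#' Stand-in region definitions (ROIs or tracts) over the synthetic target
#' axis: \code{n} contiguous, non-overlapping index sets covering all
#' targets.
#'
#' @param nTargets number of targets.
#' @param n number of regions.
#' @param prefix region-name prefix.
#' @return named list of integer index sets.
#' @export
defaultRegionSets <- function(nTargets, n, prefix = "roi") {
  n <- min(as.integer(n), as.integer(nTargets))
  sets <- unname(split(seq_len(nTargets),
                       cut(seq_len(nTargets), n, labels = FALSE)))
  names(sets) <- sprintf("%s%02d", prefix, seq_len(n))
  sets
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full simulate -> process -> parcellate -> test pipeline
#'
#' Orchestrates the whole analysis as a pure function of its
#' configuration: simulates every configured species cohort, normalizes the
#' profiles, builds per-species-hemisphere group similarity matrices, scans
#' the cluster number across all groups and parcellates at the chosen k,
#' runs the asymmetry battery (volumetric, vertex, ROI and tract levels)
#' per species, and fits the pooled allometric scaling table.  All
#' intermediate artifacts are written as TSV/JSON under
#' \code{config$output_dir}, together with a \code{pipeline_log.tsv} (one
#' line per stage: parameters, seed, output checksum) and a
#' \code{summary.json}.  Re-running with the same configuration reproduces
#' byte-identical outputs.
#'
#' @param config configuration list (see [defaultPipelineConfig()]).
#' @return (invisibly) a report list: \code{chosenK}, \code{kScan},
#'   \code{parcellations}, \code{asymmetry} (one tidy table),
#'   \code{significantCounts}, \code{allometry}, \code{outputDir}.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  validatePipelineConfig(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  logLines <- character()
  addLog <- function(stage, params, files) {
    sums <- paste(sprintf("%s=%s", basename(files),
                          unname(tools::md5sum(files))), collapse = ",")
    logLines <<- c(logLines, paste(stage, params, sums, sep = "\t"))
  }

  ## simulate + normalize ---------------------------------------------------
  datasets <- list()
  for (sp in config$species) {
    ds <- .stage(paste0("simulate:", sp$name), {
      spec <- if (!is.null(sp$preset)) presetSpec(sp$preset)
              else readSpeciesSpec(sp$spec_file)
      simulateDataset(spec, sp$seed)
    })
    d <- file.path(config$output_dir, "datasets", sp$name)
    writeDataset(ds, d)
    addLog(paste0("simulate:", sp$name), paste0("seed=", sp$seed),
           list.files(d, full.names = TRUE)[1:2])
    datasets[[sp$name]] <- normalizeProfile(ds)
  }

  ## group similarities per species x hemisphere ----------------------------
  groupSims <- .stage("similarity", {
    out <- list()
    for (nm in names(datasets)) {
      ds <- datasets[[nm]]
      for (h in c("L", "R")) {
        subs <- lapply(subjectIds(ds), function(s)
          seedSimilarity(assay(ds, paste0(s, "_", h))))
        out[[paste0(nm, "_", h)]] <- groupSimilarity(subs)
      }
    }
    out
  })

  ## k scan + parcellation ---------------------------------------------------
  pc <- config$parcellation
  scan <- .stage("scan-k",
    scanK(groupSims, kRange = seq(pc$k_min, pc$k_max), tau = pc$tau,
          seed = pc$seed,
          affinity = if (is.null(pc$affinity)) "shift" else pc$affinity))
  f <- file.path(config$output_dir, "k_scan.tsv")
  writeParcellation(scan, f)
  addLog("scan-k", sprintf("tau=%s seed=%d", pc$tau, pc$seed), f)

  parcs <- .stage("parcellate", {
    out <- list()
    for (nm in names(groupSims)) {
      out[[nm]] <- spectralParcellate(groupSims[[nm]], chosenK(scan),
                                      seed = pc$seed)
      f <- file.path(config$output_dir,
                     paste0("parcellation_", nm, ".tsv"))
      writeParcellation(out[[nm]], f)
    }
    out
  })

  ## asymmetry battery per species -------------------------------------------
  st <- config$stats
  tables <- list()
  for (sp in config$species) {
    ds <- datasets[[sp$name]]
    nT <- ncol(ds)
    tab <- .stage(paste0("asymmetry:", sp$name),
      runAsymmetryBattery(
        ds,
        parcellation = parcs[[paste0(sp$name, "_L")]],
        roiSets = defaultRegionSets(nT, st$n_rois, "roi"),
        tractSets = defaultRegionSets(nT, st$n_tracts, "tract"),
        config = batteryConfig(
          alpha = st$alpha, nPerm = st$n_perm, seed = st$seed,
          threshold = sp$threshold,
          smoothRounds = config$processing$smooth_rounds,
          zeroPolicy = st$zero_policy,
          familyMultiplier = st$family_multiplier)))
    f <- file.path(config$output_dir,
                   paste0("asymmetry_", sp$name, ".tsv"))
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    addLog(paste0("asymmetry:", sp$name),
           sprintf("alpha=%s n_perm=%d seed=%d", st$alpha, st$n_perm,
                   st$seed), f)
    tables[[sp$name]] <- tab
  }
  asym <- do.call(rbind, c(tables, list(make.row.names = FALSE)))

  ## allometry ---------------------------------------------------------------
  allo <- .stage("allometry",
    allometryTable(lapply(datasets, volumeTable),
                   mode = config$allometry$mode))
  f <- file.path(config$output_dir, "allometry_fits.tsv")
  utils::write.table(allo$fits, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(allo$comparison,
                     file.path(config$output_dir,
                               "allometry_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  addLog("allometry", paste0("mode=", config$allometry$mode), f)

  ## summary + log -----------------------------------------------------------
  counts <- do.call(rbind, lapply(split(asym, asym[c("species", "level")]),
    function(d) data.frame(species = d$species[1], level = d$level[1],
                           n_significant = sum(d$significant),
                           n_tested = nrow(d))))
  counts <- counts[order(counts$species, counts$level), ]
  rownames(counts) <- NULL
  summary <- list(
    package_version = as.character(utils::packageVersion("connAsym")),
    chosen_k = chosenK(scan),
    reached_tau = scan@reachedTau,
    k_scores = as.list(scanScores(scan)),
    significant_counts = counts,
    allometry_slopes = allo$fits$slope)
  jsonlite::write_json(summary, file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(c("stage\tparams\tchecksums", logLines),
             file.path(config$output_dir, "pipeline_log.tsv"))
  invisible(list(chosenK = chosenK(scan), kScan = scan,
                 parcellations = parcs, asymmetry = asym,
                 significantCounts = counts, allometry = allo,
                 outputDir = config$output_dir))
}
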