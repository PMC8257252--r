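test_that("identical spec and seed reproduce the dataset bit-identically", {
  sp <- tinySpec(noiseSd = 2)
  d1 <- simulateDataset(sp, 11)
  d2 <- simulateDataset(sp, 11)
  for (nm in assayNames(d1))
    expect_identical(assay(d1, nm), assay(d2, nm))
  expect_identical(volumeTable(d1), volumeTable(d2))
  d3 <- simulateDataset(sp, 12)
  expect_false(identical(assay(d1, "s01_L"), assay(d3, "s01_L")))
})

test_that("noise-free symmetric generation gives identical hemispheres and block rows", {
  ds <- generateConnectivity(tinySpec(noiseSd = 0), 1)
  L <- assay(ds, "s01_L"); R <- assay(ds, "s01_R")
  expect_identical(L, R)
  lab <- trueLabels(ds)
  for (c in 1:2) {
    rows <- L[lab == c, , drop = FALSE]
    expect_true(all(rows == rep(rows[1, ], each = nrow(rows))))
  }
})

test_that("planted multiplicative effects scale right-hemisphere rows exactly", {
  eff <- matrix(1, 2, 8); eff[1, ] <- 1.5
  ds <- generateConnectivity(tinySpec(noiseSd = 0, asymEffects = eff), 1)
  L <- assay(ds, "s02_L"); R <- assay(ds, "s02_R")
  lab <- trueLabels(ds)
  expect_equal(R[lab == 1, ], 1.5 * L[lab == 1, ])
  expect_equal(R[lab == 2, ], L[lab == 2, ])
})

test_that("noise-free volumes follow the planted power law and AI exactly", {
  sp <- tinySpec(volumeAI = c(0.5, 0), scalingExponent = c(1.2, 1),
                 scalingIntercept = c(log(2), log(3)),
                 gmvRange = c(1000, 1000))
  v <- generateVolumes(sp, 3)
  v1 <- v[v$subregion == 1, ]
  v2 <- v[v$subregion == 2, ]
  ## bilateral mean = 2 * 1000^1.2; AI = 0.5 reproduced by the formula
  expect_equal((v1$left_vol + v1$right_vol) / 2,
               rep(2 * 1000^1.2, nrow(v1)))
  expect_equal(asymmetryIndex(v1$left_vol, v1$right_vol),
               rep(0.5, nrow(v1)))
  expect_equal(v2$left_vol, v2$right_vol)
  expect_equal(v2$left_vol, rep(3 * 1000, nrow(v2)))
})

test_that("invalid specs are rejected before any computation", {
  expect_error(SpeciesSpec("bad", 2, nSeeds = 3, nTargets = 4, kTrue = 5,
                           clusterProfiles = matrix(1, 5, 4)),
               "kTrue")
  expect_error(tinySpec(noiseSd = -1), "noiseSd")
  expect_error(tinySpec(volumeAI = c(2.5, 0)), "volumeAI")
})

test_that("per-cluster sample means converge to the planted profiles", {
  sp <- tinySpec(nSubjects = 200, noiseSd = 2)
  ds <- generateConnectivity(sp, 99)
  lab <- trueLabels(ds)
  mu <- speciesSpec(ds)@clusterProfiles
  ## grand mean over subjects and cluster seeds, per target
  for (c in 1:2) {
    vals <- sapply(subjectIds(ds), function(s)
      colMeans(assay(ds, paste0(s, "_L"))[lab == c, , drop = FALSE]))
    est <- rowMeans(vals)
    se <- apply(vals, 1, stats::sd) / sqrt(ncol(vals))
    ## truncation at zero biases targets near zero upward; check the
    ## well-separated targets (mean >> noise sd)
    big <- mu[c, ] >= 9
    expect_true(all(abs(est - mu[c, ])[big] <= 3 * se[big] + 1e-9))
  }
})

test_that("datasets round-trip through the TSV/JSON layout", {
  sp <- tinySpec(nSubjects = 2, noiseSd = 1, volumeNoiseSd = 0.05)
  ds <- simulateDataset(sp, 5)
  dir <- withr::local_tempdir()
  writeDataset(ds, dir)
  back <- readDataset(dir)
  expect_setequal(assayNames(back), assayNames(ds))
  for (nm in assayNames(ds))
    expect_equal(unname(assay(back, nm)), unname(assay(ds, nm)),
                 tolerance = 1e-12)
  expect_equal(back@metadata$groundTruth$labels, trueLabels(ds))
  expect_equal(volumeTable(back)$left_vol, volumeTable(ds)$left_vol,
               tolerance = 1e-12)
})

test_that("species spec round-trips through YAML", {
  sp <- presetSpec("chimp-like")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeSpeciesSpec(sp, f)
  back <- readSpeciesSpec(f)
  expect_equal(back@clusterProfiles, sp@clusterProfiles)
  expect_equal(back@asymEffects, sp@asymEffects)
  expect_equal(back@volumeAI, sp@volumeAI)
  expect_identical(back@nSubjects, sp@nSubjects)
})
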