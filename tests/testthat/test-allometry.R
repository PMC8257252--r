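test_that("noise-free power laws are recovered exactly", {
  g <- c(1e3, 1e4, 1e5)
  fit <- suppressWarnings(allometricFit(2 * g^1.2, g))
  expect_equal(fit@slope, 1.2, tolerance = 1e-12)
  expect_equal(fit@intercept, log(2), tolerance = 1e-10)
  expect_equal(fit@rSquared, 1, tolerance = 1e-12)
  ## proportional volumes: isometry
  expect_equal(suppressWarnings(allometricFit(0.1 * g, g))@slope, 1,
               tolerance = 1e-12)
})

test_that("slope is invariant to positive rescaling of either variable", {
  set.seed(2)
  g <- exp(runif(30, 10, 12))
  v <- 0.5 * g^1.3 * exp(rnorm(30, sd = 0.1))
  f0 <- allometricFit(v, g)
  expect_equal(allometricFit(7 * v, g)@slope, f0@slope, tolerance = 1e-12)
  expect_equal(allometricFit(v, 3 * g)@slope, f0@slope, tolerance = 1e-12)
  expect_equal(allometricFit(7 * v, g)@intercept, f0@intercept + log(7),
               tolerance = 1e-10)
})

test_that("degenerate allometry inputs are rejected", {
  expect_error(allometricFit(c(1, 2), c(1, 2)), "3 observations")
  expect_error(allometricFit(c(1, -2, 3), c(1, 2, 3)), "positive")
  expect_error(allometricFit(c(1, 2, 3), c(5, 5, 5)), "constant gmv")
})

test_that("identical hemispheres give a degenerate F = 0 comparison", {
  g <- c(1e3, 3e3, 1e4, 3e4)
  v <- 2 * g^1.1
  w <- testthat::capture_warnings(cmp <- compareSlopes(v, v, g))
  expect_true(any(grepl("degenerate", w)))
  expect_equal(cmp@fStat, 0)
  expect_equal(cmp@pValue, 1)
  expect_true(cmp@degenerate)
})

test_that("slope comparison is symmetric in hemisphere labels and detects differences", {
  set.seed(4)
  g <- exp(runif(50, 10, 13))
  vL <- 0.3 * g^1.1 * exp(rnorm(50, sd = 0.02))
  vR <- 0.3 * g^1.6 * exp(rnorm(50, sd = 0.02))
  cmp <- compareSlopes(vL, vR, g)
  swapped <- compareSlopes(vR, vL, g)
  expect_equal(cmp@pValue, swapped@pValue, tolerance = 1e-12)
  expect_equal(cmp@fStat, swapped@fStat, tolerance = 1e-9)
  expect_lt(cmp@pValue, 1e-6)
  expect_equal(cmp@slopeLeft, swapped@slopeRight)
})

test_that("the pooled allometry table covers both modes and hemispheres", {
  specs <- list(a = tinySpec(nSubjects = 10, gmvRange = c(1e3, 2e3),
                             volumeNoiseSd = 0.02),
                b = tinySpec(nSubjects = 10, gmvRange = c(1e4, 2e4),
                             volumeNoiseSd = 0.02),
                c = tinySpec(nSubjects = 10, gmvRange = c(1e5, 2e5),
                             volumeNoiseSd = 0.02))
  vols <- Map(function(sp, seed) generateVolumes(sp, seed), specs, 1:3)
  tab <- allometryTable(vols, mode = "species-means")
  expect_identical(nrow(tab$fits), 4L)           # 2 subregions x 2 hemis
  expect_identical(tab$fits$n, rep(3L, 4))       # one point per species
  expect_equal(tab$fits$slope, rep(1.2, 4), tolerance = 0.05)
  tabS <- allometryTable(vols, mode = "subjects")
  expect_identical(tabS$fits$n, rep(30L, 4))
  expect_equal(tabS$fits$slope, rep(1.2, 4), tolerance = 0.05)
  expect_identical(nrow(tab$comparison), 2L)
  expect_true(all(tab$comparison$p >= 0 & tab$comparison$p <= 1))
})
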