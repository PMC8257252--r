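#' Allometric log-log scaling fit
#'
#' Ordinary least squares of \code{log(volume)} on \code{log(gmv)} (natural
#' logs; the base cancels in the slope).  The slope is the allometric
#' scaling exponent: 1 is isometry, > 1 positive allometry (disproportionate
#' growth of the part).  The 95\% confidence interval comes from the t
#' distribution of the slope estimate.
#'
#' @param volumes part volumes (mm^3), all > 0, length >= 3.
#' @param gmv total gray-matter volumes (mm^3), same length, non-constant.
#' @return an \linkS4class{AllometryFit}.
#' @examples
#' g <- c(1e3, 1e4, 1e5)
#' allometricFit(2 * g^1.2, g)   # slope 1.2, intercept log(2)
#' @export
allometricFit <- function(volumes, gmv) {
  if (length(volumes) != length(gmv)) stop("input lengths differ")
  if (length(volumes) < 3L) stop("at least 3 observations are required")
  if (any(volumes <= 0) || any(gmv <= 0))
    stop("volumes and gmv must be strictly positive")
  if (stats::sd(gmv) == 0)
    stop("constant gmv: the slope is not identifiable")
  lv <- log(volumes); lg <- log(gmv)
  fit <- stats::lm(lv ~ lg)
  sm <- summary(fit)
  ci <- tryCatch(stats::confint(fit, "lg", level = 0.95),
                 error = function(e) matrix(NA_real_, 1, 2))
  new("AllometryFit",
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      ci95 = as.numeric(ci),
      rSquared = sm$r.squared,
      n = length(volumes),
      residualDf = as.integer(fit$df.residual))
}

#' Compare left and right allometric slopes (ANCOVA)
#'
#' Stacks the two hemispheres into one model
#' \code{log(volume) ~ log(gmv) * hemisphere} and F-tests the interaction
#' term: a small p-value means the scaling slopes differ between
#' hemispheres.  The two hemispheres of the same subjects are treated as
#' independent samples for this test (the plot-level comparison; a
#' documented simplification).  Identical left and right data give F = 0,
#' p = 1 with a degenerate-fit warning, since the residuals are duplicated.
#'
#' @param volL,volR per-subject left / right volumes (> 0).
#' @param gmv per-subject total gray-matter volumes (> 0), shared by both
#'   hemispheres.
#' @return a \linkS4class{SlopeComparison}.
#' @export
compareSlopes <- function(volL, volR, gmv) {
  stopifnot(length(volL) == length(volR), length(volL) == length(gmv))
  fitL <- allometricFit(volL, gmv)
  fitR <- allometricFit(volR, gmv)
  if (identical(as.numeric(volL), as.numeric(volR))) {
    warning("identical left and right volumes: degenerate slope comparison")
    return(new("SlopeComparison", slopeLeft = fitL@slope,
               slopeRight = fitR@slope, fStat = 0, pValue = 1,
               df = c(1, 2 * length(volL) - 4), degenerate = TRUE))
  }
  lv <- log(c(volL, volR)); lg <- log(c(gmv, gmv))
  hemi <- factor(rep(c("L", "R"), each = length(volL)))
  fit <- stats::lm(lv ~ lg * hemi)
  an <- stats::anova(fit)
  new("SlopeComparison",
      slopeLeft = fitL@slope, slopeRight = fitR@slope,
      fStat = an["lg:hemi", "F value"],
      pValue = an["lg:hemi", "Pr(>F)"],
      df = c(an["lg:hemi", "Df"], an["Residuals", "Df"]),
      degenerate = FALSE)
}

#' Pooled cross-species allometry table
#'
#' Fits the log-log scaling of subregion volume against total gray-matter
#' volume pooled across species, per subregion and hemisphere, and tests
#' slope equality between hemispheres.  \code{mode = "species-means"}
#' (default) fits the per-species mean data points, mirroring regression on
#' species averages; \code{mode = "subjects"} pools all individual
#' subjects.  The hemisphere comparison always uses the pooled individual
#' subjects so its F-test has usable degrees of freedom.
#'
#' @param volumesBySpecies named list of volume tables as returned by
#'   [generateVolumes()] (columns subject, gmv, subregion, left_vol,
#'   right_vol).
#' @param mode \code{"species-means"} or \code{"subjects"}.
#' @return list with \code{fits} (data.frame: subregion, hemisphere, slope,
#'   ci_lo, ci_hi, intercept, r_squared, n) and \code{comparison}
#'   (data.frame: subregion, slope_left, slope_right, f, p).
#' @export
allometryTable <- function(volumesBySpecies,
                           mode = c("species-means", "subjects")) {
  mode <- match.arg(mode)
  stopifnot(length(volumesBySpecies) >= 1L)
  all <- do.call(rbind, Map(function(v, nm) cbind(v, species = nm),
                            volumesBySpecies, names(volumesBySpecies)))
  subregions <- sort(unique(all$subregion))
  fits <- list(); comps <- list()
  for (c in subregions) {
    sub <- all[all$subregion == c, ]
    for (h in c("L", "R")) {
      vol <- if (h == "L") sub$left_vol else sub$right_vol
      dat <- data.frame(vol = vol, gmv = sub$gmv, species = sub$species)
      if (mode == "species-means") {
        dat <- do.call(rbind, lapply(split(dat, dat$species), function(d)
          data.frame(vol = mean(d$vol), gmv = mean(d$gmv))))
      }
      f <- allometricFit(dat$vol, dat$gmv)
      fits[[paste(c, h)]] <- data.frame(
        subregion = c, hemisphere = h, slope = f@slope,
        ci_lo = f@ci95[1], ci_hi = f@ci95[2], intercept = f@intercept,
        r_squared = f@rSquared, n = f@n)
    }
    cmp <- compareSlopes(sub$left_vol, sub$right_vol, sub$gmv)
    comps[[as.character(c)]] <- data.frame(
      subregion = c, slope_left = cmp@slopeLeft,
      slope_right = cmp@slopeRight, f = cmp@fStat, p = cmp@pValue)
  }
  list(fits = do.call(rbind, c(fits, list(make.row.names = FALSE))),
       comparison = do.call(rbind, c(comps, list(make.row.names = FALSE))))
}
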