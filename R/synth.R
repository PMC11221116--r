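# Photon-level synthetic AOFLIO generator: Voronoi RPE mosaics on a jittered
# hexagonal lattice, per-cell bi-exponential ground truth with configurable
# eccentricity/age structure, and TCSPC cube rendering with Gaussian IRF and
# independent Poisson noise per pixel per bin.

#' Preset lifetime palettes per spectral channel
#'
#' Plausibility defaults for the synthetic generator (order-of-magnitude
#' values typical of RPE autofluorescence), not fitted estimates: a short
#' component near 130-150 ps dominating in amplitude and a long component
#' near 0.8-1 ns. Cell-to-cell SDs model per-cell granule heterogeneity.
#' Default slopes encode the qualitative in-vivo trends (lifetimes lengthen,
#' a1 falls, with eccentricity and age); all fields can be overridden.
#'
#' @param channel one of `"765/NIR"`, `"532/LSC"`, `"473/LSC"`, `"473/SSC"`.
#' @param ... any [ChannelPalette-class] slot to override.
#' @return A [ChannelPalette-class].
#' @export
channelPalette <- function(channel = "532/LSC", ...) {
  presets <- list(
    "765/NIR" = list(tau1MeanPs = 150, tau2MeanPs = 1000, a1Mean = 0.80),
    "532/LSC" = list(tau1MeanPs = 150, tau2MeanPs = 900,  a1Mean = 0.75),
    "473/LSC" = list(tau1MeanPs = 140, tau2MeanPs = 850,  a1Mean = 0.72),
    "473/SSC" = list(tau1MeanPs = 130, tau2MeanPs = 800,  a1Mean = 0.70))
  if (!channel %in% names(presets))
    stop("unknown channel: ", channel)
  args <- c(list(channel = channel), presets[[channel]],
            list(tau1SdPs = 15, tau2SdPs = 40, a1Sd = 0.02,
                 eccSlopeTau1PsPerDeg = 1.5, eccSlopeTau2PsPerDeg = 10,
                 eccSlopeA1PerDeg = -0.003, ageSlopeTau1PsPerYear = 0.8,
                 ageSlopeTau2PsPerYear = 4, ageSlopeA1PerYear = -0.0008))
  override <- list(...)
  args[names(override)] <- override
  do.call(new, c(list(Class = "ChannelPalette"), args))
}

#' Generate a synthetic RPE mosaic
#'
#' Voronoi tessellation of a jittered hexagonal lattice whose density is set
#' so the mean cell area matches the target; single-pixel borders between
#' neighboring cells are set to label 0, mimicking hand-drawn outlines.
#' Deterministic given the seed.
#'
#' @param spec a [MosaicSpec-class].
#' @param seed RNG seed for the lattice jitter.
#' @return list with `mask` (a [CellMask-class]) and `geometry` (the
#'   [cellGeometry()] table with areas in um^2).
#' @export
generateMosaic <- function(spec = mosaicSpec(), seed = 1L) {
  stopifnot(is(spec, "MosaicSpec"))
  n <- spec@imagePxPerSide
  umPerPx <- (spec@fovDeg / n) * 291 * (spec@axialLengthMm / 24.46)
  areaPx <- spec@targetMeanCellAreaUm2 / umPerPx^2
  # compensate the single-pixel borders: each cell loses about half its
  # boundary (~1.86 * sqrt(site area) pixels) to label 0, so the Voronoi
  # sites are laid out slightly sparser than the interior-area target
  sqrtSite <- (1.86 + sqrt(1.86^2 + 4 * areaPx)) / 2
  a <- sqrt(2 * sqrtSite^2 / sqrt(3))  # hexagonal lattice spacing
  if (a > n / 3)
    stop("target cell area incompatible with image size: fewer than ~9 cells")
  if (areaPx < 16)
    stop("target cell area incompatible with image sampling: ",
         "under 16 pixels per cell at this field of view")
  dy <- a * sqrt(3) / 2
  ri <- seq(floor(-2), ceiling(n / dy) + 2L)      # lattice row indices
  ci <- seq(floor(-2), ceiling(n / a) + 2L)       # lattice column indices
  nR <- length(ri); nC <- length(ci)
  baseY <- matrix(ri * dy, nR, nC)
  baseX <- matrix(rep(ci * a, each = nR), nR, nC) +
    matrix((ri %% 2) * a / 2, nR, nC)
  jit <- spec@jitterFraction * a
  pts <- .withSeed(seed, list(
    y = baseY + matrix(runif(nR * nC, -jit, jit), nR, nC),
    x = baseX + matrix(runif(nR * nC, -jit, jit), nR, nC)))
  pr <- matrix(row(matrix(0, n, n)), n, n)  # pixel rows
  pc <- matrix(col(matrix(0, n, n)), n, n)
  i0 <- pmin(pmax(round(pr / dy) - ri[1L] + 1, 1), nR)
  j0 <- pmin(pmax(round(pc / a) - ci[1L] + 1, 1), nC)
  bestD <- matrix(Inf, n, n)
  bestId <- matrix(0L, n, n)
  for (di in -2:2) for (dj in -2:2) {
    ii <- pmin(pmax(i0 + di, 1L), nR)
    jj <- pmin(pmax(j0 + dj, 1L), nC)
    idx <- (jj - 1L) * nR + ii
    d <- (pts$y[idx] - pr)^2 + (pts$x[idx] - pc)^2
    upd <- d < bestD
    bestD[upd] <- d[upd]
    bestId[upd] <- idx[upd]
  }
  # single-pixel borders: a pixel bordering a different label below or to
  # the right becomes background
  border <- matrix(FALSE, n, n)
  border[-n, ] <- border[-n, ] | (bestId[-n, ] != bestId[-1L, ])
  border[, -n] <- border[, -n] | (bestId[, -n] != bestId[, -1L])
  lab <- bestId
  lab[border] <- 0L
  ids <- sort(unique(lab[lab > 0L]))
  dense <- integer(max(ids))
  dense[ids] <- seq_along(ids)
  lab[lab > 0L] <- dense[lab[lab > 0L]]
  mask <- cellMask(lab)
  meta <- acquisitionMetadata(axialLengthMm = spec@axialLengthMm,
                              fovDeg = spec@fovDeg, imagePxPerSide = n)
  list(mask = mask, geometry = cellGeometry(mask, meta))
}

#' Draw per-cell ground-truth decay parameters
#'
#' Per-cell bi-exponential parameters are drawn from the palette
#' distributions with means shifted linearly by eccentricity and by age
#' (relative to 25 years). Lifetimes are clamped to (10, 12000) ps with
#' `tau1 < tau2` enforced; a1 is clamped to (0.02, 0.98).
#'
#' @param mask a [CellMask-class].
#' @param palette a [ChannelPalette-class].
#' @param eccentricityDeg retinal eccentricity in degrees.
#' @param ageYears subject age in years.
#' @param photonsPerCell expected total photons per cell (presets: 1e4
#'   "bright", 350 "threshold").
#' @param nucleusRadiusFraction radius of the dim nuclear disk as a fraction
#'   of the equivalent cell radius.
#' @param seed RNG seed.
#' @return data.frame (one row per cell): `label`, `tau1_ps`, `tau2_ps`,
#'   `a1`, `photons`, `nucleus_radius_px`, `centroid_row`, `centroid_col`,
#'   `pixel_count`, `eccentricity_deg`, `age_years`.
#' @export
assignCellTruth <- function(mask, palette = channelPalette(),
                            eccentricityDeg = 0, ageYears = 25,
                            photonsPerCell = 5000,
                            nucleusRadiusFraction = 0.3, seed = NULL) {
  stopifnot(is(mask, "CellMask"), is(palette, "ChannelPalette"))
  geo <- cellGeometry(mask)
  ncell <- nrow(geo)
  dAge <- ageYears - 25
  m1 <- palette@tau1MeanPs + palette@eccSlopeTau1PsPerDeg * eccentricityDeg +
    palette@ageSlopeTau1PsPerYear * dAge
  m2 <- palette@tau2MeanPs + palette@eccSlopeTau2PsPerDeg * eccentricityDeg +
    palette@ageSlopeTau2PsPerYear * dAge
  ma <- palette@a1Mean + palette@eccSlopeA1PerDeg * eccentricityDeg +
    palette@ageSlopeA1PerYear * dAge
  draws <- .withSeed(seed, list(
    tau1 = rnorm(ncell, m1, palette@tau1SdPs),
    tau2 = rnorm(ncell, m2, palette@tau2SdPs),
    a1 = rnorm(ncell, ma, palette@a1Sd)))
  tau1 <- pmin(pmax(draws$tau1, 11), 11999)
  tau2 <- pmin(pmax(draws$tau2, 11), 11999)
  tau2 <- pmax(tau2, tau1 + 10)
  data.frame(label = geo$label, tau1_ps = tau1, tau2_ps = tau2,
             a1 = pmin(pmax(draws$a1, 0.02), 0.98),
             photons = photonsPerCell,
             nucleus_radius_px =
               nucleusRadiusFraction * sqrt(geo$pixel_count / pi),
             centroid_row = geo$centroid_row,
             centroid_col = geo$centroid_col,
             pixel_count = geo$pixel_count,
             eccentricity_deg = eccentricityDeg, age_years = ageYears)
}

#' Render a TCSPC cube from a mosaic and its ground truth
#'
#' Each interior pixel of cell k receives the expected bi-exponential decay
#' of that cell's truth, scaled so the expected photons of the whole cell
#' equal `photons`. A central nuclear disk is dimmed by `nucleusFactor`,
#' reproducing the bright-border / dark-interior appearance of RPE cells.
#' Border/background pixels receive background only. Counts are independent
#' Poisson draws per pixel per bin; deterministic given the seed.
#'
#' @param mask a [CellMask-class].
#' @param truths the [assignCellTruth()] table.
#' @param calib a [TimingCalibration-class].
#' @param irfFwhmPs Gaussian IRF FWHM in ps (0 = none).
#' @param backgroundRate expected background counts per pixel per bin.
#' @param nucleusFactor brightness factor inside the nuclear disk.
#' @param scanDirection stored in the cube.
#' @param seed RNG seed.
#' @return A [HistogramCube-class].
#' @export
renderCube <- function(mask, truths, calib = timingCalibration(),
                       irfFwhmPs = 120, backgroundRate = 0,
                       nucleusFactor = 0.3, scanDirection = "combined",
                       seed = NULL) {
  stopifnot(is(mask, "CellMask"), is(calib, "TimingCalibration"))
  lab <- maskLabels(mask)
  n <- nrow(lab); m <- ncol(lab); B <- calib@nBins
  shapes <- t(vapply(seq_len(nrow(truths)), function(i)
    modelDecay(calib, truths$tau1_ps[i], truths$tau2_ps[i],
               photonFraction(truths$a1[i], truths$tau1_ps[i],
                              truths$tau2_ps[i]),
               totalCounts = 1, irfFwhmPs = irfFwhmPs), numeric(B)))
  cellIdx <- match(lab, truths$label)      # NA for background
  pix <- which(!is.na(cellIdx))
  ci <- cellIdx[pix]
  pr <- ((pix - 1L) %% n) + 1L
  pc <- ((pix - 1L) %/% n) + 1L
  d2 <- (pr - truths$centroid_row[ci])^2 + (pc - truths$centroid_col[ci])^2
  wpx <- ifelse(d2 <= truths$nucleus_radius_px[ci]^2, nucleusFactor, 1)
  wsum <- as.numeric(rowsum(wpx, ci, reorder = TRUE))
  wsum_by_cell <- numeric(nrow(truths))
  wsum_by_cell[sort(unique(ci))] <- wsum
  rate <- truths$photons[ci] * wpx / wsum_by_cell[ci]
  lambda <- rate * shapes[ci, , drop = FALSE]   # pixels x bins
  countsArr <- .withSeed(seed, {
    flat <- matrix(0L, n * m, B)
    flat[pix, ] <- rpois(length(lambda), lambda)
    if (backgroundRate > 0) {
      bg <- which(is.na(cellIdx))
      flat[bg, ] <- rpois(length(bg) * B, backgroundRate)
      flat[pix, ] <- flat[pix, ] + rpois(length(lambda), backgroundRate)
    }
    array(flat, c(n, m, B))
  })
  histogramCube(countsArr, calib, scanDirection)
}

#' Simulate a forward/backward scan pair or a two-visit pair
#'
#' Two independent Poisson realizations of the same per-cell ground truth.
#' In `"forward_backward"` mode the cubes differ only in noise realization
#' and scan-direction tag. In `"test_retest"` mode the second visit may
#' additionally carry a small mask shift (returned as `mask2`) and a global
#' brightness factor.
#'
#' @param mask a [CellMask-class].
#' @param truths the [assignCellTruth()] table.
#' @param calib a [TimingCalibration-class].
#' @param mode `"forward_backward"` or `"test_retest"`.
#' @param seeds two RNG seeds, one per realization.
#' @param retestShift integer (dRow, dCol) mask shift for visit 2.
#' @param retestBrightness brightness factor for visit 2.
#' @param ... passed on to [renderCube()].
#' @return list with `cube1`, `cube2`, `mask1`, `mask2`.
#' @export
simulateVisitPair <- function(mask, truths, calib = timingCalibration(),
                              mode = c("test_retest", "forward_backward"),
                              seeds = c(1L, 2L), retestShift = c(0L, 0L),
                              retestBrightness = 1, ...) {
  mode <- match.arg(mode)
  dir1 <- if (mode == "forward_backward") "forward" else "combined"
  dir2 <- if (mode == "forward_backward") "backward" else "combined"
  cube1 <- renderCube(mask, truths, calib, scanDirection = dir1,
                      seed = seeds[1L], ...)
  truths2 <- truths
  mask2 <- mask
  if (mode == "test_retest") {
    truths2$photons <- truths2$photons * retestBrightness
    if (any(retestShift != 0L))
      mask2 <- shiftMask(mask, retestShift[1L], retestShift[2L])
  }
  cube2 <- renderCube(mask, truths2, calib, scanDirection = dir2,
                      seed = seeds[2L], ...)
  list(cube1 = cube1, cube2 = cube2, mask1 = mask, mask2 = mask2)
}
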