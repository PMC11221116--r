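#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats rnorm rpois sd var optim aov lm coef pf qnorm
#'   p.adjust fft t.test anova setNames runif cor median
#' @importFrom utils read.csv write.csv packageVersion
NULL

VALID_CHANNELS <- c("765/NIR", "532/LSC", "473/LSC", "473/SSC")
VALID_ECCENTRICITIES <- c(0, 2, 8, 12)

#' Timing calibration of a TCSPC acquisition
#'
#' Holds the laser repetition frequency and the time-bin geometry of a
#' time-correlated single-photon counting (TCSPC) record. One record spans at
#' most one laser period; phasors are evaluated at the repetition (angular)
#' frequency stored here.
#'
#' @slot repFrequencyHz laser repetition frequency in Hz (default 80 MHz).
#' @slot nBins number of time bins per period.
#' @slot binWidthS duration of one bin in seconds.
#'
#' @export
setClass("TimingCalibration",
  representation(repFrequencyHz = "numeric", nBins = "integer",
                 binWidthS = "numeric"))

setValidity("TimingCalibration", function(object) {
  msgs <- character()
  if (length(object@repFrequencyHz) != 1L || object@repFrequencyHz <= 0)
    msgs <- c(msgs, "repFrequencyHz must be a single positive number")
  if (length(object@nBins) != 1L || object@nBins < 8L)
    msgs <- c(msgs, "nBins must be >= 8")
  if (length(object@binWidthS) != 1L || object@binWidthS <= 0)
    msgs <- c(msgs, "binWidthS must be positive")
  if (length(msgs) == 0L) {
    period <- 1 / object@repFrequencyHz
    if (object@nBins * object@binWidthS > period * (1 + 1e-9))
      msgs <- c(msgs, "record length nBins * binWidthS exceeds the laser period")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a timing calibration
#'
#' @param repFrequencyHz laser repetition frequency in Hz.
#' @param nBins number of TCSPC time bins per period.
#' @param binWidthS bin width in seconds; defaults to one full period divided
#'   into `nBins` bins (48.828 ps at 80 MHz and 256 bins).
#' @return A [TimingCalibration-class] object.
#' @examples
#' calib <- timingCalibration()
#' period(calib)            # 1.25e-8 s at 80 MHz
#' @export
timingCalibration <- function(repFrequencyHz = 8e7, nBins = 256L,
                              binWidthS = NULL) {
  nBins <- as.integer(nBins)
  if (is.null(binWidthS)) binWidthS <- (1 / repFrequencyHz) / nBins
  new("TimingCalibration", repFrequencyHz = repFrequencyHz, nBins = nBins,
      binWidthS = binWidthS)
}

#' TCSPC histogram cube
#'
#' A rows x cols x time-bins array of non-negative photon counts, one decay
#' histogram per pixel, together with its timing calibration. The scan
#' direction records whether the cube came from the forward or backward sweep
#' of the resonant scanner (or their combination).
#'
#' @slot counts 3-D numeric array (rows x cols x bins) of photon counts.
#' @slot calibration a [TimingCalibration-class].
#' @slot scanDirection one of `"forward"`, `"backward"`, `"combined"`.
#'
#' @export
setClass("HistogramCube",
  representation(counts = "array", calibration = "TimingCalibration",
                 scanDirection = "character"))

setValidity("HistogramCube", function(object) {
  msgs <- character()
  d <- dim(object@counts)
  if (length(d) != 3L)
    msgs <- c(msgs, "counts must be a 3-D array (rows x cols x bins)")
  else if (d[3L] != object@calibration@nBins)
    msgs <- c(msgs, sprintf(
      "cube has %d time bins but calibration declares %d", d[3L],
      object@calibration@nBins))
  if (any(object@counts < 0))
    msgs <- c(msgs, "photon counts must be non-negative")
  if (!object@scanDirection %in% c("forward", "backward", "combined"))
    msgs <- c(msgs, "scanDirection must be forward, backward or combined")
  if (length(msgs)) msgs else TRUE
})

#' Construct a histogram cube
#'
#' @param counts 3-D non-negative array, rows x cols x time bins.
#' @param calibration a [TimingCalibration-class]; its `nBins` must equal
#'   `dim(counts)[3]`.
#' @param scanDirection `"forward"`, `"backward"` or `"combined"`.
#' @return A [HistogramCube-class].
#' @export
histogramCube <- function(counts, calibration, scanDirection = "combined") {
  new("HistogramCube", counts = counts, calibration = calibration,
      scanDirection = scanDirection)
}

#' Cell segmentation mask
#'
#' A label image over the same pixel grid as a histogram cube. Label 0 encodes
#' background and the single-pixel hand-drawn cell borders; label k > 0 is the
#' interior of cell k.
#'
#' @slot labels non-negative integer matrix (rows x cols).
#'
#' @export
setClass("CellMask", representation(labels = "matrix"))

setValidity("CellMask", function(object) {
  l <- object@labels
  if (!is.numeric(l)) return("labels must be numeric")
  if (any(l < 0) || any(l != round(l)))
    return("labels must be non-negative integers")
  TRUE
})

#' Construct a cell mask from a label matrix
#'
#' @param labels non-negative integer matrix; 0 = background/border.
#' @return A [CellMask-class].
#' @export
cellMask <- function(labels) {
  storage.mode(labels) <- "integer"
  new("CellMask", labels = labels)
}

#' Acquisition metadata for one AOFLIO image
#'
#' @slot subjectId subject identifier.
#' @slot ageYears subject age in years.
#' @slot channel spectral channel, one of 765/NIR, 532/LSC, 473/LSC, 473/SSC.
#' @slot eccentricityDeg retinal eccentricity in degrees (0, 2, 8 or 12).
#' @slot meridian `"temporal"`, `"inferior"` or `"none"` (fovea).
#' @slot visitDate visit date string.
#' @slot axialLengthMm measured axial length of the eye in mm.
#' @slot fovDeg square field of view in degrees (default 1.4).
#' @slot imagePxPerSide pixels per image side; no standard value exists, so it
#'   is required metadata.
#'
#' @export
setClass("AcquisitionMetadata",
  representation(subjectId = "character", ageYears = "numeric",
                 channel = "character", eccentricityDeg = "numeric",
                 meridian = "character", visitDate = "character",
                 axialLengthMm = "numeric", fovDeg = "numeric",
                 imagePxPerSide = "integer"))

setValidity("AcquisitionMetadata", function(object) {
  msgs <- character()
  if (!object@channel %in% VALID_CHANNELS)
    msgs <- c(msgs, paste("channel must be one of",
                          paste(VALID_CHANNELS, collapse = ", ")))
  if (!object@eccentricityDeg %in% VALID_ECCENTRICITIES)
    msgs <- c(msgs, "eccentricityDeg must be one of 0, 2, 8, 12")
  if (!object@meridian %in% c("temporal", "inferior", "none"))
    msgs <- c(msgs, "meridian must be temporal, inferior or none")
  if (is.na(object@axialLengthMm) ||
      object@axialLengthMm <= 15 || object@axialLengthMm >= 35)
    msgs <- c(msgs, "axialLengthMm must lie in (15, 35)")
  if (object@fovDeg <= 0) msgs <- c(msgs, "fovDeg must be positive")
  if (object@imagePxPerSide < 1L)
    msgs <- c(msgs, "imagePxPerSide must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct acquisition metadata
#'
#' @param subjectId subject identifier.
#' @param ageYears age in years.
#' @param channel spectral channel (`"765/NIR"`, `"532/LSC"`, `"473/LSC"`,
#'   `"473/SSC"`).
#' @param eccentricityDeg 0, 2, 8 or 12.
#' @param meridian `"temporal"`, `"inferior"` or `"none"`.
#' @param visitDate free-form date string.
#' @param axialLengthMm axial length in mm, in (15, 35).
#' @param fovDeg field of view in degrees.
#' @param imagePxPerSide pixels per image side.
#' @return An [AcquisitionMetadata-class].
#' @export
acquisitionMetadata <- function(subjectId = "S1", ageYears = NA_real_,
                                channel = "532/LSC", eccentricityDeg = 0,
                                meridian = "none", visitDate = "",
                                axialLengthMm = 24.46, fovDeg = 1.4,
                                imagePxPerSide = 500L) {
  new("AcquisitionMetadata", subjectId = subjectId, ageYears = ageYears,
      channel = channel, eccentricityDeg = eccentricityDeg,
      meridian = meridian, visitDate = visitDate,
      axialLengthMm = axialLengthMm, fovDeg = fovDeg,
      imagePxPerSide = as.integer(imagePxPerSide))
}

#' Configuration of the bi-exponential decay fit
#'
#' @slot minPhotons minimum photons per histogram for a fit to be attempted
#'   (default 300).
#' @slot tauBoundsPs lower/upper bounds on the component lifetimes, ps.
#' @slot nStarts number of multi-start initialisations over a log-spaced
#'   lifetime grid (a perfect square; default 16 = a 4 x 4 grid).
#' @slot maxIter maximum optimizer iterations per start.
#' @slot tolerance relative convergence tolerance of the optimizer.
#' @slot fitBackground fit a constant per-bin offset (dark counts) if `TRUE`,
#'   otherwise fix it to 0.
#' @slot irfFwhmPs full width at half maximum of the Gaussian instrument
#'   response function, ps; 0 disables IRF convolution.
#' @slot shiftBins fixed circular timing offset of the model, in bins.
#'
#' @export
setClass("FitConfig",
  representation(minPhotons = "numeric", tauBoundsPs = "numeric",
                 nStarts = "integer", maxIter = "integer",
                 tolerance = "numeric", fitBackground = "logical",
                 irfFwhmPs = "numeric", shiftBins = "numeric"))

setValidity("FitConfig", function(object) {
  msgs <- character()
  if (object@minPhotons < 1) msgs <- c(msgs, "minPhotons must be >= 1")
  if (length(object@tauBoundsPs) != 2L ||
      object@tauBoundsPs[1L] <= 0 ||
      object@tauBoundsPs[1L] >= object@tauBoundsPs[2L])
    msgs <- c(msgs, "tauBoundsPs must be an ordered positive pair")
  if (object@nStarts < 1L) msgs <- c(msgs, "nStarts must be >= 1")
  if (object@irfFwhmPs < 0) msgs <- c(msgs, "irfFwhmPs must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a fit configuration
#'
#' @param minPhotons photon threshold below which a histogram is not fitted.
#' @param tauBoundsPs lifetime bounds in ps.
#' @param nStarts multi-start count (perfect square).
#' @param maxIter optimizer iteration cap.
#' @param tolerance optimizer relative tolerance.
#' @param fitBackground whether to fit a constant offset per bin.
#' @param irfFwhmPs Gaussian IRF FWHM in ps (0 = tail/no-IRF mode).
#' @param shiftBins fixed circular timing offset in bins.
#' @return A [FitConfig-class].
#' @export
fitConfig <- function(minPhotons = 300, tauBoundsPs = c(10, 12000),
                      nStarts = 16L, maxIter = 300L, tolerance = 1e-9,
                      fitBackground = TRUE, irfFwhmPs = 120,
                      shiftBins = 0) {
  new("FitConfig", minPhotons = minPhotons, tauBoundsPs = tauBoundsPs,
      nStarts = as.integer(nStarts), maxIter = as.integer(maxIter),
      tolerance = tolerance, fitBackground = fitBackground,
      irfFwhmPs = irfFwhmPs, shiftBins = shiftBins)
}

#' Per-cell aggregated decay histograms
#'
#' A \linkS4class{SummarizedExperiment} whose rows are segmented cells and
#' whose columns are TCSPC time bins; the single assay `"counts"` holds the
#' per-cell summed histograms. `rowData` carries `label`, `pixel_count`,
#' `total_photons` and `touches_edge`; `metadata` carries the
#' [TimingCalibration-class] and the labels excluded at the image frame.
#'
#' @export
setClass("CellDecaySet", contains = "SummarizedExperiment")

setValidity("CellDecaySet", function(object) {
  msgs <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'counts' is required")
  calib <- S4Vectors::metadata(object)$calibration
  if (!is(calib, "TimingCalibration"))
    msgs <- c(msgs, "metadata$calibration must be a TimingCalibration")
  else if (ncol(object) != calib@nBins)
    msgs <- c(msgs, "number of columns must equal calibration nBins")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("label", "pixel_count", "total_photons")
  if (!all(need %in% colnames(rd)))
    msgs <- c(msgs, paste("rowData must contain",
                          paste(need, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Specification of a synthetic RPE mosaic
#'
#' Defaults are anchored to in-vivo adaptive-optics observations of the human
#' retinal pigment epithelium: ~220 um^2 mean cell area in a 1.4 deg field.
#'
#' @slot imagePxPerSide image side length in pixels.
#' @slot fovDeg field of view in degrees.
#' @slot targetMeanCellAreaUm2 target mean interior cell area, um^2.
#' @slot jitterFraction lattice-point jitter as a fraction of lattice spacing.
#' @slot axialLengthMm axial length used for the um-per-pixel conversion.
#'
#' @export
setClass("MosaicSpec",
  representation(imagePxPerSide = "integer", fovDeg = "numeric",
                 targetMeanCellAreaUm2 = "numeric", jitterFraction = "numeric",
                 axialLengthMm = "numeric"))

setValidity("MosaicSpec", function(object) {
  msgs <- character()
  if (object@targetMeanCellAreaUm2 <= 50 ||
      object@targetMeanCellAreaUm2 >= 1000)
    msgs <- c(msgs, "targetMeanCellAreaUm2 must lie in (50, 1000)")
  if (object@jitterFraction < 0 || object@jitterFraction > 0.5)
    msgs <- c(msgs, "jitterFraction must lie in [0, 0.5]")
  if (object@imagePxPerSide < 16L)
    msgs <- c(msgs, "imagePxPerSide must be >= 16")
  if (object@fovDeg <= 0) msgs <- c(msgs, "fovDeg must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct a mosaic specification
#'
#' @param imagePxPerSide image side in pixels (default 500).
#' @param fovDeg field of view in degrees (default 1.4).
#' @param targetMeanCellAreaUm2 target mean cell area (default 220 um^2).
#' @param jitterFraction lattice jitter fraction in [0, 0.5] (default 0.35).
#' @param axialLengthMm axial length in mm (default 24.46, emmetropic eye).
#' @return A [MosaicSpec-class].
#' @export
mosaicSpec <- function(imagePxPerSide = 500L, fovDeg = 1.4,
                       targetMeanCellAreaUm2 = 220, jitterFraction = 0.35,
                       axialLengthMm = 24.46) {
  new("MosaicSpec", imagePxPerSide = as.integer(imagePxPerSide),
      fovDeg = fovDeg, targetMeanCellAreaUm2 = targetMeanCellAreaUm2,
      jitterFraction = jitterFraction, axialLengthMm = axialLengthMm)
}

#' Channel lifetime palette for the synthetic generator
#'
#' Distributions from which per-cell bi-exponential parameters are drawn, plus
#' linear eccentricity and age slopes applied to their means. The slopes are
#' configurable study conditions of the simulator, not fitted estimates.
#'
#' @slot channel spectral channel name.
#' @slot tau1MeanPs,tau1SdPs short-component lifetime distribution, ps.
#' @slot tau2MeanPs,tau2SdPs long-component lifetime distribution, ps.
#' @slot a1Mean,a1Sd amplitude-fraction distribution of the short component.
#' @slot eccSlopeTau1PsPerDeg,eccSlopeTau2PsPerDeg,eccSlopeA1PerDeg
#'   eccentricity slopes applied to the means.
#' @slot ageSlopeTau1PsPerYear,ageSlopeTau2PsPerYear,ageSlopeA1PerYear
#'   age slopes applied to the means (relative to age 25).
#'
#' @export
setClass("ChannelPalette",
  representation(channel = "character",
                 tau1MeanPs = "numeric", tau1SdPs = "numeric",
                 tau2MeanPs = "numeric", tau2SdPs = "numeric",
                 a1Mean = "numeric", a1Sd = "numeric",
                 eccSlopeTau1PsPerDeg = "numeric",
                 eccSlopeTau2PsPerDeg = "numeric",
                 eccSlopeA1PerDeg = "numeric",
                 ageSlopeTau1PsPerYear = "numeric",
                 ageSlopeTau2PsPerYear = "numeric",
                 ageSlopeA1PerYear = "numeric"))

setValidity("ChannelPalette", function(object) {
  if (object@tau1SdPs < 0 || object@tau2SdPs < 0 || object@a1Sd < 0)
    return("all palette SDs must be >= 0")
  if (object@tau1MeanPs <= 0 || object@tau2MeanPs <= 0)
    return("palette mean lifetimes must be positive")
  if (object@a1Mean < 0 || object@a1Mean > 1)
    return("a1Mean must lie in [0, 1]")
  TRUE
})
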