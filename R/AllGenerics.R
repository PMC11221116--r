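#' @importFrom BiocGenerics counts
NULL

#' Accessors for timing calibrations, cubes and masks
#'
#' `calibration` returns the [TimingCalibration-class] attached to an object;
#' `repFrequency`, `nBins`, `binWidth`, `period` and `angularFrequency` read
#' the calibration fields (seconds / Hz / rad s^-1); `binCenters` returns the
#' bin-center time coordinates `(i + 0.5) * binWidth`, i = 0..nBins-1, in
#' seconds; `maskLabels` returns the integer label matrix of a
#' [CellMask-class].
#'
#' @param object a cellFLIM object.
#' @return The accessed value.
#' @name calibration
#' @aliases calibration repFrequency nBins binWidth period angularFrequency
#'   binCenters maskLabels
#' @examples
#' angularFrequency(timingCalibration())  # 2 * pi * 8e7
NULL

#' @rdname calibration
#' @export
setGeneric("calibration", function(object) standardGeneric("calibration"))

#' @rdname calibration
#' @export
setGeneric("repFrequency", function(object) standardGeneric("repFrequency"))

#' @rdname calibration
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))

#' @rdname calibration
#' @export
setGeneric("binWidth", function(object) standardGeneric("binWidth"))

#' @rdname calibration
#' @export
setGeneric("period", function(object) standardGeneric("period"))

#' @rdname calibration
#' @export
setGeneric("angularFrequency",
           function(object) standardGeneric("angularFrequency"))

#' @rdname calibration
#' @export
setGeneric("binCenters", function(object) standardGeneric("binCenters"))

#' @rdname calibration
#' @export
setGeneric("maskLabels", function(object) standardGeneric("maskLabels"))

setMethod("repFrequency", "TimingCalibration",
          function(object) object@repFrequencyHz)
setMethod("nBins", "TimingCalibration", function(object) object@nBins)
setMethod("binWidth", "TimingCalibration", function(object) object@binWidthS)
setMethod("period", "TimingCalibration",
          function(object) 1 / object@repFrequencyHz)
setMethod("angularFrequency", "TimingCalibration",
          function(object) 2 * pi * object@repFrequencyHz)
setMethod("binCenters", "TimingCalibration",
          function(object) (seq_len(object@nBins) - 0.5) * object@binWidthS)

setMethod("calibration", "HistogramCube", function(object) object@calibration)
setMethod("nBins", "HistogramCube", function(object) object@calibration@nBins)
setMethod("binCenters", "HistogramCube",
          function(object) binCenters(object@calibration))

#' @describeIn HistogramCube-class photon-count array accessor.
#' @param object a `HistogramCube`.
#' @export
setMethod("counts", "HistogramCube", function(object) object@counts)

setMethod("dim", "HistogramCube", function(x) dim(x@counts))

#' @describeIn CellMask-class label-matrix accessor.
#' @param object a `CellMask`.
#' @export
setMethod("maskLabels", "CellMask", function(object) object@labels)

setMethod("dim", "CellMask", function(x) dim(x@labels))

setMethod("calibration", "CellDecaySet",
          function(object) S4Vectors::metadata(object)$calibration)

#' @describeIn CellDecaySet-class per-cell histogram matrix (cells x bins).
#' @param object a `CellDecaySet`.
#' @export
setMethod("counts", "CellDecaySet",
          function(object) SummarizedExperiment::assay(object, "counts"))

setMethod("show", "TimingCalibration", function(object) {
  cat("TimingCalibration:", format(object@repFrequencyHz / 1e6), "MHz,",
      object@nBins, "bins of", format(object@binWidthS * 1e12), "ps\n")
})

setMethod("show", "HistogramCube", function(object) {
  d <- dim(object@counts)
  cat(sprintf("HistogramCube: %d x %d pixels, %d time bins (%s scan)\n",
              d[1L], d[2L], d[3L], object@scanDirection))
  cat("  total photons:", format(sum(object@counts)), "\n")
  show(object@calibration)
})

setMethod("show", "CellMask", function(object) {
  l <- object@labels
  cat(sprintf("CellMask: %d x %d pixels, %d cells (max label %d)\n",
              nrow(l), ncol(l), length(setdiff(unique(as.vector(l)), 0L)),
              max(l)))
})

setMethod("show", "FitConfig", function(object) {
  cat(sprintf(
    "FitConfig: minPhotons %g, tau in [%g, %g] ps, %d starts, IRF FWHM %g ps, background %s\n",
    object@minPhotons, object@tauBoundsPs[1L], object@tauBoundsPs[2L],
    object@nStarts, object@irfFwhmPs,
    if (object@fitBackground) "fitted" else "fixed 0"))
})

setMethod("show", "ChannelPalette", function(object) {
  cat(sprintf(
    "ChannelPalette [%s]: tau1 %g+/-%g ps, tau2 %g+/-%g ps, a1 %g+/-%g\n",
    object@channel, object@tau1MeanPs, object@tau1SdPs, object@tau2MeanPs,
    object@tau2SdPs, object@a1Mean, object@a1Sd))
})
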