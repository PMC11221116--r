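#' Phasor transform of a decay histogram
#'
#' The phasor coordinates are the real (`g`) and imaginary (`s`) components
#' of the Fourier transform of the raw histogram evaluated at the laser
#' repetition frequency (harmonic 1) and normalized by the photon count:
#' `g = sum(k_i cos(w t_i)) / sum(k_i)`, `s = sum(k_i sin(w t_i)) / sum(k_i)`
#' with `w = harmonic * 2 * pi * repFrequency` and `t_i` the bin centers.
#' No fitting and no IRF correction are involved; any physical histogram maps
#' inside the unit circle, and mono-exponential decays lie on the universal
#' semicircle `g^2 + s^2 = g`.
#'
#' @param hist non-negative counts, one per time bin (sum must be positive).
#' @param calib a [TimingCalibration-class].
#' @param harmonic harmonic of the repetition frequency (default 1).
#' @return data.frame row with `g`, `s`, `harmonic`, `n_photons`.
#' @export
phasorFromHistogram <- function(hist, calib, harmonic = 1L) {
  stopifnot(is(calib, "TimingCalibration"))
  if (length(hist) != calib@nBins)
    stop("histogram length does not match calibration nBins")
  if (any(hist < 0)) stop("histogram counts must be non-negative")
  total <- sum(hist)
  if (total <= 0) stop("empty histogram has no phasor")
  wt <- harmonic * angularFrequency(calib) * binCenters(calib)
  data.frame(g = sum(hist * cos(wt)) / total,
             s = sum(hist * sin(wt)) / total,
             harmonic = as.integer(harmonic), n_photons = total)
}

#' Closed-form phasor of a mono-exponential decay
#'
#' `g = 1 / (1 + (w tau)^2)`, `s = w tau / (1 + (w tau)^2)`: the point lies
#' exactly on the universal semicircle. Serves as the analytic oracle for the
#' histogram transform.
#'
#' @param tauS lifetime in seconds (> 0).
#' @param omega angular frequency in rad/s (e.g.
#'   `angularFrequency(timingCalibration())`).
#' @return data.frame row with `g`, `s`.
#' @examples
#' phasorOfMonoexponential(1e-9, 2 * pi * 8e7)  # (0.79830, 0.40127)
#' @export
phasorOfMonoexponential <- function(tauS, omega) {
  if (any(tauS <= 0)) stop("tau must be positive")
  x <- omega * tauS
  data.frame(g = 1 / (1 + x^2), s = x / (1 + x^2))
}

#' Photon-weighted phasor mixture
#'
#' Because the transform is linear in the histogram, the phasor of a photon
#' mixture is the photon-weighted average of the component phasors; this
#' equals the phasor of the summed histograms.
#'
#' @param points data.frame with columns `g`, `s` (one row per component).
#' @param photonWeights non-negative weights, not all zero (typically photon
#'   counts).
#' @return data.frame row with `g`, `s`, `n_photons`.
#' @export
phasorMixture <- function(points, photonWeights) {
  stopifnot(nrow(points) == length(photonWeights))
  if (any(photonWeights < 0)) stop("weights must be non-negative")
  W <- sum(photonWeights)
  if (W == 0) stop("all-zero weights")
  data.frame(g = sum(points$g * photonWeights) / W,
             s = sum(points$s * photonWeights) / W, n_photons = W)
}

#' Per-image phasor summary
#'
#' Mean and sample standard deviation of `g` and `s` across cells (or
#' pixels); the SD pair is the quantity compared between cell-encircled and
#' pixel-wise analyses and the input to the power analysis.
#'
#' @param points data.frame with columns `g`, `s`, at least 2 rows.
#' @return data.frame row with `mean_g`, `mean_s`, `sd_g`, `sd_s`, `n`.
#' @export
phasorSummary <- function(points) {
  if (nrow(points) < 2L) stop("phasor summary needs at least 2 points")
  data.frame(mean_g = mean(points$g), mean_s = mean(points$s),
             sd_g = sd(points$g), sd_s = sd(points$s), n = nrow(points))
}

#' Phasors of all cells in a decay set
#'
#' @param cds a [CellDecaySet-class].
#' @param harmonic harmonic of the repetition frequency.
#' @param minPhotons cells with fewer total photons are skipped (0 = keep
#'   all non-empty).
#' @return data.frame with one row per retained cell: `label`,
#'   `pixel_count`, `g`, `s`, `harmonic`, `n_photons`.
#' @export
phasorCells <- function(cds, harmonic = 1L, minPhotons = 0) {
  stopifnot(is(cds, "CellDecaySet"))
  calib <- calibration(cds)
  rd <- SummarizedExperiment::rowData(cds)
  hmat <- counts(cds)
  tot <- rowSums(hmat)
  keep <- if (minPhotons > 0) tot >= minPhotons else tot > 0
  idx <- which(keep)
  out <- do.call(rbind, lapply(idx, function(i)
    phasorFromHistogram(hmat[i, ], calib, harmonic)))
  cbind(data.frame(label = rd$label[idx],
                   pixel_count = rd$pixel_count[idx]), out)
}
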