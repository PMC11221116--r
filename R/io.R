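# On-disk layout of an HDF5 cube:
#   /counts                       rows x cols x bins integer array
#   /calibration/rep_frequency_hz, /calibration/n_bins, /calibration/bin_width_s
#   /meta/scan_direction
# TIFF import: one frame per time bin (16-bit), calibration in a YAML sidecar.

#' Write a histogram cube to an HDF5 container
#'
#' Counts are stored as integers under `/counts` with the timing calibration
#' under `/calibration/*`; the round trip through [readCube()] is bit-exact.
#'
#' @param cube a [HistogramCube-class].
#' @param path output file path (`.h5`).
#' @return `path`, invisibly.
#' @export
writeCube <- function(cube, path) {
  stopifnot(is(cube, "HistogramCube"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "calibration")
  rhdf5::h5createGroup(path, "meta")
  counts <- cube@counts
  storage.mode(counts) <- "integer"
  rhdf5::h5write(counts, path, "counts")
  calib <- cube@calibration
  rhdf5::h5write(calib@repFrequencyHz, path, "calibration/rep_frequency_hz")
  rhdf5::h5write(calib@nBins, path, "calibration/n_bins")
  rhdf5::h5write(calib@binWidthS, path, "calibration/bin_width_s")
  rhdf5::h5write(cube@scanDirection, path, "meta/scan_direction")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a histogram cube
#'
#' Reads either the package's HDF5 layout (see [writeCube()]) or a multi-frame
#' 16-bit TIFF (one frame per time bin) with a YAML calibration sidecar
#' holding `rep_frequency_hz`, `n_bins` and optionally `bin_width_s`.
#'
#' @param path `.h5`/`.hdf5` file, or a multi-frame `.tif`/`.tiff`.
#' @param sidecar YAML calibration file for TIFF input; defaults to
#'   `<path>.yaml`.
#' @return A [HistogramCube-class].
#' @examples
#' calib <- timingCalibration(nBins = 16L)
#' cube <- histogramCube(array(0L, c(4, 4, 16)), calib)
#' f <- tempfile(fileext = ".h5")
#' writeCube(cube, f)
#' identical(counts(readCube(f)), counts(cube))
#' @export
readCube <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5", "hdf5")) .readCubeH5(path) else
    if (ext %in% c("tif", "tiff")) .readCubeTiff(path, sidecar) else
      stop("unsupported cube format: .", ext)
}

.readCubeH5 <- function(path) {
  contents <- rhdf5::h5ls(path)$name
  if (!all(c("counts", "rep_frequency_hz", "n_bins", "bin_width_s") %in%
           contents))
    stop("HDF5 cube at ", path,
         " is missing /counts or /calibration datasets")
  counts <- rhdf5::h5read(path, "counts")
  calib <- timingCalibration(
    repFrequencyHz = as.numeric(rhdf5::h5read(path,
                                              "calibration/rep_frequency_hz")),
    nBins = as.integer(rhdf5::h5read(path, "calibration/n_bins")),
    binWidthS = as.numeric(rhdf5::h5read(path, "calibration/bin_width_s")))
  scan <- if ("scan_direction" %in% contents)
    as.character(rhdf5::h5read(path, "meta/scan_direction")) else "combined"
  rhdf5::h5closeAll()
  if (any(counts < 0)) stop("cube contains negative counts")
  histogramCube(counts, calib, scan)
}

.readCubeTiff <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- paste0(path, ".yaml")
  if (!file.exists(sidecar))
    stop("TIFF cube needs a calibration sidecar; not found: ", sidecar)
  side <- yaml::read_yaml(sidecar)
  if (is.null(side$rep_frequency_hz) || is.null(side$n_bins))
    stop("calibration sidecar must provide rep_frequency_hz and n_bins")
  frames <- tiff::readTIFF(path, all = TRUE)
  if (length(frames) != side$n_bins)
    stop(sprintf("TIFF has %d frames but sidecar declares %d bins",
                 length(frames), side$n_bins))
  counts <- array(0L, c(dim(frames[[1L]]), length(frames)))
  for (i in seq_along(frames))
    counts[, , i] <- as.integer(round(frames[[i]] * 65535))
  calib <- timingCalibration(
    repFrequencyHz = side$rep_frequency_hz, nBins = side$n_bins,
    binWidthS = if (is.null(side$bin_width_s)) NULL else side$bin_width_s)
  histogramCube(counts, calib,
                if (is.null(side$scan_direction)) "combined"
                else side$scan_direction)
}

#' Write a histogram cube as a multi-frame 16-bit TIFF plus YAML sidecar
#'
#' @param cube a [HistogramCube-class] with all counts <= 65535.
#' @param path output `.tif` path; the sidecar is written to `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
writeCubeTiff <- function(cube, path) {
  stopifnot(is(cube, "HistogramCube"))
  if (max(cube@counts) > 65535)
    stop("16-bit TIFF export requires counts <= 65535 per pixel-bin")
  frames <- lapply(seq_len(dim(cube@counts)[3L]),
                   function(i) cube@counts[, , i] / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  calib <- cube@calibration
  yaml::write_yaml(list(rep_frequency_hz = calib@repFrequencyHz,
                        n_bins = calib@nBins,
                        bin_width_s = calib@binWidthS,
                        scan_direction = cube@scanDirection),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read / write cell masks as label images
#'
#' Masks are single-channel label images; label 0 is background/border.
#' TIFF masks are written 16-bit (labels up to 65535); PNG masks are written
#' 8-bit (labels up to 255; 16-bit PNGs from other tools are read
#' correctly). Labels round-trip exactly within those depths. The stored bit
#' depth is inferred on read: values that are exact multiples of 1/255 are
#' decoded as 8-bit, otherwise as 16-bit.
#'
#' @param path image file (`.png`, `.tif`, `.tiff`).
#' @return `readMask` returns a [CellMask-class]; `writeMask` returns `path`
#'   invisibly.
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format: .", ext))
  if (length(dim(img)) != 2L)
    stop("mask must be a single-channel label image")
  l8 <- img * 255
  scale <- if (max(abs(l8 - round(l8))) < 1e-9) 255 else 65535
  cellMask(matrix(as.integer(round(img * scale)), nrow(img), ncol(img)))
}

#' @rdname readMask
#' @param mask a [CellMask-class].
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "CellMask"))
  l <- maskLabels(mask)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = {
      if (max(l) > 255)
        stop("label overflow: PNG masks are written 8-bit (labels <= 255); ",
             "use TIFF for larger label counts")
      png::writePNG(l / 255, path)
    },
    tif = ,
    tiff = {
      if (max(l) > 65535)
        stop("label overflow: 16-bit masks require labels <= 65535")
      tiff::writeTIFF(l / 65535, path, bits.per.sample = 16L)
    },
    stop("unsupported mask format: .", ext))
  invisible(path)
}

#' Write / read per-cell result tables
#'
#' Tables are plain CSV with one row per cell and documented column names
#' (`label`, `pixel_count`, `total_photons`, fit and phasor fields, metadata
#' columns); [readResults()] restores them as a data.frame.
#'
#' @param cells data.frame of per-cell records.
#' @param path CSV path.
#' @return `writeResults` returns `path` invisibly; `readResults` the
#'   data.frame.
#' @export
writeResults <- function(cells, path) {
  stopifnot(is.data.frame(cells))
  write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  read.csv(path, check.names = FALSE)
}
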