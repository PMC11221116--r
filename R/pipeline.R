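# Orchestration used by the cellkit command-line script: every subcommand is
# an exported function over the package API, so scripted runs and interactive
# use share one code path. Outputs are CSV/HDF5 plus a JSON run manifest
# recording versions, seeds, thresholds and exclusion counts.

.writeManifest <- function(path, subcommand, params, extras = list()) {
  manifest <- c(list(
    tool = "cellkit", package = "cellFLIM",
    version = as.character(packageVersion("cellFLIM")),
    r_version = as.character(getRversion()),
    subcommand = subcommand, timestamp = format(Sys.time(), tz = "UTC"),
    params = params), extras)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read / write a timing calibration as YAML
#'
#' @param path YAML file with `rep_frequency_hz`, `n_bins` and optionally
#'   `bin_width_s`.
#' @return `readCalibration` returns a [TimingCalibration-class].
#' @export
readCalibration <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$rep_frequency_hz) || is.null(y$n_bins))
    stop("calibration file must provide rep_frequency_hz and n_bins")
  timingCalibration(y$rep_frequency_hz, y$n_bins,
                    if (is.null(y$bin_width_s)) NULL else y$bin_width_s)
}

#' @rdname readCalibration
#' @param calib a [TimingCalibration-class].
#' @export
writeCalibration <- function(calib, path) {
  yaml::write_yaml(list(rep_frequency_hz = calib@repFrequencyHz,
                        n_bins = calib@nBins,
                        bin_width_s = calib@binWidthS), path)
  invisible(path)
}

#' Write / read per-cell decay histograms as CSV
#'
#' One row per cell: `label`, `pixel_count`, `total_photons`, then one
#' `bin_<i>` column per time bin. The calibration travels separately (YAML,
#' see [readCalibration()]).
#'
#' @param cds a [CellDecaySet-class].
#' @param path CSV path.
#' @return `writeCellDecays` returns `path` invisibly; `readCellDecays` a
#'   [CellDecaySet-class].
#' @export
writeCellDecays <- function(cds, path) {
  stopifnot(is(cds, "CellDecaySet"))
  rd <- SummarizedExperiment::rowData(cds)
  hmat <- counts(cds)
  colnames(hmat) <- sprintf("bin_%04d", seq_len(ncol(hmat)))
  writeResults(cbind(data.frame(label = rd$label,
                                pixel_count = rd$pixel_count,
                                total_photons = rd$total_photons), hmat),
               path)
}

#' @rdname writeCellDecays
#' @param calib the [TimingCalibration-class] of the stored histograms.
#' @export
readCellDecays <- function(path, calib) {
  tab <- readResults(path)
  bins <- grep("^bin_", colnames(tab))
  if (length(bins) != calib@nBins)
    stop("stored histograms have ", length(bins),
         " bins but calibration declares ", calib@nBins)
  hmat <- as.matrix(tab[, bins, drop = FALSE])
  dimnames(hmat) <- NULL
  rd <- S4Vectors::DataFrame(label = tab$label,
                             pixel_count = tab$pixel_count,
                             total_photons = rowSums(hmat),
                             touches_edge = FALSE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = hmat), rowData = rd,
    metadata = list(calibration = calib, edge_excluded = integer(),
                    scan_direction = "combined"))
  rownames(se) <- as.character(tab$label)
  new("CellDecaySet", se)
}

#' Simulate a complete synthetic AOFLIO acquisition
#'
#' Mosaic, per-cell ground truth and rendered TCSPC cube in one call; the
#' returned list carries the full provenance (spec, palette, seed) needed to
#' regenerate the data exactly.
#'
#' @param spec a [MosaicSpec-class].
#' @param palette a [ChannelPalette-class].
#' @param calib a [TimingCalibration-class].
#' @param eccentricityDeg,ageYears study conditions of the ground truth.
#' @param photonsPerCell expected photons per cell.
#' @param irfFwhmPs,backgroundRate rendering parameters (see [renderCube()]).
#' @param seed master seed; mosaic, truth and rendering use child streams.
#' @return list: `cube`, `mask`, `truth`, `geometry`, `seed`.
#' @export
simulateAoflio <- function(spec = mosaicSpec(), palette = channelPalette(),
                           calib = timingCalibration(), eccentricityDeg = 0,
                           ageYears = 25, photonsPerCell = 5000,
                           irfFwhmPs = 120, backgroundRate = 0, seed = 1L) {
  mos <- generateMosaic(spec, seed = .childSeed(seed, 1L))
  truth <- assignCellTruth(mos$mask, palette, eccentricityDeg, ageYears,
                           photonsPerCell, seed = .childSeed(seed, 2L))
  cube <- renderCube(mos$mask, truth, calib, irfFwhmPs = irfFwhmPs,
                     backgroundRate = backgroundRate,
                     seed = .childSeed(seed, 3L))
  list(cube = cube, mask = mos$mask, truth = truth, geometry = mos$geometry,
       seed = seed)
}

#' Cell-encircled versus pixel-wise comparison on one cube
#'
#' Runs the cell-encircled analysis and the traditional pixel-wise baseline
#' (kernel pooling, one pooled histogram per retained-cell centroid pixel)
#' on the same cube, and reports per-image means and SDs of the lifetime and
#' phasor parameters for both methods plus the consistency ICC between them,
#' parameter by parameter.
#'
#' @param cube a [HistogramCube-class].
#' @param mask a [CellMask-class].
#' @param config a [FitConfig-class].
#' @param kernelPx pooling kernel of the pixel-wise baseline (default 7).
#' @return list with `per_cell` (matched per-cell values of both methods),
#'   `summary` (mean/SD per parameter and method) and `icc` (between-method
#'   consistency ICC per parameter).
#' @export
comparePixelwise <- function(cube, mask, config = fitConfig(),
                             kernelPx = 7L) {
  cds <- aggregateCells(cube, mask)
  fits_cell <- fitCells(cds, config)
  ph_cell <- phasorCells(cds, minPhotons = config@minPhotons)
  cell <- merge(fits_cell[fits_cell$status == "fit", ],
                ph_cell[, c("label", "g", "s")], by = "label")

  pooled <- pixelwisePool(cube, kernelPx)
  calib <- cube@calibration
  keep <- cell$label
  cent <- cellGeometry(mask)
  cent <- cent[match(keep, cent$label), ]
  px <- lapply(seq_len(nrow(cent)), function(i) {
    r <- round(cent$centroid_row[i]); c <- round(cent$centroid_col[i])
    pooled@counts[r, c, ]
  })
  pxrows <- lapply(seq_along(px), function(i) {
    h <- px[[i]]
    if (sum(h) < config@minPhotons)
      return(NULL)
    fit <- fitBiexponential(h, calib, config, polish = 2L)
    ph <- phasorFromHistogram(h, calib)
    cbind(data.frame(label = keep[i]), fit, g = ph$g, s = ph$s)
  })
  pixel <- do.call(rbind, pxrows)
  params <- c("tau_m_ps", "tau1_ps", "tau2_ps", "a1", "g", "s")
  merged <- merge(cell[, c("label", params)], pixel[, c("label", params)],
                  by = "label", suffixes = c(".cell", ".pixel"))
  summary <- do.call(rbind, lapply(params, function(p) {
    data.frame(parameter = p,
               mean_cell = mean(merged[[paste0(p, ".cell")]]),
               sd_cell = sd(merged[[paste0(p, ".cell")]]),
               mean_pixel = mean(merged[[paste0(p, ".pixel")]]),
               sd_pixel = sd(merged[[paste0(p, ".pixel")]]))
  }))
  icc <- do.call(rbind, lapply(params, function(p) {
    v <- iccConsistency(cbind(merged[[paste0(p, ".cell")]],
                              merged[[paste0(p, ".pixel")]]))
    data.frame(parameter = p, icc_value = as.numeric(v),
               icc_p = attr(v, "p_value"),
               icc_class = classifyIcc(as.numeric(v), attr(v, "p_value")))
  }))
  list(per_cell = merged, summary = summary, icc = icc)
}

#' Run one cellkit pipeline subcommand
#'
#' Programmatic equivalent of the `cellkit` command-line tool. `config` is a
#' named list with `subcommand` (one of `simulate`, `aggregate`, `fit`,
#' `phasor`, `repeat`, `anova`, `compare-pixelwise`) and the subcommand's
#' parameters; defaults mirror the CLI flags. Every run writes its outputs
#' plus a JSON manifest (`<out>.manifest.json`) recording package version,
#' seed, thresholds and exclusion counts. Invalid configurations raise an
#' error before any output is written; outputs of a failed run are removed.
#'
#' @param config named list, see Details.
#' @return Invisibly, a list of produced artifact paths.
#' @export
runPipeline <- function(config) {
  sub <- config$subcommand
  if (is.null(sub) ||
      !sub %in% c("simulate", "aggregate", "fit", "phasor", "repeat",
                  "anova", "compare-pixelwise"))
    stop("unknown subcommand: ", if (is.null(sub)) "<missing>" else sub)
  get0(paste0(".pipe_", gsub("-", "_", sub)),
       envir = asNamespace("cellFLIM"))(config)
}

.cfg <- function(config, name, default = NULL, required = FALSE) {
  v <- config[[name]]
  if (is.null(v)) {
    if (required) stop("missing required parameter: ", name)
    v <- default
  }
  v
}

.needFile <- function(path, what) {
  if (!file.exists(path)) stop(what, " not found: ", path)
  path
}

.cleanOnFail <- function(paths, expr) {
  ok <- FALSE
  on.exit(if (!ok) unlink(paths))
  res <- expr
  ok <- TRUE
  res
}

.pipe_simulate <- function(config) {
  out <- .cfg(config, "out", required = TRUE)
  maskOut <- .cfg(config, "mask_out", sub("\\.h5$", "_mask.tif", out))
  truthOut <- .cfg(config, "truth_out", sub("\\.h5$", "_truth.csv", out))
  seed <- .cfg(config, "seed", 1L)
  spec <- mosaicSpec(
    imagePxPerSide = .cfg(config, "px_per_side", 500L),
    targetMeanCellAreaUm2 = .cfg(config, "cell_area_um2", 220))
  calib <- timingCalibration(nBins = .cfg(config, "n_bins", 256L))
  sim <- .cleanOnFail(c(out, maskOut, truthOut), {
    sim <- simulateAoflio(
      spec, channelPalette(.cfg(config, "preset", "532/LSC")), calib,
      eccentricityDeg = .cfg(config, "ecc", 0),
      ageYears = .cfg(config, "age", 25),
      photonsPerCell = .cfg(config, "photons", 5000),
      irfFwhmPs = .cfg(config, "irf_fwhm", 120),
      backgroundRate = .cfg(config, "background", 0), seed = seed)
    writeCube(sim$cube, out)
    writeMask(sim$mask, maskOut)
    writeResults(sim$truth, truthOut)
    writeCalibration(calib, paste0(out, ".calib.yaml"))
    sim
  })
  .writeManifest(paste0(out, ".manifest.json"), "simulate",
                 config[setdiff(names(config), "subcommand")],
                 list(seed = seed, n_cells = nrow(sim$truth)))
  invisible(list(cube = out, mask = maskOut, truth = truthOut))
}

.pipe_aggregate <- function(config) {
  cubePath <- .needFile(.cfg(config, "cube", required = TRUE), "cube")
  maskPath <- .needFile(.cfg(config, "mask", required = TRUE), "mask")
  out <- .cfg(config, "out", required = TRUE)
  cube <- readCube(cubePath)
  mask <- readMask(maskPath)
  cds <- .cleanOnFail(out, {
    cds <- aggregateCells(cube, mask)
    writeCellDecays(cds, out)
    writeCalibration(calibration(cds), paste0(out, ".calib.yaml"))
    cds
  })
  .writeManifest(paste0(out, ".manifest.json"), "aggregate",
                 list(cube = cubePath, mask = maskPath),
                 list(n_cells = nrow(cds),
                      n_edge_excluded =
                        length(S4Vectors::metadata(cds)$edge_excluded)))
  invisible(list(cells = out))
}

.pipe_fit <- function(config) {
  cellsPath <- .needFile(.cfg(config, "cells", required = TRUE), "cells table")
  calibPath <- .needFile(.cfg(config, "calib",
                              paste0(cellsPath, ".calib.yaml")),
                         "calibration")
  out <- .cfg(config, "out", required = TRUE)
  cfg <- fitConfig(minPhotons = .cfg(config, "min_photons", 300),
                   irfFwhmPs = .cfg(config, "irf_fwhm", 120))
  cds <- readCellDecays(cellsPath, readCalibration(calibPath))
  fits <- .cleanOnFail(out, {
    fits <- fitCells(cds, cfg)
    writeResults(fits, out)
    fits
  })
  .writeManifest(paste0(out, ".manifest.json"), "fit",
                 list(cells = cellsPath, min_photons = cfg@minPhotons,
                      irf_fwhm_ps = cfg@irfFwhmPs),
                 list(n_fit = sum(fits$status == "fit"),
                      n_below_threshold =
                        sum(fits$status == "below_threshold")))
  invisible(list(fits = out))
}

.pipe_phasor <- function(config) {
  cellsPath <- .needFile(.cfg(config, "cells", required = TRUE), "cells table")
  calibPath <- .needFile(.cfg(config, "calib",
                              paste0(cellsPath, ".calib.yaml")),
                         "calibration")
  out <- .cfg(config, "out", required = TRUE)
  minPhotons <- .cfg(config, "min_photons", 0)
  cds <- readCellDecays(cellsPath, readCalibration(calibPath))
  ph <- .cleanOnFail(out, {
    ph <- phasorCells(cds, minPhotons = minPhotons)
    writeResults(ph, out)
    ph
  })
  .writeManifest(paste0(out, ".manifest.json"), "phasor",
                 list(cells = cellsPath, min_photons = minPhotons),
                 list(n_cells = nrow(ph)))
  invisible(list(phasor = out))
}

.pipe_repeat <- function(config) {
  aPath <- .needFile(.cfg(config, "a", required = TRUE), "first table")
  bPath <- .needFile(.cfg(config, "b", required = TRUE), "second table")
  out <- .cfg(config, "out", required = TRUE)
  report <- .cleanOnFail(out, {
    report <- repeatabilityReport(
      readResults(aPath), readResults(bPath),
      matchOn = .cfg(config, "match_on", "label"),
      model = .cfg(config, "model", "agreement"))
    writeResults(report, out)
    report
  })
  .writeManifest(paste0(out, ".manifest.json"), "repeat",
                 list(a = aPath, b = bPath),
                 list(n_parameters = nrow(report),
                      n_units = report$n_units[1L]))
  invisible(list(report = out))
}

.pipe_anova <- function(config) {
  fitsPath <- .needFile(.cfg(config, "fits", required = TRUE), "fits table")
  factorCol <- .cfg(config, "factor", "eccentricity_deg")
  out <- .cfg(config, "out", required = TRUE)
  tab <- readResults(fitsPath)
  if (!factorCol %in% colnames(tab))
    stop("factor column not in fits table: ", factorCol)
  params <- intersect(c("tau_m_ps", "tau1_ps", "tau2_ps", "a1", "g", "s"),
                      colnames(tab))
  res <- .cleanOnFail(out, {
    res <- do.call(rbind, lapply(params, function(p) {
      ok <- is.finite(tab[[p]])
      cbind(parameter = p, oneWayAnova(tab[[p]][ok], tab[[factorCol]][ok]))
    }))
    writeResults(res, out)
    res
  })
  .writeManifest(paste0(out, ".manifest.json"), "anova",
                 list(fits = fitsPath, factor = factorCol),
                 list(n_parameters = nrow(res)))
  invisible(list(anova = out))
}

.pipe_compare_pixelwise <- function(config) {
  cubePath <- .needFile(.cfg(config, "cube", required = TRUE), "cube")
  maskPath <- .needFile(.cfg(config, "mask", required = TRUE), "mask")
  out <- .cfg(config, "out", required = TRUE)
  cfg <- fitConfig(minPhotons = .cfg(config, "min_photons", 300),
                   irfFwhmPs = .cfg(config, "irf_fwhm", 120))
  cmp <- comparePixelwise(readCube(cubePath), readMask(maskPath), cfg,
                          kernelPx = .cfg(config, "kernel", 7L))
  .cleanOnFail(out, {
    writeResults(cmp$summary, out)
    writeResults(cmp$icc, sub("\\.csv$", "_icc.csv", out))
  })
  .writeManifest(paste0(out, ".manifest.json"), "compare-pixelwise",
                 list(cube = cubePath, mask = maskPath,
                      kernel = .cfg(config, "kernel", 7L)),
                 list(n_cells = nrow(cmp$per_cell)))
  invisible(list(summary = out))
}
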