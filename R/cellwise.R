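# Pixel coordinates are R-native: 1-based (row, col), row-major semantics
# shared by cubes and masks so that mask perturbations are unambiguous.

#' Label hand-drawn cell outlines
#'
#' Converts a binary outline image (1 on the single-pixel-wide hand-drawn
#' cell borders, 0 elsewhere) into a label mask: every 4-connected background
#' region that is fully enclosed (not connected to the image frame through
#' background) becomes one cell; outline pixels stay 0.
#'
#' @param outline binary matrix; 1 = border pixel.
#' @return A [CellMask-class] with labels 1..K in row-major order of first
#'   appearance.
#' @examples
#' o <- matrix(0L, 9, 9); o[3:7, 3] <- o[3:7, 7] <- o[3, 3:7] <- o[7, 3:7] <- 1L
#' max(maskLabels(outlineToLabels(o)))  # one enclosed 3 x 3 interior
#' @export
outlineToLabels <- function(outline) {
  outline <- (outline != 0) * 1L
  if (all(outline == 1L)) stop("no interiors: outline image is all border")
  bg <- EBImage::bwlabel(1L - outline)  # 4-connected components
  bg <- matrix(as.integer(bg), nrow(outline), ncol(outline))
  frame_labels <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
  frame_labels <- setdiff(frame_labels, 0L)
  bg[bg %in% frame_labels] <- 0L
  # relabel densely in row-major order of first appearance
  ids <- unique(as.vector(t(bg)))
  ids <- ids[ids != 0L]
  relab <- integer(max(bg, 1L))
  relab[ids] <- seq_along(ids)
  out <- bg
  out[out > 0L] <- relab[out[out > 0L]]
  cellMask(out)
}

.checkShapes <- function(cube, mask) {
  dc <- dim(cube@counts)
  dm <- dim(maskLabels(mask))
  if (dc[1L] != dm[1L] || dc[2L] != dm[2L])
    stop(sprintf("cube (%d x %d) and mask (%d x %d) shapes differ",
                 dc[1L], dc[2L], dm[1L], dm[2L]))
}

#' Aggregate per-pixel histograms into per-cell decays
#'
#' All photons of the pixels interior to a cell are summed, bin by bin, into a
#' single decay histogram; label-0 border/background pixels contribute to no
#' cell. Cells with any pixel on the outermost pixel ring are partially
#' outside the field of view and are excluded (recorded in
#' `metadata(x)$edge_excluded`). Photon conservation is exact: summed cell
#' histograms account for every photon of every retained label.
#'
#' @param cube a [HistogramCube-class].
#' @param mask a [CellMask-class] of matching pixel dimensions.
#' @param dropEdge exclude frame-touching cells (default `TRUE`).
#' @return A [CellDecaySet-class] (cells x time bins).
#' @export
aggregateCells <- function(cube, mask, dropEdge = TRUE) {
  stopifnot(is(cube, "HistogramCube"), is(mask, "CellMask"))
  .checkShapes(cube, mask)
  lab <- maskLabels(mask)
  d <- dim(cube@counts)
  nb <- d[3L]
  edge <- matrix(FALSE, d[1L], d[2L])
  edge[1L, ] <- edge[d[1L], ] <- edge[, 1L] <- edge[, d[2L]] <- TRUE
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  touches <- vapply(ids, function(k) any(edge[lab == k]), logical(1L))
  names(touches) <- ids
  keep_ids <- if (dropEdge) ids[!touches] else ids
  sel <- lab %in% keep_ids
  if (!any(sel)) {
    hmat <- matrix(0, 0L, nb)
    rd <- S4Vectors::DataFrame(label = integer(), pixel_count = integer(),
                               total_photons = numeric(),
                               touches_edge = logical())
  } else {
    pix <- matrix(cube@counts, d[1L] * d[2L], nb)[which(sel), , drop = FALSE]
    grp <- factor(lab[sel], levels = keep_ids)
    hmat <- rowsum(pix, grp)
    rd <- S4Vectors::DataFrame(
      label = as.integer(keep_ids),
      pixel_count = as.integer(table(grp)),
      total_photons = unname(rowSums(hmat)),
      touches_edge = unname(touches[as.character(keep_ids)]))
  }
  dropped <- ids[touches & dropEdge]
  if (length(dropped))
    message(length(dropped), " cell(s) touching the image frame excluded",
            " (labels in metadata()$edge_excluded)")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = hmat), rowData = rd,
    metadata = list(calibration = cube@calibration,
                    edge_excluded = as.integer(dropped),
                    scan_direction = cube@scanDirection))
  rownames(se) <- as.character(rd$label)
  new("CellDecaySet", se)
}

#' Photon-count intensity image
#'
#' @param cube a [HistogramCube-class].
#' @return Matrix of per-pixel total photon counts (sum over time bins).
#' @export
intensityImage <- function(cube) {
  stopifnot(is(cube, "HistogramCube"))
  d <- dim(cube@counts)
  matrix(rowSums(matrix(cube@counts, d[1L] * d[2L], d[3L])), d[1L], d[2L])
}

.reflectIdx <- function(i, n) {
  # whole-sample symmetric reflection about the first/last pixel
  if (n == 1L) return(rep(1L, length(i)))
  repeat {
    bad <- i < 1L | i > n
    if (!any(bad)) return(i)
    i[i < 1L] <- 2L - i[i < 1L]
    i[i > n] <- 2L * n - i[i > n]
  }
}

#' Gaussian low-pass filter for intensity images
#'
#' Segmentation aid only: the blur is applied to 2-D intensity images to make
#' dim mosaics outlineable, never to histogram data (the function rejects
#' anything but a 2-D matrix). Separable Gaussian with reflective boundaries;
#' a normalized kernel preserves constants exactly.
#'
#' @param intensity 2-D numeric matrix.
#' @param sigmaPx Gaussian sigma in pixels; 0 returns the input unchanged.
#' @return Filtered matrix of the same dimensions.
#' @export
lowPass <- function(intensity, sigmaPx = 1.5) {
  if (!is.matrix(intensity))
    stop("lowPass accepts 2-D intensity images only; ",
         "histogram data must not be filtered")
  if (sigmaPx < 0) stop("sigmaPx must be >= 0")
  if (sigmaPx == 0) return(intensity)
  r <- max(1L, ceiling(4 * sigmaPx))
  w <- exp(-((-r:r)^2) / (2 * sigmaPx^2))
  w <- w / sum(w)
  pass <- function(x, along_rows) {
    n <- if (along_rows) nrow(x) else ncol(x)
    out <- x * 0
    for (k in -r:r) {
      idx <- .reflectIdx(seq_len(n) + k, n)
      out <- out + w[k + r + 1L] *
        (if (along_rows) x[idx, , drop = FALSE] else x[, idx, drop = FALSE])
    }
    out
  }
  pass(pass(intensity, TRUE), FALSE)
}

#' Mask perturbations for segmentation-sensitivity tests
#'
#' `shiftMask` translates all labels by an integer pixel offset with zero fill
#' (vacated pixels become background); `rotateMask90` rotates a square mask
#' 90 degrees counter-clockwise about the image center. Shifting by (0, 0) is
#' the identity, and four successive rotations restore the original mask.
#'
#' @param mask a [CellMask-class].
#' @param dRow,dCol integer shift in rows / columns (positive = down / right).
#' @return A perturbed [CellMask-class].
#' @export
shiftMask <- function(mask, dRow, dCol) {
  stopifnot(is(mask, "CellMask"))
  l <- maskLabels(mask)
  nr <- nrow(l); nc <- ncol(l)
  dRow <- as.integer(dRow); dCol <- as.integer(dCol)
  if (abs(dRow) >= nr || abs(dCol) >= nc)
    stop("shift magnitude must be smaller than the image size")
  out <- matrix(0L, nr, nc)
  src_r <- seq_len(nr) - dRow
  src_c <- seq_len(nc) - dCol
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- l[src_r[ok_r], src_c[ok_c], drop = FALSE]
  cellMask(out)
}

#' @rdname shiftMask
#' @export
rotateMask90 <- function(mask) {
  stopifnot(is(mask, "CellMask"))
  l <- maskLabels(mask)
  if (nrow(l) != ncol(l))
    stop("90 degree rotation about the center requires a square mask")
  cellMask(apply(t(l), 2L, rev))  # counter-clockwise
}

# Truncated (in-bounds) box sum of a matrix over a (2r+1)^2 window,
# via an integral image; exact for integer input.
.boxSum <- function(x, r) {
  nr <- nrow(x); nc <- ncol(x)
  S <- matrix(0, nr + 1L, nc + 1L)
  cs <- apply(x, 2L, cumsum)
  if (nr == 1L) cs <- matrix(cs, 1L, nc)
  cs <- t(apply(cs, 1L, cumsum))
  if (nc == 1L) cs <- matrix(cs, nr, 1L)
  S[-1L, -1L] <- cs
  r1 <- pmax(seq_len(nr) - r, 1L); r2 <- pmin(seq_len(nr) + r, nr)
  c1 <- pmax(seq_len(nc) - r, 1L); c2 <- pmin(seq_len(nc) + r, nc)
  S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
}

#' Pixel-wise kernel pooling (the per-pixel baseline)
#'
#' Replaces each pixel's histogram by the sum over its
#' `kernelPx` x `kernelPx` neighborhood, truncated at the image borders.
#' This is the traditional pixel-based analysis the cell-encircled method is
#' compared against; a kernel of 1 is the identity.
#'
#' @param cube a [HistogramCube-class].
#' @param kernelPx odd positive kernel side (default 7).
#' @return A pooled [HistogramCube-class] of the same dimensions.
#' @export
pixelwisePool <- function(cube, kernelPx = 7L) {
  stopifnot(is(cube, "HistogramCube"))
  kernelPx <- as.integer(kernelPx)
  if (kernelPx < 1L || kernelPx %% 2L == 0L)
    stop("kernelPx must be an odd positive integer")
  if (kernelPx == 1L) return(cube)
  r <- (kernelPx - 1L) %/% 2L
  d <- dim(cube@counts)
  out <- array(0, d)
  for (b in seq_len(d[3L])) out[, , b] <- .boxSum(cube@counts[, , b], r)
  histogramCube(out, cube@calibration, cube@scanDirection)
}

#' Retinal magnification: microns per pixel
#'
#' Converts pixel geometry to retinal microns via the Gaussian-eye scaling
#' 291 um/deg at a 24.46 mm axial length, scaled linearly with the measured
#' axial length.
#'
#' @param meta an [AcquisitionMetadata-class] (axial length, field of view and
#'   image size are used).
#' @param umPerDegEmmetropic scale constant at the reference axial length.
#' @param referenceAxialLengthMm reference axial length in mm.
#' @return Microns per pixel.
#' @export
micronsPerPixel <- function(meta, umPerDegEmmetropic = 291,
                            referenceAxialLengthMm = 24.46) {
  stopifnot(is(meta, "AcquisitionMetadata"))
  if (is.na(meta@axialLengthMm)) stop("axial length is missing")
  (meta@fovDeg / meta@imagePxPerSide) * umPerDegEmmetropic *
    (meta@axialLengthMm / referenceAxialLengthMm)
}

#' Cell area in square microns
#'
#' @param pixelCount number of interior pixels of the cell.
#' @param meta an [AcquisitionMetadata-class].
#' @param ... passed to [micronsPerPixel()].
#' @return Area in um^2: `pixelCount * (um per pixel)^2`.
#' @examples
#' meta <- acquisitionMetadata(axialLengthMm = 24.46, imagePxPerSide = 500)
#' cellAreaUm2(1000, meta)  # ~663.9 um^2
#' @export
cellAreaUm2 <- function(pixelCount, meta, ...) {
  if (any(pixelCount < 0)) stop("pixelCount must be >= 0")
  pixelCount * micronsPerPixel(meta, ...)^2
}

#' Per-cell geometry table
#'
#' @param mask a [CellMask-class].
#' @param meta optional [AcquisitionMetadata-class]; if supplied, areas in
#'   um^2 are added.
#' @return data.frame with `label`, `pixel_count`, `centroid_row`,
#'   `centroid_col` and (with metadata) `area_um2`.
#' @export
cellGeometry <- function(mask, meta = NULL) {
  stopifnot(is(mask, "CellMask"))
  l <- maskLabels(mask)
  ids <- sort(setdiff(unique(as.vector(l)), 0L))
  rows <- row(l); cols <- col(l)
  geo <- data.frame(
    label = ids,
    pixel_count = vapply(ids, function(k) sum(l == k), numeric(1L)),
    centroid_row = vapply(ids, function(k) mean(rows[l == k]), numeric(1L)),
    centroid_col = vapply(ids, function(k) mean(cols[l == k]), numeric(1L)))
  if (!is.null(meta)) geo$area_um2 <- cellAreaUm2(geo$pixel_count, meta)
  geo
}
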