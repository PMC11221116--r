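test_that("closed outlines become labeled interiors; open ones do not", {
  # single closed 5x5 square in a 9x9 frame: one 3x3 interior
  o <- squareOutline(9L, 3L, 3L, 5L)
  mask <- outlineToLabels(o)
  expect_equal(max(maskLabels(mask)), 1L)
  expect_equal(sum(maskLabels(mask) == 1L), 9L)
  expect_true(all(maskLabels(mask)[o == 1L] == 0L))

  # two disjoint closed outlines -> two labels
  o2 <- squareOutline(15L, 2L, 2L, 5L) + squareOutline(15L, 9L, 9L, 5L)
  expect_equal(max(maskLabels(outlineToLabels(o2))), 2L)

  # an open (broken) outline merges with the surround: flood-fill oracle
  o3 <- squareOutline(9L, 3L, 3L, 5L)
  o3[3L, 5L] <- 0L  # break the top edge
  reach <- floodFromFrame(o3)
  expect_true(all(reach[o3 == 0L]))       # oracle: interior leaks out
  expect_equal(max(maskLabels(outlineToLabels(o3))), 0L)

  expect_error(outlineToLabels(matrix(1L, 4, 4)), "no interiors")
})

test_that("aggregation sums member-pixel histograms and drops edge cells", {
  calib <- timingCalibration(nBins = 8L)
  counts <- array(0L, c(5, 5, 8))
  lab <- matrix(0L, 5, 5)
  lab[2, 2:4] <- 1L  # one 3-pixel interior cell
  counts[2, 2, 1:2] <- c(1L, 0L)
  counts[2, 3, 1:2] <- c(2L, 1L)
  counts[2, 4, 1:2] <- c(0L, 4L)
  cds <- aggregateCells(histogramCube(counts, calib), cellMask(lab))
  expect_equal(unname(counts(cds)[1L, 1:2]), c(3, 5))
  expect_equal(SummarizedExperiment::rowData(cds)$total_photons, 8)
  expect_equal(SummarizedExperiment::rowData(cds)$pixel_count, 3L)

  # a cell touching row 1 is dropped and recorded
  lab[1, 1:2] <- 2L
  expect_message(
    cds2 <- aggregateCells(histogramCube(counts, calib), cellMask(lab)),
    "excluded")
  expect_equal(SummarizedExperiment::rowData(cds2)$label, 1L)
  expect_equal(S4Vectors::metadata(cds2)$edge_excluded, 2L)

  # all-zero cube -> zero totals
  lab0 <- matrix(0L, 5, 5); lab0[3, 2:4] <- 1L
  z <- aggregateCells(histogramCube(array(0L, c(5, 5, 8)), calib),
                      cellMask(lab0))
  expect_true(all(SummarizedExperiment::rowData(z)$total_photons == 0))

  expect_error(
    aggregateCells(histogramCube(array(0L, c(4, 5, 8)), calib),
                   cellMask(lab)),
    "shapes differ")
})

test_that("aggregation conserves photons exactly (property, 100 trials)", {
  set.seed(202)
  for (trial in 1:100) {
    nb <- sample(8:12, 1L)
    n <- sample(6:10, 1L)
    cube <- histogramCube(
      array(rpois(n * n * nb, 2), c(n, n, nb)),
      timingCalibration(nBins = as.integer(nb)))
    mask <- randomRectMask(n, sample(2:4, 1L))
    cds <- suppressMessages(aggregateCells(cube, mask))
    lab <- maskLabels(mask)
    kept <- SummarizedExperiment::rowData(cds)$label
    sel <- matrix(lab %in% kept, n, n)
    expect_identical(as.numeric(sum(counts(cds))),
                     as.numeric(sum(counts(cube)[array(sel, dim(cube))])))
    # border pixels (label 0) contribute to no cell
    expect_identical(as.numeric(rowSums(counts(cds))),
                     as.numeric(SummarizedExperiment::rowData(cds)$total_photons))
  }
})

test_that("intensity image and low-pass behave as segmentation aids", {
  cube <- tinyCube()
  ii <- intensityImage(cube)
  expect_equal(ii[2, 3], sum(counts(cube)[2, 3, ]))

  expect_identical(lowPass(ii, 0), ii)
  const <- matrix(3.7, 12, 12)
  expect_equal(lowPass(const, 2), const, tolerance = 1e-9)
  delta <- matrix(0, 21, 21); delta[11, 11] <- 1
  expect_equal(sum(lowPass(delta, 2)), 1, tolerance = 1e-6)
  expect_error(lowPass(ii, -1), ">= 0")
  # histogram data must not pass through the filter
  expect_error(lowPass(counts(cube), 1), "2-D")
})

test_that("mask shift and rotation obey their group identities", {
  set.seed(5)
  mask <- randomRectMask(10L, 3L)
  expect_identical(maskLabels(shiftMask(mask, 0L, 0L)), maskLabels(mask))

  lab <- matrix(0L, 8, 8); lab[3:5, 4] <- 1L
  sh <- shiftMask(cellMask(lab), 1L, 0L)
  expect_equal(which(maskLabels(sh)[, 4] == 1L), 4:6)
  expect_equal(maskLabels(sh)[3, 4], 0L)  # vacated pixel is background

  r <- rotateMask90(mask)
  r4 <- rotateMask90(rotateMask90(rotateMask90(r)))
  expect_identical(maskLabels(r4), maskLabels(mask))
  expect_error(rotateMask90(cellMask(matrix(0L, 3, 4))), "square")

  # shifting a mask by (0,0) leaves aggregation untouched
  cube <- tinyCube(10L, 10L, 8L)
  cds_a <- suppressMessages(aggregateCells(cube, mask))
  cds_b <- suppressMessages(aggregateCells(cube, shiftMask(mask, 0L, 0L)))
  expect_identical(counts(cds_a), counts(cds_b))
})

test_that("pixelwise pooling matches a brute-force neighborhood sum", {
  cube <- tinyCube(5L, 5L, 8L)
  expect_identical(counts(pixelwisePool(cube, 1L)), counts(cube))
  expect_error(pixelwisePool(cube, 4L), "odd")

  ones <- histogramCube(array(1L, c(3, 3, 8)), timingCalibration(nBins = 8L))
  pooled <- pixelwisePool(ones, 3L)
  expect_equal(pooled@counts[2, 2, ], rep(9, 8))
  expect_equal(pooled@counts[1, 1, ], rep(4, 8))  # truncated corner

  # brute-force oracle over every pixel of a random cube
  set.seed(9)
  cube2 <- histogramCube(array(rpois(6 * 6 * 8, 5), c(6, 6, 8)),
                         timingCalibration(nBins = 8L))
  pooled2 <- pixelwisePool(cube2, 3L)
  for (r in 1:6) for (c in 1:6) {
    rr <- max(1, r - 1):min(6, r + 1)
    cc <- max(1, c - 1):min(6, c + 1)
    expect_equal(pooled2@counts[r, c, ],
                 apply(cube2@counts[rr, cc, , drop = FALSE], 3, sum))
  }
})

test_that("cell areas follow the axial-length magnification formula", {
  meta <- acquisitionMetadata(axialLengthMm = 24.46, fovDeg = 1.4,
                              imagePxPerSide = 500L)
  expect_equal(cellAreaUm2(0, meta), 0)
  expect_equal(cellAreaUm2(1000, meta), 1000 * (1.4 * 291 / 500)^2,
               tolerance = 1e-12)
  expect_equal(cellAreaUm2(1000, meta), 663.9, tolerance = 1e-3)
  # doubling the axial length quadruples the area (via the reference ratio)
  expect_equal(micronsPerPixel(meta, referenceAxialLengthMm = 12.23)^2,
               4 * micronsPerPixel(meta)^2)
  expect_error(cellAreaUm2(10, acquisitionMetadata(axialLengthMm = NA)),
               "axial")
})
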