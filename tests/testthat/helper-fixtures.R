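# Fixture builders shared across test files. Everything is generated in code;
# sizes are kept small so the whole suite stays fast.

# A tiny deterministic cube: counts[r, c, b] = r + 10*c + 100*b (non-negative,
# distinct values everywhere).
tinyCube <- function(nr = 6L, nc = 5L, nb = 8L, repHz = 8e7) {
  calib <- timingCalibration(repFrequencyHz = repHz, nBins = nb)
  counts <- array(0L, c(nr, nc, nb))
  for (b in seq_len(nb))
    counts[, , b] <- outer(seq_len(nr), 10L * seq_len(nc), `+`) + 100L * b
  histogramCube(counts, calib)
}

# Closed square outline (border width 1) with its top-left corner at (r0, c0)
# and outer side `side`, drawn into an n x n zero matrix.
squareOutline <- function(n = 9L, r0 = 3L, c0 = 3L, side = 5L) {
  o <- matrix(0L, n, n)
  r1 <- r0 + side - 1L; c1 <- c0 + side - 1L
  o[r0:r1, c(c0, c1)] <- 1L
  o[c(r0, r1), c0:c1] <- 1L
  o
}

# Independent flood-fill oracle: labels of 4-connected zero regions reachable
# from the image frame (returns a logical matrix of frame-connected zeros).
floodFromFrame <- function(outline) {
  n <- nrow(outline); m <- ncol(outline)
  open <- outline == 0L
  reach <- matrix(FALSE, n, m)
  queue <- which(open & (row(outline) %in% c(1L, n) |
                           col(outline) %in% c(1L, m)))
  reach[queue] <- TRUE
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    r <- ((i - 1L) %% n) + 1L; c <- ((i - 1L) %/% n) + 1L
    for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
      if (d[1L] < 1L || d[1L] > n || d[2L] < 1L || d[2L] > m) next
      j <- (d[2L] - 1L) * n + d[1L]
      if (open[j] && !reach[j]) {
        reach[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  reach
}

# Random label mask: k rectangular cells dropped into an n x n zero matrix
# (cells may touch the frame; overlaps resolved by later labels winning).
randomRectMask <- function(n = 8L, k = 3L) {
  lab <- matrix(0L, n, n)
  for (id in seq_len(k)) {
    r0 <- sample.int(n - 1L, 1L); c0 <- sample.int(n - 1L, 1L)
    r1 <- min(n, r0 + sample.int(3L, 1L))
    c1 <- min(n, c0 + sample.int(3L, 1L))
    lab[r0:r1, c0:c1] <- id
  }
  cellMask(lab)
}

# aov-based oracle for the two-way mean squares used by both ICC forms.
aovMeanSquares <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  d <- data.frame(y = as.vector(mat),
                  unit = factor(rep(seq_len(n), k)),
                  meas = factor(rep(seq_len(k), each = n)))
  tab <- suppressWarnings(anova(lm(y ~ unit + meas, data = d)))
  z <- function(v) ifelse(abs(v) < 1e-10, 0, v)  # strip lm round-off junk
  list(msr = z(tab["unit", "Mean Sq"]), msc = z(tab["meas", "Mean Sq"]),
       mse = z(tab["Residuals", "Mean Sq"]), n = n, k = k)
}

# Small synthetic acquisition reused by several files (cached per session).
.simCache <- new.env(parent = emptyenv())
smallSim <- function(pxPerSide = 160L, nBins = 128L, photons = 3000,
                     irfFwhmPs = 0, seed = 11L) {
  key <- paste(pxPerSide, nBins, photons, irfFwhmPs, seed, sep = "_")
  if (is.null(.simCache[[key]]))
    .simCache[[key]] <- simulateAoflio(
      mosaicSpec(imagePxPerSide = pxPerSide),
      calib = timingCalibration(nBins = as.integer(nBins)),
      photonsPerCell = photons, irfFwhmPs = irfFwhmPs, seed = seed)
  .simCache[[key]]
}
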