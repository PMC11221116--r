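test_that("the forward model is normalized, wraps, and has the right limits", {
  calib <- timingCalibration(nBins = 64L)
  # mono-exponential, no background: bins sum exactly to N
  m <- modelDecay(calib, 400, totalCounts = 1e5)
  expect_equal(sum(m), 1e5, tolerance = 1e-10)
  # with background: sum(m) = N + nBins * b
  m2 <- modelDecay(calib, 200, 900, 0.6, 1e5, backgroundPerBin = 3)
  expect_equal(sum(m2), 1e5 + 64 * 3, tolerance = 1e-6 * 1e5)
  # long-lifetime limit: flat profile N / nBins + b
  mflat <- modelDecay(calib, 1e9, totalCounts = 6400, backgroundPerBin = 1)
  expect_equal(mflat, rep(6400 / 64 + 1, 64), tolerance = 1e-4)
  expect_error(modelDecay(calib, -5), "positive")

  # wrapped shape equals an explicit multi-period series sum
  calib2 <- timingCalibration(nBins = 256L)
  tau <- 500
  tPs <- (seq_len(256) - 0.5) * binWidth(calib2) * 1e12
  Tps <- period(calib2) * 1e12
  series <- rowSums(vapply(0:40, function(k) exp(-(tPs + k * Tps) / tau),
                           numeric(256)))
  series <- series / sum(series) * 1000
  expect_equal(modelDecay(calib2, tau, totalCounts = 1000), series,
               tolerance = 1e-10)
})

test_that("IRF convolution preserves total counts and delays the peak", {
  calib <- timingCalibration(nBins = 256L)
  m0 <- modelDecay(calib, 300, totalCounts = 1e5)
  m1 <- modelDecay(calib, 300, totalCounts = 1e5, irfFwhmPs = 120)
  expect_equal(sum(m1), 1e5, tolerance = 1e-6)
  expect_true(all(m1 >= 0))
  expect_lte(max(m1), max(m0))  # blur flattens the peak
})

test_that("mean lifetime is the amplitude-weighted average", {
  expect_equal(meanLifetime(1, 350, 900), 350)
  expect_equal(meanLifetime(0.5, 400, 400), 400)
  expect_equal(meanLifetime(0.6, 100, 500), 260)
  fit <- data.frame(a1 = c(0.6, 1), tau1_ps = c(100, 200),
                    tau2_ps = c(500, 900))
  expect_equal(meanLifetime(fit), c(260, 200))
})

test_that("reduced chi-square matches hand arithmetic and the chi2 law", {
  expect_equal(reducedChiSquare(c(5, 7), c(5, 7), 0), 0)
  expect_equal(reducedChiSquare(c(4, 6), c(5, 5), 0), 0.2)
  expect_error(reducedChiSquare(c(4, 6), c(5, 5), 2), "degrees of freedom")
  # Poisson data from its own model: expectation ~ 1 over many bins
  set.seed(31)
  m <- rep(50, 4000)
  k <- rpois(4000, m)
  expect_equal(reducedChiSquare(k, m, 0), 1, tolerance = 0.08)
})

test_that("noise-free decays are recovered to high accuracy", {
  calib <- timingCalibration()
  cfg <- fitConfig(irfFwhmPs = 0, fitBackground = FALSE)
  hist <- modelDecay(calib, 300, totalCounts = 1e6)
  fit <- fitBiexponential(hist, calib, cfg)
  # mono-exponential truth: both components collapse onto tau
  expect_equal(fit$tau1_ps, 300, tolerance = 0.005)
  expect_equal(fit$tau2_ps, 300, tolerance = 0.005)
  expect_equal(fit$tau_m_ps, 300, tolerance = 0.005)
  expect_equal(fit$a1 + fit$a2, 1, tolerance = 1e-9)
  expect_true(fit$converged)

  # amplitude fraction 0.75 -> photon fraction for the forward model
  hist2 <- modelDecay(calib, 150, 1000, photonFraction(0.75, 150, 1000), 5e5)
  fit2 <- fitBiexponential(hist2, calib, cfg)
  expect_equal(fit2$tau1_ps, 150, tolerance = 0.01)
  expect_equal(fit2$tau2_ps, 1000, tolerance = 0.01)
  expect_equal(fit2$a1, 0.75, tolerance = 0.01)
  expect_true(fit2$tau1_ps <= fit2$tau_m_ps && fit2$tau_m_ps <= fit2$tau2_ps)
})

test_that("the photon threshold rejects sparse histograms", {
  calib <- timingCalibration(nBins = 64L)
  h <- round(modelDecay(calib, 400, totalCounts = 299))
  h[1] <- h[1] + (299 - sum(h))  # exactly 299 photons
  expect_equal(sum(h), 299)
  expect_error(fitBiexponential(h, calib, fitConfig()),
               class = "belowThreshold")
  expect_error(fitBiexponential(rep(0, 64), calib, fitConfig(minPhotons = 1)),
               "zero")
})

test_that("Poisson realizations recover the generating parameters", {
  calib <- timingCalibration()
  truthM <- modelDecay(calib, 120, 900, photonFraction(0.7, 120, 900), 1e4)
  cfg <- fitConfig(irfFwhmPs = 0, fitBackground = FALSE)
  set.seed(77)
  fits <- do.call(rbind, lapply(1:40, function(i)
    fitBiexponential(rpois(256, truthM), calib, cfg)))
  expect_lt(abs(median(fits$tau1_ps) - 120) / 120, 0.10)
  expect_lt(abs(median(fits$tau2_ps) - 900) / 900, 0.10)
  expect_lt(abs(median(fits$a1) - 0.7), 0.05)
})

test_that("fits are invariant to histogram scale and start ordering", {
  calib <- timingCalibration()
  cfg <- fitConfig(irfFwhmPs = 0, fitBackground = FALSE)
  h <- modelDecay(calib, 200, 1100, 0.65, 2e4)
  f1 <- fitBiexponential(h, calib, cfg)
  f5 <- fitBiexponential(5 * h, calib, cfg)
  expect_equal(f5$tau1_ps, f1$tau1_ps, tolerance = 1e-3)
  expect_equal(f5$tau2_ps, f1$tau2_ps, tolerance = 1e-3)
  expect_equal(f5$a1, f1$a1, tolerance = 1e-3)
  expect_equal(f5$tau_m_ps, f1$tau_m_ps, tolerance = 1e-3)
  expect_equal(f5$amplitude, 5 * f1$amplitude, tolerance = 1e-3)
  # output is canonical (tau1 <= tau2) regardless of which start wins
  expect_lte(f1$tau1_ps, f1$tau2_ps)
  set.seed(12)
  k <- rpois(256, h)
  g <- fitBiexponential(k, calib, cfg, polish = 6L)
  expect_lte(g$tau1_ps, g$tau2_ps)
})

test_that("fitCells splits fitted and below-threshold cells", {
  calib <- timingCalibration(nBins = 64L)
  counts <- array(0L, c(8, 8, 64))
  lab <- matrix(0L, 8, 8)
  lab[2, 2:3] <- 1L; lab[4, 2:3] <- 2L; lab[6, 2:3] <- 3L
  shape <- modelDecay(calib, 350, totalCounts = 1)
  put <- function(r, cvec, total) {
    h <- round(shape * total)
    h[1] <- h[1] + total - sum(h)
    counts[r, cvec[1], ] <<- as.integer(h)
  }
  put(2, 2:3, 500L)
  put(4, 2:3, 299L)
  put(6, 2:3, 800L)
  fits <- fitCells(aggregateCells(histogramCube(counts, calib), cellMask(lab)),
                   fitConfig(minPhotons = 300, irfFwhmPs = 0))
  expect_equal(sum(fits$status == "fit"), 2L)
  expect_equal(fits$status[fits$label == 2L], "below_threshold")
  expect_true(all(is.na(fits$tau1_ps[fits$status == "below_threshold"])))
})
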