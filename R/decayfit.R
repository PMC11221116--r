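# Forward model and Poisson maximum-likelihood fitting of bi-exponential
# TCSPC decays. All lifetimes are handled internally in picoseconds for
# numerical conditioning; the record is treated as circular (periodic
# excitation), so the wrap of the slow component into the next period is
# implicit in the normalization.

.fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Periodic Gaussian IRF kernel sampled at bin centers, normalized to sum 1.
.irfKernel <- function(calib, fwhmPs) {
  tPs <- binCenters(calib) * 1e12
  Trec <- calib@nBins * calib@binWidthS * 1e12
  sigma <- .fwhmToSigma(fwhmPs)
  k <- exp(-(tPs)^2 / (2 * sigma^2)) +
    exp(-(tPs - Trec)^2 / (2 * sigma^2)) +
    exp(-(tPs + Trec)^2 / (2 * sigma^2))
  k / sum(k)
}

# Frequency response of IRF convolution plus a fixed circular shift (bins).
# NULL means identity (no IRF, no shift).
.convTransfer <- function(calib, irfFwhmPs, shiftBins) {
  B <- calib@nBins
  if (irfFwhmPs <= 0 && shiftBins == 0) return(NULL)
  H <- if (irfFwhmPs > 0) fft(.irfKernel(calib, irfFwhmPs)) else rep(1 + 0i, B)
  if (shiftBins != 0)
    H <- H * exp(-2i * pi * (seq_len(B) - 1L) * shiftBins / B)
  H
}

.circApply <- function(w, H) {
  if (is.null(H)) return(w)
  Re(fft(fft(w) * H, inverse = TRUE)) / length(w)
}

# Normalized wrapped decay shape at the bin centers: softmax of -t/tau.
# The geometric wrap factor 1/(1 - e^(-T/tau)) cancels in the normalization
# when the bins span one period.
.decayShape <- function(tPs, tauPs) {
  u <- exp(-tPs / tauPs)
  list(w = u / sum(u), u = u, S = sum(u))
}

#' Amplitude and photon fractions of a bi-exponential decay
#'
#' A bi-exponential decay can be weighted in two conventions. The
#' *amplitude* fraction `a1` weights the decay amplitudes at t = 0
#' (`a1 e^(-t/tau1) + a2 e^(-t/tau2)`, `a1 + a2 = 1`) and is the `a1` of the
#' mean-lifetime formula `tau_m = a1 tau1 + a2 tau2`. The *photon* fraction
#' `f1` is the share of detected photons contributed by component 1; since a
#' component's photon yield is amplitude x lifetime,
#' `f1 = a1 tau1 / (a1 tau1 + a2 tau2)`. These helpers convert between the
#' two.
#'
#' @param a1,f1 fraction of component 1 in the respective convention.
#' @param tau1Ps,tau2Ps component lifetimes (any common unit).
#' @return The converted fraction.
#' @examples
#' photonFraction(0.7, 120, 900)            # 0.237...
#' amplitudeFraction(photonFraction(0.7, 120, 900), 120, 900)  # 0.7
#' @export
photonFraction <- function(a1, tau1Ps, tau2Ps) {
  a1 * tau1Ps / (a1 * tau1Ps + (1 - a1) * tau2Ps)
}

#' @rdname photonFraction
#' @export
amplitudeFraction <- function(f1, tau1Ps, tau2Ps) {
  (f1 / tau1Ps) / (f1 / tau1Ps + (1 - f1) / tau2Ps)
}

#' Expected bi-exponential TCSPC histogram
#'
#' Forward model: `m_i = N * (f1 * w(t_i; tau1) + (1 - f1) * w(t_i; tau2)) +
#' b`, where `w` is the periodically wrapped, optionally IRF-convolved decay
#' shape normalized so its bins sum to 1; hence `sum(m) = N + nBins * b`.
#' Because each `w` integrates to one photon, `f1` here is the *photon*
#' fraction of component 1; use [photonFraction()] to convert an amplitude
#' fraction `a1` before calling.
#'
#' @param calib a [TimingCalibration-class].
#' @param tau1Ps,tau2Ps component lifetimes in ps (must be positive).
#' @param f1 photon fraction of component 1, in `[0, 1]`.
#' @param totalCounts total model photons N.
#' @param backgroundPerBin constant offset b per bin.
#' @param irfFwhmPs Gaussian IRF FWHM in ps (0 = none).
#' @param shiftBins fixed circular timing shift in bins.
#' @return Numeric vector of expected counts per bin.
#' @export
modelDecay <- function(calib, tau1Ps, tau2Ps = tau1Ps, f1 = 1,
                       totalCounts = 1, backgroundPerBin = 0,
                       irfFwhmPs = 0, shiftBins = 0) {
  stopifnot(is(calib, "TimingCalibration"))
  if (tau1Ps <= 0 || tau2Ps <= 0) stop("lifetimes must be positive")
  if (f1 < 0 || f1 > 1) stop("f1 must lie in [0, 1]")
  tPs <- binCenters(calib) * 1e12
  H <- .convTransfer(calib, irfFwhmPs, shiftBins)
  w1 <- .circApply(.decayShape(tPs, tau1Ps)$w, H)
  w2 <- if (f1 < 1) .circApply(.decayShape(tPs, tau2Ps)$w, H) else w1
  # clip FFT round-off: the exact model is strictly non-negative
  pmax(totalCounts * (f1 * w1 + (1 - f1) * w2) + backgroundPerBin, 0)
}

#' Amplitude-weighted mean lifetime
#'
#' `tau_m = a1 * tau1 + a2 * tau2` with `a1 + a2 = 1`; always lies between
#' the two component lifetimes.
#'
#' @param fit a fit result (row(s) with `a1`, `tau1_ps`, `tau2_ps`), or a
#'   numeric `a1` if `tau1Ps`/`tau2Ps` are given directly.
#' @param tau1Ps,tau2Ps component lifetimes when calling with plain numbers.
#' @return Mean lifetime(s) in ps.
#' @examples
#' meanLifetime(0.6, 100, 500)  # 260
#' @export
meanLifetime <- function(fit, tau1Ps = NULL, tau2Ps = NULL) {
  if (is.numeric(fit) && !is.null(tau1Ps))
    return(fit * tau1Ps + (1 - fit) * tau2Ps)
  fit$a1 * fit$tau1_ps + (1 - fit$a1) * fit$tau2_ps
}

#' Pearson reduced chi-square of a fitted histogram
#'
#' `sum((k_i - m_i)^2 / m_i)` over bins with model expectation `m_i >= 1`
#' (the Pearson statistic is unstable at near-zero expectation), divided by
#' the number of included bins minus the number of free parameters.
#'
#' @param hist observed counts.
#' @param modelCounts fitted expectations, same length.
#' @param nFreeParams number of fitted parameters.
#' @return Reduced chi-square value (>= 0).
#' @export
reducedChiSquare <- function(hist, modelCounts, nFreeParams) {
  stopifnot(length(hist) == length(modelCounts))
  inc <- modelCounts >= 1
  dof <- sum(inc) - nFreeParams
  if (dof <= 0) stop("non-positive degrees of freedom in reduced chi-square")
  sum((hist[inc] - modelCounts[inc])^2 / modelCounts[inc]) / dof
}

# Poisson negative log-likelihood (up to the k! constant) and its gradient in
# the working parameterization p = (log tau1, log tau2, f1, log N [, log b]).
# A one-slot cache avoids recomputing the model when optim asks for the
# gradient at the point it just evaluated.
.makeObjective <- function(k, tPs, H, fitBackground) {
  B <- length(k)
  cache <- new.env(parent = emptyenv())
  cache$p <- NULL
  compute <- function(p) {
    if (!is.null(cache$p) && identical(p, cache$p)) return(cache$val)
    tau1 <- exp(p[1L]); tau2 <- exp(p[2L]); f1 <- p[3L]; N <- exp(p[4L])
    b <- if (fitBackground) exp(p[5L]) else 0
    s1 <- .decayShape(tPs, tau1); s2 <- .decayShape(tPs, tau2)
    W1 <- .circApply(s1$w, H); W2 <- .circApply(s2$w, H)
    m <- N * (f1 * W1 + (1 - f1) * W2) + b
    m <- pmax(m, 1e-12)
    r <- 1 - k / m
    dshape <- function(s, tau) {
      du <- s$u * tPs / tau^2
      .circApply((du - s$w * sum(du)) / s$S, H)
    }
    g <- c(
      sum(r * N * f1 * dshape(s1, tau1)) * tau1,
      sum(r * N * (1 - f1) * dshape(s2, tau2)) * tau2,
      sum(r * N * (W1 - W2)),
      sum(r * (m - b)))
    if (fitBackground) g <- c(g, sum(r) * b)
    val <- list(nll = sum(m) - sum(k * log(m)), grad = g)
    cache$p <- p; cache$val <- val
    val
  }
  list(fn = function(p) compute(p)$nll, gr = function(p) compute(p)$grad)
}

.belowThreshold <- function(total, minPhotons) {
  stop(errorCondition(
    sprintf("histogram has %g photons, below the %g-photon threshold",
            total, minPhotons),
    class = c("belowThreshold", "cellFLIMError")))
}

#' Fit a bi-exponential decay by Poisson maximum likelihood
#'
#' Maximizes the Poisson log-likelihood `sum(k_i * log(m_i) - m_i)` of the
#' forward model [modelDecay()] over `(tau1, tau2, f1, N[, b])`, multi-started
#' from a log-spaced lifetime grid (deterministic, no randomness). The
#' optimization runs in the photon-fraction parameterization (well
#' conditioned); the reported `a1` is the *amplitude* fraction of the short
#' component (see [amplitudeFraction()]), matching the mean-lifetime formula
#' `tau_m = a1 tau1 + a2 tau2`. The result is canonicalized so
#' `tau1 <= tau2` and carries the mean lifetime, the Pearson reduced
#' chi-square and a convergence flag. Histograms below the photon threshold
#' raise a `belowThreshold` condition rather than returning a fit.
#'
#' @param hist integer vector of observed counts, one per time bin.
#' @param calib a [TimingCalibration-class] matching `length(hist)`.
#' @param config a [FitConfig-class].
#' @param polish number of best grid starts refined by the optimizer.
#' @return One-row data.frame with columns `tau1_ps`, `tau2_ps`, `a1`, `a2`,
#'   `tau_m_ps`, `amplitude`, `background`, `shift_bins`, `chi2_reduced`,
#'   `n_photons`, `converged`.
#' @export
fitBiexponential <- function(hist, calib, config = fitConfig(), polish = 3L) {
  stopifnot(is(calib, "TimingCalibration"), is(config, "FitConfig"))
  if (length(hist) != calib@nBins)
    stop("histogram length does not match calibration nBins")
  if (any(hist < 0)) stop("histogram counts must be non-negative")
  total <- sum(hist)
  if (total == 0) stop("all-zero histogram cannot be fitted")
  if (total < config@minPhotons) .belowThreshold(total, config@minPhotons)

  tPs <- binCenters(calib) * 1e12
  H <- .convTransfer(calib, config@irfFwhmPs, config@shiftBins)
  obj <- .makeObjective(as.numeric(hist), tPs, H, config@fitBackground)
  B <- calib@nBins
  lo <- config@tauBoundsPs[1L]; hi <- config@tauBoundsPs[2L]

  # deterministic starts: log-spaced lifetimes inside the bounds
  ng <- max(2L, round(sqrt(config@nStarts)))
  grid <- exp(seq(log(max(lo, 20)), log(min(hi, 6000)), length.out = ng))
  sm <- stats::filter(as.numeric(hist), rep(1 / 5, 5), circular = TRUE)
  b0 <- if (config@fitBackground) max(1e-3, 0.5 * min(sm)) else 0
  N0 <- max(total - B * b0, 10)
  starts <- expand.grid(t1 = grid, t2 = grid)
  starts <- starts[starts$t1 <= starts$t2, , drop = FALSE]
  mkp <- function(t1, t2) {
    p <- c(log(t1), log(t2), 0.5, log(N0))
    if (config@fitBackground) p <- c(p, log(b0))
    p
  }
  scores <- mapply(function(t1, t2) obj$fn(mkp(t1, t2)),
                   starts$t1, starts$t2)
  ord <- order(scores)[seq_len(min(polish, nrow(starts)))]

  lower <- c(log(lo), log(lo), 1e-4, log(N0) - 8)
  upper <- c(log(hi), log(hi), 1 - 1e-4, log(N0) + 8)
  if (config@fitBackground) {
    lower <- c(lower, log(1e-6))
    upper <- c(upper, log(max(max(hist), 1)))
  }
  best <- NULL
  for (i in ord) {
    fit <- tryCatch(
      optim(mkp(starts$t1[i], starts$t2[i]), obj$fn, obj$gr,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = config@maxIter,
                           factr = config@tolerance / .Machine$double.eps)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("optimization failed from every start")

  p <- best$par
  tau1 <- exp(p[1L]); tau2 <- exp(p[2L]); f1 <- p[3L]; N <- exp(p[4L])
  b <- if (config@fitBackground) exp(p[5L]) else 0
  if (tau1 > tau2) {  # canonical order: short component first
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
    f1 <- 1 - f1
  }
  m <- modelDecay(calib, tau1, tau2, f1, N, b,
                  config@irfFwhmPs, config@shiftBins)
  nfree <- 4L + as.integer(config@fitBackground)
  chi2 <- tryCatch(reducedChiSquare(hist, m, nfree), error = function(e) NA_real_)
  a1 <- amplitudeFraction(f1, tau1, tau2)
  data.frame(tau1_ps = tau1, tau2_ps = tau2, a1 = a1, a2 = 1 - a1,
             tau_m_ps = a1 * tau1 + (1 - a1) * tau2, amplitude = N,
             background = b, shift_bins = config@shiftBins,
             chi2_reduced = chi2, n_photons = total,
             converged = best$convergence == 0L)
}

#' Fit all cells of a decay set
#'
#' Applies [fitBiexponential()] to every aggregated cell histogram at or
#' above the photon threshold; cells below it are reported with status
#' `"below_threshold"` and `NA` parameters, mirroring the exclusion count a
#' run log would show.
#'
#' @param cds a [CellDecaySet-class].
#' @param config a [FitConfig-class].
#' @param polish optimizer starts refined per cell (see [fitBiexponential()]).
#' @return data.frame with one row per cell: `label`, `pixel_count`,
#'   `status` (`"fit"` or `"below_threshold"`) and the fit columns.
#' @export
fitCells <- function(cds, config = fitConfig(), polish = 2L) {
  stopifnot(is(cds, "CellDecaySet"))
  calib <- calibration(cds)
  rd <- SummarizedExperiment::rowData(cds)
  hmat <- counts(cds)
  empty <- data.frame(tau1_ps = NA_real_, tau2_ps = NA_real_, a1 = NA_real_,
                      a2 = NA_real_, tau_m_ps = NA_real_,
                      amplitude = NA_real_, background = NA_real_,
                      shift_bins = NA_real_, chi2_reduced = NA_real_,
                      n_photons = NA_real_, converged = NA)
  res <- lapply(seq_len(nrow(hmat)), function(i) {
    h <- hmat[i, ]
    if (sum(h) < config@minPhotons) {
      out <- empty
      out$n_photons <- sum(h)
      out$status <- "below_threshold"
    } else {
      out <- fitBiexponential(h, calib, config, polish = polish)
      out$status <- "fit"
    }
    out
  })
  res <- do.call(rbind, res)
  cbind(data.frame(label = rd$label, pixel_count = rd$pixel_count), res)
}
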