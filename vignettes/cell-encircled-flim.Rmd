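---
title: "Cell-encircled FLIM analysis: models, parameters and design choices"
author: "cellFLIM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-encircled FLIM analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the measurement model, the estimators, the tunable parameters with their
defaults and units, what the synthetic generator does and does not emulate,
and the design choices made where more than one defensible option existed.

## The measurement model

Adaptive-optics fluorescence lifetime ophthalmoscopy records, per pixel, a
TCSPC histogram: photon arrival delays relative to the 80 MHz excitation
pulse train, binned over one 12.5 ns period. A `HistogramCube` is the
rows x cols x bins array of counts plus a `TimingCalibration` (repetition
frequency, bin count, bin width). The time coordinate of bin *i* is its
center, `t_i = (i - 0.5) * binWidth`: for symmetric binning this makes the
first-harmonic phase unbiased, which matters for phasors.

Because the bin count of the original acquisition hardware is not a
universal constant, the default calibration uses 256 bins spanning one
period (48.828 ps per bin) — a common TCSPC setting that leaves at least
five bins per 300 ps lifetime — and every reader requires the calibration
to be explicit (HDF5 group or YAML sidecar). A cube whose third dimension
disagrees with its calibration is rejected at load time.

## Cell-encircled aggregation

The segmentation is a label image: 0 encodes background *and* the
single-pixel hand-drawn borders, k > 0 the interior of cell k.
`outlineToLabels()` converts a binary outline drawing to labels by
4-connected flood fill: every enclosed background region becomes one cell,
and any region connected to the image frame through background is left
unlabeled (an open outline therefore yields no cell — the conservative
choice for hand-drawn data).

`aggregateCells()` sums member-pixel histograms bin by bin; border pixels
contribute to no cell, so no photon is double counted, and photon
conservation over retained labels is exact in integer arithmetic. "Partially
outside the field of view" is operationalized as *any member pixel on the
outermost pixel ring* — frame truncation is the only clipping detectable
from the mask alone — and such cells are dropped with their labels recorded
in the object metadata.

Two auxiliary operations support the surrounding workflow. A Gaussian
low-pass filter (`lowPass`, default sigma 1.5 px, reflective boundaries,
normalized kernel so constants are preserved exactly) exists purely as a
segmentation aid for dim mosaics; it accepts 2-D intensity images only, so
histogram data cannot be filtered by construction. `pixelwisePool()`
implements the traditional per-pixel baseline: each pixel's histogram is
replaced by the truncated in-bounds sum over a `k x k` neighborhood
(default 7), computed exactly via integral images.

Pixel geometry converts to retinal microns through the Gaussian-eye scaling
291 um/deg at a 24.46 mm axial length, scaled linearly with the measured
axial length; the constant is an argument, not a hard-coded truth.

## Bi-exponential Poisson maximum likelihood

The forward model for expected counts is

```
m_i = N * ( f1 * w(t_i; tau1) + (1 - f1) * w(t_i; tau2) ) + b
```

where `w(t; tau)` is the periodically wrapped decay shape, normalized so
its bins sum to 1, optionally circularly convolved with a Gaussian
instrument response (default FWHM 120 ps, covering the 50 ps pulse plus
detector response; 0 disables it). Because the bins span one period, the
geometric wrap factor cancels in the normalization and `w` is simply the
softmax of `-t/tau`. Two weighting conventions coexist in FLIM practice:
`f1` above multiplies photon-normalized shapes and is therefore the
*photon* fraction, while the reported `a1` of the mean-lifetime formula
`tau_m = a1*tau1 + a2*tau2` (with `a1 + a2 = 1`) is the *amplitude*
fraction; the two are related by `f1 = a1*tau1 / (a1*tau1 + a2*tau2)` and
the package exposes `photonFraction()` / `amplitudeFraction()` to convert.
Fits run in the photon-fraction parameterization, which is well
conditioned, and report amplitude fractions.

`fitBiexponential()` minimizes the Poisson negative log-likelihood
`sum(m_i - k_i log m_i)` over `(log tau1, log tau2, f1, log N[, log b])`
with L-BFGS-B and an analytic gradient, multi-started from a 4 x 4
log-spaced lifetime grid (deterministic — no RNG in fitting); the best
`polish` starts are refined and the winner reported, canonicalized to
`tau1 <= tau2`. Defaults: lifetime bounds 10–12000 ps, background fitted
(dark counts exist in real detectors; fix it to 0 when simulating without
background), 300-photon minimum per histogram (below it a `belowThreshold`
condition is raised and the cell counted as excluded, never silently
dropped).

Goodness of fit is the Pearson reduced chi-square over bins with model
expectation of at least 1 photon (the statistic is unstable at near-zero
expectation), with `n_free = 4 + fitBackground`. On Poisson data from the
true model it centers on 1.

Degenerate inputs: a mono-exponential truth makes the amplitude split
unidentifiable (`tau1 = tau2` fits equally well at any `f1`); the fit
returns both lifetimes at the common value, so the identifiable quantities
— the lifetimes and `tau_m` — are recovered while `a1` is arbitrary. The
timing offset `shift_bins` is carried as a fixed, config-supplied circular
shift (default 0) rather than a free parameter: with cell-level photon
counts it trades against `tau1` and destabilizes the short component.

## Phasor analysis

`phasorFromHistogram()` evaluates the Fourier transform of the *raw*
histogram at the repetition frequency: `g = Σ k_i cos(ω t_i) / Σ k_i`,
`s = Σ k_i sin(ω t_i) / Σ k_i`, with `ω = 2π f_rep` (harmonic 1 by
default). No fitting, no IRF correction, no reference-dye calibration —
that matches the stated computation; a calibration hook can be layered on
top by rotating/scaling against a reference of known lifetime if an
instrument needs it. Mono-exponential decays lie on the universal
semicircle `g² + s² = g` (`phasorOfMonoexponential()` is the closed-form
oracle), mixtures are photon-weighted averages (`phasorMixture()`), and
scaling a histogram leaves `(g, s)` unchanged. Bin centers, not edges, are
used for `t_i`; with 256 bins the discretization error against the closed
form is below 1e-3 and shrinks with bin count.

## Repeatability and group statistics

The two ICC forms are the single-measure, two-way mixed-effects
coefficients, written out from the mean squares of the crossed
decomposition: consistency `(MSR - MSE) / (MSR + (k-1) MSE)` and absolute
agreement `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE)/n)`. Both carry
the `MSR/MSE` F-test p-value; values are classed poor / moderate / good /
excellent at 0.5 / 0.75 / 0.9 (lower bounds inclusive), with
non-significant ICCs marked `ns`, mirroring how such tables are reported.
Paired comparisons additionally report the mean and SD of `|x1 - x2|` and
of the percent difference; the percent denominator is the pair mean — the
symmetric choice, made once and documented because the convention is often
left unstated.

One-way fixed-factor ANOVA, repeated-measures ANOVA (via the
`Error(subject/condition)` stratum decomposition; at two conditions the
within-effect F equals the squared paired-t statistic) and pooled-variance
t-tests ride on base R. The Holm–Bonferroni step-down is written out:
ascending p-values face `alpha / (m - i + 1)`; with four eccentricity
levels the six pairwise comparisons give the smallest p-value a corrected
threshold of `0.05/6` (0.008 at three decimals). Two-group sample sizes use
the normal approximation `n = ceil(2 (z_{1-alpha/side} + z_{power})² (σ/δ)²)`
with both sidedness options exposed: published n's of this kind are often
irreproducible from a single formula because the calculator is unstated, so
the formula itself is the documented contract.

## The synthetic generator

`generateMosaic()` builds an RPE-like mosaic as the Voronoi tessellation of
a jittered hexagonal lattice, with single-pixel borders set to 0. The
lattice density is compensated for border loss (~1.86·sqrt(area) px per
cell) so the mean *interior* area hits the target, 220 um² by default in a
1.4° field at a 24.46 mm axial length. Jitter (default 0.35 of the lattice
spacing) produces realistic area spread; zero jitter gives a regular
hexagonal mosaic, useful as a symmetry check.

`assignCellTruth()` draws per-cell `(tau1, tau2, a1)` from a channel
palette. Preset means (765/NIR: 150/1000 ps, a1 0.80; 532/LSC: 150/900,
0.75; 473/LSC: 140/850, 0.72; 473/SSC: 130/800, 0.70) are plausibility
values typical of RPE autofluorescence, not fitted estimates. The
cell-to-cell SDs — tau1 15 ps, tau2 40 ps, a1 0.02 — were anchored once to
observed per-image statistics of cell-encircled data (phasor SD of order
0.005–0.01 in g, mean-lifetime spreads of a couple of tens of ps) through
first-order sensitivity of `(g, s)` to the parameters. Eccentricity and age
slopes default to the qualitative in-vivo directions (lifetimes lengthen,
a1 falls) and are study conditions to configure, not estimates.

`renderCube()` gives every interior pixel its cell's expected decay scaled
so the expected cell total equals the photon budget, dims a central nuclear
disk (factor 0.3, radius 30% of the equivalent radius — the bright-border /
dark-interior look that makes RPE cells outlineable), and draws independent
Poisson counts per pixel per bin. Photon presets: "bright" 1e4 per cell and
"threshold" ~350, straddling the 300-photon rule. `simulateVisitPair()`
produces forward/backward-scan or test-retest pairs as two independent
realizations of the same truth; scanner distortion is out of scope, so scan
pairs differ only in noise.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: optical blur and residual aberrations, eye motion,
within-cell fluorophore gradients beyond the nuclear disk, spectral
cross-talk, afterpulsing, and model mismatch (the fitted family *is* the
generating family, which flatters lifetime-component repeatability relative
to real instruments, where the decay is only approximately bi-exponential).

## Problem sizes in the tests

The validation suite runs the full pipeline at sizes chosen to exercise the
science rather than the hardware: fields of 120–200 px for pipeline
contracts, 400 px (the realistic ~20 px-per-cell sampling) wherever the
comparison is geometric — the 7-px kernel baseline and the 1/15-px
mask-shift sensitivity — because a kernel or shift comparable to a whole
cell changes the question being asked, not just the noise level. The
repeatability tiering uses the full default acquisition model (256 bins,
120 ps IRF, fitted background) at 1000 photons per cell with 200 matched
cells; the power property uses 50 replicates of two 100-cell groups
separated by one cell-SD in tau1. `scripts/acceptance.R` recomputes all of
these from scratch from a single `--seed`.

## Known limitations

- The amplitude split of near-mono-exponential decays is unidentifiable;
  interpret `a1` only when the components are separated.
- The Pearson chi-square excludes bins with expectation below 1; for very
  low-count histograms few bins remain and the statistic is coarse.
- PNG mask export is 8-bit (labels up to 255); use TIFF for larger mosaics.
  16-bit PNGs produced elsewhere are read correctly.
- The native acquisition format of commercial TCSPC hardware is not parsed;
  cubes enter through the documented HDF5 layout or multi-frame TIFF.
- Matching across visits is by shared label only; registration and rotation
  between visits are out of scope.
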