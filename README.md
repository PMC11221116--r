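# cellFLIM

Cell-encircled fluorescence-lifetime analysis for adaptive-optics
fluorescence lifetime imaging ophthalmoscopy (AOFLIO) of the retinal pigment
epithelium (RPE).

## The problem

AOFLIO resolves individual RPE cells in the living human eye and records, at
every pixel, a time-correlated single-photon counting (TCSPC) histogram of
photon arrival delays after each 80 MHz excitation pulse. Fitting decay
models per pixel (or per small pixel kernel) is noisy: each pixel holds few
photons. Because the RPE is a mosaic of discrete cells, a biologically
natural alternative is to sum all photons inside each hand-segmented cell
into a single high-count histogram and analyze decays *per cell*.

cellFLIM implements that cell-encircled analysis end to end, for researchers
working with AOFLIO/FLIM data of cellular mosaics:

- **Aggregation** — apply a label mask (0 = background and the single-pixel
  hand-drawn borders) to a TCSPC cube; sum member-pixel histograms per cell;
  exclude cells partially outside the field of view; exact photon
  conservation.
- **Decay fitting** — bi-exponential model fitted by Poisson maximum
  likelihood: expected counts
  `m_i = N (f1 w(t_i; tau1) + (1 - f1) w(t_i; tau2)) + b`, with `w` the
  periodically wrapped, optionally Gaussian-IRF-convolved decay shape;
  deterministic multi-start optimization; mean lifetime
  `tau_m = a1 tau1 + a2 tau2` (`a1 + a2 = 1`); Pearson reduced chi-square;
  a 300-photon minimum threshold per histogram.
- **Phasor analysis** — first-harmonic Fourier coordinates of the raw
  histogram at the laser repetition frequency:
  `g = sum(k_i cos(w t_i)) / sum(k_i)`, `s = sum(k_i sin(w t_i)) / sum(k_i)`;
  mono-exponential decays lie on the universal semicircle `g^2 + s^2 = g`.
- **Statistics** — two-way mixed-effects intraclass correlations
  (consistency and absolute agreement, single measure) with the
  poor/moderate/good/excellent bands at 0.5/0.75/0.9; absolute and percent
  paired differences; fixed-factor and repeated-measures ANOVA; unpaired
  t-tests with Holm-Bonferroni correction; z-approximation two-group sample
  sizes; linear trends.
- **Synthetic generator** — photon-level AOFLIO simulator with full ground
  truth: Voronoi RPE mosaics (jittered hexagonal lattice, ~220 um^2 mean
  cell area, dim nuclear centers), per-cell bi-exponential palettes with
  configurable eccentricity/age slopes, Gaussian IRF, 12.5 ns periodic wrap,
  Poisson noise, forward/backward-scan and test-retest visit pairs.

Data containers follow Bioconductor conventions: S4 classes for cubes,
masks and calibrations, and a `SummarizedExperiment` subclass
(`CellDecaySet`, cells x time bins) for aggregated decays.

## Worked example

```r
library(cellFLIM)

# simulate one acquisition: 200 px field, 256 time bins at 80 MHz,
# 5000 expected photons per cell, 120 ps Gaussian IRF
sim <- simulateAoflio(mosaicSpec(imagePxPerSide = 200L),
                      photonsPerCell = 5000, seed = 42)

cds  <- aggregateCells(sim$cube, sim$mask)   # per-cell histograms
fits <- fitCells(cds)                        # bi-exponential MLE per cell
ph   <- phasorCells(cds, minPhotons = 300)   # raw-histogram phasors

ok <- fits$status == "fit"
summary(fits$tau_m_ps[ok])
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   269.8   321.9   336.9   338.3   353.6   407.4
phasorSummary(ph)
#>      mean_g  mean_s       sd_g       sd_s   n
#> 1 0.8883557 0.26394 0.01121648 0.01369957 525
```

The per-cell mean lifetime centers on `a1*tau1 + a2*tau2` of the generating
palette (0.75 x 150 ps + 0.25 x 900 ps ~ 337 ps), the phasor mean sits at
the matching photon-weighted mixture point, and the per-image phasor SD pair
(`sd_g`, `sd_s`) is the quantity the method shrinks relative to pixel-wise
analysis. Merging `fits` with `sim$truth` by `label` gives per-cell recovery
errors against ground truth.

A repeatability comparison across two simulated visits:

```r
pair <- simulateVisitPair(sim$mask, sim$truth, seeds = c(1L, 2L))
a <- analyzeCells(pair$cube1, sim$mask)
b <- analyzeCells(pair$cube2, sim$mask)
repeatabilityReport(a, b, model = "agreement")
#>   parameter icc_value icc_class mean_abs_diff mean_pct_diff n_units
#> 1  tau_m_ps 0.7273861  moderate   14.59228485     4.3365696     525
#> 2   tau1_ps 0.6618538  moderate   12.45390206     8.3131444     525
#> 3   tau2_ps 0.6965190  moderate   26.72459551     2.9738299     525
#> 4        a1 0.6596784  moderate    0.01641539     2.1950475     525
#> 5         g 0.8937319      good    0.00409932     0.4620208     525
#> 6         s 0.9113909 excellent    0.00461046     1.7511680     525
```

The phasor coordinates repeat across visits better than the exponential
components — the property that motivates phasor analysis for longitudinal
cell tracking.

## Command line

A thin CLI over the same functions:

```sh
Rscript inst/scripts/cellkit.R simulate --out sim.h5 --photons 5000 --seed 7
Rscript inst/scripts/cellkit.R aggregate --cube sim.h5 --mask sim_mask.tif --out cells.csv
Rscript inst/scripts/cellkit.R fit --cells cells.csv --min-photons 300 --out fits.csv
Rscript inst/scripts/cellkit.R phasor --cells cells.csv --out phasor.csv
```

Subcommands: `simulate`, `aggregate`, `fit`, `phasor`, `repeat`, `anova`,
`compare-pixelwise`. Every run writes a JSON manifest with the package
version, seed, thresholds and exclusion counts.

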