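# smdmr

Single-molecule displacement mapping (SMdM) of protein diffusion in small,
confined cells such as bacteria.

SMdM pairs two short excitation pulses across consecutive camera frames so
that every photoactivated emitter is localized twice, a fixed 1.5-ms lag
apart. Accumulating millions of such displacements, binned by their starting
position, yields spatial maps of the diffusion coefficient at 50–200 nm
resolution — fine enough to compare the center of a bacterium with its
poles. The catch is that inside a ~1 × 2 µm compartment a 1.5-ms lag is
long: molecules reflect off the membrane within a single observation, so
the fitted coefficient systematically underestimates the true one, worst
near the boundary. This package implements both halves of the problem: the
analysis chain for localization streams, and the confined-diffusion
simulations that quantify how much of an observed slowdown is mere geometry.

The core model is the truncated Rayleigh displacement density with a linear
mispairing background,

    p(r) = [1 - exp(-r_max^2/4DΔt) + k r_max^2/2]^(-1)
           [ (2r/4DΔt) exp(-r^2/4DΔt) + k r ],   0 ≤ r ≤ r_max,

fitted by maximum likelihood for the diffusion coefficient `D` (µm²/s) and
background slope `k` (nm⁻²), with `r_max = 600` nm and `Δt = 1.5` ms by
default. Downstream, measured coefficients are related to the mass of the
diffusing complex by a power law `D = α·M_complex^β` and to a perceived
cytoplasmic viscosity through the Einstein–Stokes relation.

For whom: microscopists analysing SMdM/SMLM localization tables from
bacteria or other confined geometries, and anyone needing a reflective-
spherocylinder Brownian-dynamics baseline for confinement bias.

## What is in the box

- `pairFrames()`, `pairPeaks()`, `extractDisplacements()` — stroboscopic
  frame pairing and all-pairs peak matching within 600 nm.
- `clusterCells()`, `rotateToMajorAxis()`, `qcFilter()`,
  `partitionRegions()` — Voronoi-density segmentation, major-axis rotation,
  2,000–20,000 displacement QC, 20%-length pole regions.
- `fitMLE()`, `fitPixelMap()`, `fitRegions()`, `dFromRMSD()` — the MLE and
  per-pixel / per-region diffusion maps.
- `simulateConfinedWalk()`, `extractLagDisplacements()`,
  `confinementBias()`, `poleCenterEnsemble()` — reflective-spherocylinder
  simulation and confinement benchmarks.
- `synthesizeLocalizationStream()`, `generateCellPopulation()`,
  `generateProteinPanel()` — synthetic data with ground-truth labels.
- `complexMass()`, `loneliness()`, `spearmanCorrelation()`,
  `fitPowerLaw()`, `perceivedViscosity()`, `poleCenterRatio()` plus rank
  tests — the scaling statistics, and `loadProteinPanel()` for the packaged
  12-construct measurement panel.
- `runPipeline()` — the whole chain on a localization table, with a
  manifest and per-stage log.

## Worked example

```r
library(smdmr)

panel <- loadProteinPanel()
spearmanCorrelation(panel$complex_mass_kda, panel$d_mean)
#> $r
#> [1] -0.8791607
#> $p
#> [1] 0.00016599

native <- panel[!panel$heterologous, ]
fitPowerLaw(native$complex_mass_kda, native$d_mean, sd = native$d_sd)
#> PowerLawFit: D = 68.5 * M^-0.539 (SE alpha 14.7, beta 0.051), SD-weighted
```

Diffusion across the panel falls steeply and monotonically with the mass of
the tagged complex (Spearman r ≈ −0.88), and the weighted power-law fit
over the ten non-heterologous constructs gives an exponent of −0.54 ± 0.05 —
much steeper than the −1/3 expected for a globular particle in a Newtonian
fluid, the signature of mass-dependent ("perceived") cytoplasmic viscosity.

How much of a measured pole-versus-center slowdown is just the membrane?

```r
confinementBias(c(1, 5), seed = 1)[, c("d_sim", "ratio_compartment", "ratio_center")]
#>   d_sim ratio_compartment ratio_center
#> 1     1             0.951        1.004
#> 2     5             0.895        0.943
```

At an input of 5 µm²/s the compartment-wide estimate in a median cell
(0.45 µm radius, 2.25 µm length) is already ~10% low while the centermost
150 × 100 nm patch is still within ~6%; `poleCenterEnsemble()` extends this
to a heterogeneous population and shows confinement alone drives the
pole/center ratio to ≈0.90–0.94 — a measured ratio well below that indicates
genuinely slower diffusion at the poles.

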