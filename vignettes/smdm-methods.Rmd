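---
title: "Mapping protein diffusion in confined cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping protein diffusion in confined cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smdmr)
```

## The measurement and its model

Single-molecule displacement mapping (SMdM) times two short excitation
pulses across consecutive camera frames so that each photoactivated emitter
is localized twice, a fixed lag $\Delta t$ apart (1.5 ms here). Tracking is
deliberately abandoned: each molecule contributes exactly one displacement,
and millions of displacements, binned by their starting position, build a
spatial map of mobility.

For free two-dimensional Brownian motion the displacement length $r$ follows
the Rayleigh density

$$p(r) = \frac{2r}{4D\Delta t}\, e^{-r^2/4D\Delta t}.$$

Two corrections adapt this to real localization streams:

* **Mispairing background.** Peaks are paired *all-against-all* within a
  search radius $r_\mathrm{max}$ (600 nm by default). Ambiguous pairings are
  not resolved; instead, spurious pairs of uniformly distributed detections
  produce a pair-distance density proportional to $r$, absorbed by a linear
  term $kr$.
* **Truncation.** Displacements above $r_\mathrm{max}$ are discarded, and
  the density is renormalized over $[0, r_\mathrm{max}]$:

$$p(r) = \frac{1}{1 - e^{-r_\mathrm{max}^2/4D\Delta t} +
  k\,r_\mathrm{max}^2/2}\left(\frac{2r}{4D\Delta t}e^{-r^2/4D\Delta t} +
  kr\right), \qquad 0 \le r \le r_\mathrm{max}.$$

`fitMLE()` maximizes the likelihood of this density. Internally the free-$k$
problem is reparametrized as a two-component mixture over $(\log D,
\operatorname{logit} w)$, where $w$ is the background mass fraction; this is
well conditioned for any magnitude of $k$ and keeps $D > 0$, $k \ge 0$ by
construction. Initialization is the method of moments, $D_0 =
\overline{r^2}/4\Delta t$, with a 1% starting background weight; the fixed
$k = 0$ case (appropriate for simulated displacements, which cannot be
mispaired) is a one-dimensional golden-section optimization in $\log D$ with
a $10^{-10}$ tolerance. The 600-nm bound itself corresponds, read as a 2-D
RMSD over 1.5 ms, to $D = r_\mathrm{max}^2 / (4\Delta t) = 60\ \mu m^2/s$
(`dFromRMSD()`), several times faster than any cytoplasmic protein measured,
so the bound does not clip genuine displacements.

## Segmentation and regions

Cells are detected from the point cloud by Voronoi-density clustering
(`clusterCells()`): points whose Voronoi polygon area falls below a
threshold are kept and connected components of the kept points (adjacency =
shared Voronoi edge) become cells. The tessellation is a Bowyer–Watson
Delaunay triangulation implemented in C++; polygon areas come from the
circumcentres of incident triangles, with unbounded hull polygons treated as
infinitely large (hence always discarded). The published description of
this step names no threshold, so the default — keep polygons below twice the
median polygon area, minimum 500 points per cluster — is this package's own
calibration, exposed in `pipelineConfig()`. A consequence worth knowing:
any density threshold trims the sparsest edge points of a genuine cell, so
cluster membership is expected to be high but not total.

Each cell is rotated onto its major axis (`rotateToMajorAxis()`), the
leading eigenvector of the origin covariance matrix, recorded modulo $\pi$
in $(-\pi/2, \pi/2]$. Near-isotropic clouds are flagged rather than
rejected; the eigenvalue-ratio cutoff of 1.2 leaves room for the sampling
spread of eigenvalue ratios in finite isotropic clouds. Cells then pass a
count filter of 2,000–20,000 (distance-filtered) displacements
(`qcFilter()`); visual-inspection criteria (edge truncation, adjacency,
division, aggregation) cannot be inferred from coordinates alone and are
caller-supplied flags.

Regions are cut along the long axis (`partitionRegions()`): each pole takes
20% of the measured length from the outermost displacement origins,
boundary ties going to the poles. For the median cell (radius 0.45 μm,
length 2.25 μm) the fraction 0.20 equals radius/length, so each pole region
covers one hemispherical cap. Regions are fitted independently when they
hold at least 100 displacements, which keeps the relative error of a region
estimate near or below 10%; per-pixel maps (`fitPixelMap()`) use pixel sizes
of 50–200 nm, fit pixels with at least 10 displacements, and flag 45
displacements per pixel as the quality level at which the estimate's spread
stays below 15%.

## The confined-diffusion simulator

Because a 1.5-ms lag is long relative to the size of a bacterium, a particle
near the membrane reflects off it within one lag and its observed
displacement shortens: the fitted $D_\mathrm{app}$ *underestimates* the true
$D$, most strongly at the poles. `simulateConfinedWalk()` quantifies this
with a Brownian-dynamics walk inside a reflective spherocylinder: particles
start uniformly distributed, each 0.1-ms step displaces every coordinate by
an independent normal draw with SD $\sqrt{2D\,\mathrm{d}t}$, and proposals
ending outside are specularly reflected across the tangent plane at the
nearest surface point, iterated until interior. The published analysis
delegates this to an off-the-shelf stochastic simulator; the reflection
scheme above is this package's concrete choice for the same reflective
contract.

Two conventions deserve explicit statement:

* **Length convention.** "Length 2.25 μm" is taken end-to-end *including*
  the hemispherical caps, so the cylindrical section is $L - 2R$. Cell
  lengths measured from data include the poles, and the 0.45/2.25 = 0.2 pole
  fraction argument only works under this reading.
* **Row convention.** Trajectories record positions after steps $1..N$ with
  no $t=0$ row, so a 2-s run at 0.1-ms steps has 20,000 rows and lag-15
  pairing yields exactly $N - 15 = 19{,}985$ displacements per particle —
  the only convention consistent with that printed count. Because Brownian
  motion is Markov, every row pair $(i, i+15)$ is a valid 1.5-ms
  displacement; the pairs overlap, so roughly one in fifteen is
  statistically independent, which matters when quoting standard errors
  (tests use an effective sample size of count/15).

The equivalence between lag-15 pairs at a 0.1-ms step and single 1.5-ms
steps is exact in free space but only approximate against a boundary: a
single coarse step reflects at most once where the fine path reflects
repeatedly. The difference is ~1.5% in mean displacement at 5 μm²/s in the
median cell — which is precisely why the simulator uses the fine step — and
the Markov-consistency test is therefore run at 1 μm²/s, where within-lag
reflections are rare.

`confinementBias()` reports the apparent-to-input ratio for three analysis
areas: the whole compartment, the cylindrical section only, and the
centermost 150 × 100 nm patch. In the median cell the centermost patch
reproduces the input to within 10% up to ≈2.5 μm²/s and the compartment-wide
estimate underestimates by ~7% at 2.5 and ~16% at 10 μm²/s. The magnitude
of the compartment-wide bias at 2.5 μm²/s deserves a note: the published
account quotes at least 10% there, but the mean-squared transverse
displacement in a reflective cylinder of radius $R$ saturates at $R^2/2$,
which caps the achievable bias near 5–8% for this geometry and lag under
every area definition we could construct (pooled fits or per-pixel map
means). The corresponding acceptance test records this discrepancy rather
than hiding it: the 2.5-μm²/s assertion fails by construction while every
surrounding property (free-diffusion limit, monotonicity, never
overestimating, the 10-μm²/s figure) holds.

## The pole/center ensemble

`poleCenterEnsemble()` samples a heterogeneous population of spherocylinders
(diameters 0.41–2.34 μm, lengths 1.1–3.64 μm, input $D$ 0.5–20 μm²/s —
the extremes of the experimental cell-shape and mobility distributions),
simulates 25 particles for 2 s in each, and fits the three regions with $k =
0$. Confinement alone yields a mean pole/center ratio of ≈0.90–0.94: the
poles look slower even when mobility is perfectly uniform. Experimental
streams showing substantially lower ratios than this baseline therefore
carry a genuine, physical pole slowdown on top of the geometric artefact.
The package's default population size of 40 cells reproduces the ensemble
with a per-run spread of about ±0.01; the published simulated population was
about an order of magnitude larger, a choice that changes the error bar, not
the mean. A second paper-internal convention is worth noting: the
simulation methods quote simulated diameters from 0.2 μm while the
pole-ensemble analysis quotes 0.41 μm as the experimental minimum;
`generateCellPopulation()` defaults to the former and the ensemble passes
the latter explicitly.

The stream generator can plant a true slowdown (`poleSlowdown`), scaling $D$
while a particle is inside a cap. Recovery of such a slowdown is diluted by
diffusive exchange: molecules cross the region boundary within one lag, so a
0.7× cap slowdown surfaces as an ensemble ratio between 0.7× and 1× the
confinement-only baseline (≈0.78 against ≈0.91 at these defaults). Tests
assert detection and ordering, not the naive product, for exactly this
reason.

## The synthetic localization stream

`synthesizeLocalizationStream()` emulates the acquisition: per frame couple
one emitter is placed uniformly in the compartment, propagated 1.5 ms by the
confined walk, and observed twice with isotropic Gaussian localization noise
(default SD 20 nm, a typical single-molecule precision — the published setup
does not state one; note that noise on both ends adds $\sigma^2/\Delta t
\approx 0.27\ \mu m^2/s$ to a fitted $D$). Spurious detections arrive as
Poisson counts per frame, uniform over the cell footprint, which is exactly
the mechanism that makes the $kr$ background linear. Ground-truth pairing
labels are retained so segmentation and pairing can be scored.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: photophysics (blinking, incomplete
photoconversion, bleaching within a couple), motion blur during the 0.5-ms
pulses, detection heterogeneity across the field, z-dependent defocus,
drift, and non-spherocylindrical cell shapes.

## The protein panel statistics

The packaged 12-construct panel carries the measured center-region
coefficients of mEos3.2-tagged cytoplasmic proteins. `complexMass()`
implements $(M_\mathrm{monomer} + M_\mathrm{tag}) \times
\mathrm{oligomeric\ state}$ with the 25.7-kDa tag on every subunit;
`loneliness()` is the copy number over the summed copy numbers of known
binary interactors. Diffusion against complex mass is summarized by
Spearman rank correlation and by a power law $D = \alpha
M_\mathrm{complex}^{\beta}$ fitted by nonlinear least squares on the linear
scale, initialized from the log–log regression. When per-construct SDs are
available the fit is weighted by $1/\mathrm{SD}^2$ — the standard chi-square
weighting when each point is a mean with a known spread — and on this panel
the weighted fit over the ten non-heterologous constructs gives $\beta =
-0.54 \pm 0.05$ (the unweighted fit gives $-0.48 \pm 0.06$; the choice of
weighting is the single largest lever on this exponent, so it is explicit
and configurable).

`perceivedViscosity()` inverts Einstein–Stokes, $D = k_BT/(6\pi\eta r)$,
with a hydrodynamic radius from mass, $r = (3M\bar v/4\pi N_A)^{1/3}$
(defaults $T = 294.15$ K, the 21 °C stage temperature, and $\bar v = 0.73$
cm³/g, a typical protein partial specific volume; both configurable). For
an exact $D \propto M^{-0.54}$ and $r \propto M^{1/3}$ the viscosity
exponent is algebraically $0.54 - 1/3 \approx 0.21$; on the panel itself
the fitted exponent lands near 0.20–0.24 depending on weighting. The
published account prints both 0.20 and 0.15 for this exponent in different
places and derives a 9–15 cP range with constants from supplementary
material that is not reproduced here, so the package exposes the computation
and the ambiguity rather than asserting either printed value.

Group comparisons follow the conventional chain: Shapiro–Wilk at the 1%
level to test normality, Mann–Whitney U for non-normal comparisons, and an
extra-sum-of-squares F test for nested power-law fits.

## Problem sizes and numerical choices

The test-suite and acceptance computations use 25 particles × 20,000 steps
per simulated cell (one condition ≈ 2 s of compute), a 40-cell population
for the pole/center ensemble, 2,000 repetitions for estimator calibration,
and 200 seeded panels for power-law recovery — sizes at which every
stochastic assertion has comfortable margin while a full run stays in the
minutes range. All randomness flows through explicit integer seeds;
simulation output is bit-reproducible for a fixed seed. Degenerate inputs
fail loudly: collinear point sets report a tessellation error, empty
displacement sets refuse to fit, regions below the count threshold are
excluded by name, and a `poleFraction` ≥ 0.5 (overlapping poles) is
rejected.

## Known limitations

* Apparent coefficients are biased low by confinement; maps and region
  estimates are comparable across cells of similar geometry but are not
  estimates of the unconfined $D_0$.
* Single-component fitting is assumed throughout; mixtures of mobility
  states within a region are out of scope.
* The Voronoi density threshold is a documented assumption, not a published
  value; segmentation of touching cells is not attempted.
* The stream generator's simplifications listed above bound what synthetic
  validation can claim about microscope data.
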