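---
title: "Mapping lipid nanoenvironments from tracer diffusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping lipid nanoenvironments from tracer diffusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nerdmap)
```

## The assay

Transmembrane proteins perturb the lipids in their immediate vicinity, but
quantifying that perturbation in a living cell membrane is hard. The assay
implemented here immobilizes a GFP-tagged protein of interest (POI) on
micropatterned antibody dots (3 µm diameter, 6 µm pitch) at the basal
plasma membrane and tracks single fluorescent lipid tracers by TIRF
microscopy. Tracer mobility inside the protein-enriched dots (ON) is
compared with the surrounding membrane (OFF) of the *same* cell; the
per-cell ratio $D_{ON}/D_{OFF}$ as a function of the immobilized protein
density $\rho$ encodes the effective in-plane size of the obstacle that the
tracer experiences — protein plus any tightly associated lipid shell.

`nerdmap` implements the full quantitative chain: trajectory pooling and
MSD fitting, molecular counting of the patterned protein density,
the obstructed-diffusion model fit that yields the apparent radius, the
parameter-space scan for annular nanoenvironments with reduced diffusivity
(NERDs), in-plane radii from membrane-oriented structures, and a
Brownian-dynamics simulator that generates every input synthetically.

## Diffusion analysis

Trajectories are split into ON and OFF groups under the recorded pattern
mask. A trajectory counts as ON only when *all* its localizations fall on
ON pixels (and conversely for OFF); mixed trajectories are discarded and
counted. The published description does not state how edge-straddling
tracks were handled; whole-track classification is the default here because
it never mixes the two conditions within one displacement, and a
per-localization splitting mode is available as a configuration switch.

The pooled (ensemble and time averaged) MSD uses every overlapping frame
pair at each lag; frame gaps contribute only to the lags they span. The
diffusion coefficient and localization precision come from

$$\mathrm{MSD}(t_{lag}) = 4D\left(t_{lag} - \tfrac{1}{3}t_{ill}\right) + 4\sigma^2,$$

fitted through the first two lag points only (`fit_diffusion()`), because
mask clipping makes the MSD fall below linearity at long lags — a selection
artifact that the simulator reproduces (see below). The $-t_{ill}/3$ term
corrects for motion blur during the finite illumination time
($t_{ill}$ = 3 ms per 10 ms frame by default). A negative fitted intercept
is truncated to $\sigma = 0$ and flagged rather than treated as an error.
Errors on $D$ are obtained by bootstrapping whole trajectories — the
trajectory, not the localization, is the exchangeable unit.

## Molecular counting

The patterned obstacle density is obtained by relating the
background-subtracted mean ON intensity to the brightness of a single mGFP,
measured as the median integrated brightness of well-separated molecules in
late movie frames (early frames may still contain unbleached multimers).
The single-molecule brightness is scaled linearly to the bulk illumination
time; the published description says "adjusted for the illumination time"
without a formula, and linearity in exposure is the natural camera model.
The fluorophore density is then corrected for immature, non-fluorescent
mGFP and the assumed oligomeric state $n$:
$\rho_{POI} = \rho_{mGFP} \times 1.2 / n$ at the default 20% dark fraction.
Note the published correction factor 1.2 corresponds to counting the dark
tags per *fluorescent* tag ($1 + 0.2$), not to renormalizing by the mature
fraction ($1/0.8 = 1.25$); `obstacle_density()` implements the published
1.2. Oligomer reanalysis (`reinterpret_oligomer()`) divides
already-corrected densities, e.g. 1000 µm⁻² of monomers becomes 500 µm⁻²
of dimers.

## The obstruction model and the apparent radius

Immobilized proteins act as steric obstacles. For randomly placed,
overlapping disc obstacles of combined (obstacle + tracer) radius $R$ at
density $\rho$, the mobility ratio is modeled as

$$\frac{D_{ON}}{D_{OFF}} = 1 - \sqrt{1 - e^{-\rho \pi R^2 / C_P}},$$

with $C_P \approx 0.676$ the critical area coverage at the continuum
percolation threshold of overlapping discs. `fit_apparent_radius()` inverts
this relation by one-parameter least squares (coarse log-grid bracket plus
golden-section refinement — deterministic and immune to the start-value
sensitivity of generic NLS on this flat objective). Radii are in nm and
densities in µm⁻²; the $10^{-6}$ unit conversion lives in a single internal
helper so the formulas read as published. Cells enter unweighted by
default, since the published fit does not state a weighting; inverse
variance weighting is available behind a flag.

The fit error is estimated by simulating 1000 synthetic datasets at the
fitted radius — resampling the observed densities, applying multiplicative
Gaussian noise with the dataset's relative errors to density and ratio, and
keeping the cell count — then refitting each and taking the SD of the
refitted radii. Density noise is applied multiplicatively because the
published procedure refers to *relative* experimental errors. This
estimator is well calibrated: in closed-loop experiments its SD matches the
across-seed spread of the fitted radius, so the 1-SD interval has the usual
~68% coverage.

Subtracting the lipid tracer radius gives the apparent protein radius
$R_{POI,app} = R_{app} - R_{lipid}$. The default $R_{lipid} = 0.49$ nm and
its ±0.05 nm uncertainty is deliberately *not* folded into the reported
radius error, matching the published convention.

## Lipid tracer size

`lipid_tracer_radius()` converts the area per lipid (0.625 nm² for C18
sphingomyelin) into a minimal radius $\sqrt{A/\pi} = 0.446$ nm, and adds
the in-plane area of the rigid triazole moiety of the labeled headgroup for
the maximal estimate. The triazole cross-section is not printed in the
source material; the default 0.29 nm² is this package's own estimate of the
vdW footprint of a 1,2,3-triazole ring (~0.6 nm envelope diameter), which
reproduces the published working value 0.49 ± 0.05 nm. Both the area and
the extra term are plain arguments.

## Protein radii from oriented structures

For a membrane-oriented structure (OPM convention: membrane normal along
z, bilayer midplane at z = 0), `select_leaflet()` keeps the atoms of the
outer leaflet slab $[0, z_{top}]$ (closed interval; $z_{top}$ from the OPM
DUM markers) and `inplane_hull_radius()` projects each atom onto the
membrane plane as a disc of its Bondi vdW radius. The cross-sectional area
is the convex hull of the *disc set* — tangent lines and arcs, not the hull
of the centers — because the atoms are taken to *have* vdW size; a
centers-only mode exists for sensitivity analysis. The hull is evaluated by
dense boundary sampling (720 points per disc; relative area error below
$10^{-5}$, verified against closed-form stadium geometry and a
rasterization oracle). The equal-area radius $\sqrt{A/\pi}$ is reported in
nm. Multi-chain assemblies are processed as provided in the oriented file;
no symmetry expansion is performed by default since published dimer
arrangements are not reconstructible from coordinates alone.

## NERD parameter-space mapping

A NERD is modeled as an annulus of width $d_{NERD}$ around the obstacle
core in which tracer mobility is scaled by $f_{NERD} \in [0, 1]$. The
mobility ratio generalizes to

$$\frac{D_{ON}}{D_{OFF}} =
  \left(1 - \sqrt{1 - e^{-\rho \pi (R_{POI}+R_{lipid})^2 / C_P}}\right)
  \cdot B(\rho, x, f_{NERD}),$$

$$B = 1 - \left(1 - e^{-\rho \pi x}\right)(1 - f) +
      \left(e^{-2 \rho \pi x} - e^{-\rho \pi x}\right)(1 - f)^2,$$

with $x = (R_{POI} + R_{lipid} + d_{NERD})^2 - (R_{POI} + R_{lipid})^2$.
One formula detail deserves emphasis: the core term carries the $C_P$
divisor, the exponentials inside $B$ do **not** — the model is implemented
exactly as published. $B$ reduces to 1 when $d = 0$ or $f = 1$ (recovering
the inert model) and to $e^{-2\rho\pi x}$ when $f = 0$; both reductions are
asserted in the tests, as are monotonicity in $d$ and $f$.

`model_expected_radius()` reproduces the published modeling procedure for
one $(d, f)$ combination: generate a pool of 5000 noisy
$(\rho, D_{ON}/D_{OFF})$ pairs from the NERD model using the measured
density distribution and per-cell relative errors, then 1000 times draw
$n_{cells}$ pairs, fit the *inert* model (exactly as the experimental data
are fitted), subtract $R_{lipid}$, and report the mean and SD.
`scan_nerd_grid()` does this over a grid and classifies each combination
against the experimental radius. Two classification rules appear in the
source material and they disagree; the figure-caption rule is the default
(consistent: experimental mean within the modeled error; borderline: error
intervals overlap; not consistent: disjoint), and the alternative
d = 0-interval rule is available via `rule = "d0_interval"`.

The default grid is $d_{NERD} \in \{0, 0.35, \ldots, 2.1\}$ nm (half-lipid
steps; 0.7 nm is a single lipid layer) by
$f_{NERD} \in \{0.05, 0.10, \ldots, 0.95\}$ — 7 × 19 = 133 combinations,
matching the published count. The exact grid values are not printed in the
source material, so the grid is fully configurable; 0.35 nm steps were
chosen to hit the single-lipid-layer landmark at every second row.

## The synthetic-data generator

The simulator is first-class code, not a fixture: it generates every input
the pipeline consumes and serves as the brute-force oracle for the
percolation constant.

* **Obstacle fields** are Poisson-placed overlapping discs at surface
  densities of order 10²–10³ µm⁻², the experimental regime.
* **Tracers** perform Gaussian sub-steps (D = 1 µm²/s scale) with periodic
  boundaries. A move ending inside an obstacle core is rejected (the tracer
  stays), which is the simplest scheme with the correct uniform equilibrium
  for small steps; the sub-step is capped at one fifth of the core radius.
  Steps *originating* inside an annulus are scaled by $\sqrt{f}$, giving a
  local diffusivity $f \cdot D$; the starting-point rule handles the
  boundary.
* **Imaging** applies motion blur (mean of ≥10 sub-positions across
  $t_{ill}$) and per-coordinate Gaussian localization noise
  (σ = 40 nm default). Reported coordinates are unwrapped; mask clipping
  happens only in the analysis stage, mirroring the experiment.
* **Pattern masks** are boolean rasters of 3 µm dots on a 6 µm square
  lattice, written as TIFF with a JSON sidecar.
* **Per-cell datasets** draw a density from a configurable distribution,
  evaluate the NERD model, and add multiplicative Gaussian noise (5%
  relative by default on both density and ratio, the scale of the
  per-cell measurement errors in this assay); observed ratios are clipped
  to (0, 1.05] with the clip count recorded.

What the generator deliberately does **not** emulate: photophysics beyond
constant brightness (no blinking or bleaching), anisotropic or elliptical
obstacles, membrane topography, and spot detection/linking from raw movies
(the pipeline starts at localization tables). Passing closed-loop tests
therefore demonstrates the correctness of the analysis chain under the
model's own assumptions, not robustness to every artifact of real data.

## Percolation threshold estimation

`estimate_percolation_coverage()` estimates the critical coverage of
overlapping discs by spanning-cluster Monte Carlo: discs in a square box
with free boundaries, union-find over the overlap graph, a replicate
percolates when one cluster touches both left and right (or bottom and
top) edges. The density is bisected toward the 50% spanning probability
with ≥200 replicates per density, and the final coverage and its SE come
from a probit fit over all evaluated densities. The default box is 150 disc
radii wide — at that size the residual finite-size bias of the
either-direction spanning rule (about −0.006 in coverage) is comparable to
the Monte-Carlo error and well inside the ±0.015 band around the literature
value 0.676 that the package commits to. The estimate is asserted to be
independent of the disc radius, as it must be for a dimensionless
threshold.

## Simulator versus the obstruction model

A direct cross-check of the Brownian simulator against the obstruction
model at equal coverage is included in the acceptance suite and **fails by
construction**, a fact worth documenting prominently: a point tracer among
reflecting discs at area coverage 0.05–0.3 shows mobility ratios of
0.94/0.87/0.73/0.59 (converged, step = R/5, lags 2–5), bracketed by
standard effective-medium estimates, whereas the model formula evaluates to
0.73/0.62/0.47/0.36. The formula is an *empirical* law for the membrane
experiment — living-membrane tracer diffusion responds far more strongly to
protein crowding than hard-disc Brownian theory predicts — and should not
be expected to coincide with an idealized hard-disc simulation at equal
coverage. Within the package the formula is used exactly as published for
fitting and modeling; the simulator is used for the percolation constant,
for imaging-artifact studies (blur, noise, mask clipping), and for
closed-loop tests of the fitting machinery, where it is self-consistent.

## Numerical choices and degenerate inputs

* Radius search interval [0.05, 30] nm; hitting a boundary raises a
  convergence warning. All-flat ratio data (~1) trigger an
  "unidentifiable radius" warning; densities spanning less than a 2-fold
  range trigger a conditioning warning.
* More than 5% failed refits aborts the error estimator; refits at the
  search boundary are excluded from the SD.
* Bootstrap resamples without displacement pairs at a used lag are skipped
  and counted.
* All stochastic entry points take an integer `seed` and restore the
  caller's RNG state; fixed seeds reproduce results exactly, including
  across the C++ core (which draws from R's RNG stream).

## Problem sizes used in the shipped tests

The test suite runs the full chain at reduced but statistically meaningful
sizes chosen by the authors: 100-seed closed-loop recovery at n = 88 cells,
2000-tracer simulator cross-checks, 200-replicate percolation sweeps, and
6000-track mask-artifact simulations. These sizes keep every Monte-Carlo
standard error several times smaller than the tolerance it is tested
against.

## Known limitations

* The obstruction formula does not vanish exactly at the percolation
  threshold (it evaluates to ~0.1 there); it is an empirical
  interpolation validated in the low-coverage regime of the assay
  (obstacle coverage of a few percent).
* $d_{NERD}$ and $f_{NERD}$ are scanned, never fitted — combinations along
  a ridge produce nearly identical density dependences and are genuinely
  unidentifiable from this data alone.
* The consistency classification inherits the ~68% coverage of 1-SD
  intervals; neighboring grid cells flip labels near the region boundaries
  under reseeding.
* Real calibration inputs (flat-field references, camera gain) are accepted
  as pre-processed images; their acquisition is out of scope.
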