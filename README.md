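# nerdmap

Mapping the lipid nanoenvironment of immobilized membrane proteins from
single-molecule tracer diffusion.

## What it does, and for whom

Transmembrane proteins influence the lipids around them — from loosely
perturbed annular shells to tightly bound, co-moving lipid layers. This
package implements a quantitative micropatterning assay for probing that
nanoenvironment in live-cell membranes: a GFP-tagged protein of interest
(POI) is immobilized on antibody-stamped dots (3 µm dots, 6 µm pitch), a
fluorescent lipid tracer is tracked at single-molecule level, and the
tracer mobility ratio between protein-enriched (ON) and protein-depleted
(OFF) areas of each cell is interpreted through a continuum-percolation
model of obstructed diffusion.

The core model: for immobilized disc obstacles of combined
(protein + tracer) radius *R* at density ρ,

    D_ON / D_OFF = 1 − √(1 − exp(−ρ π R² / C_P)),      C_P ≈ 0.676,

where C_P is the critical area coverage at the continuum percolation
threshold of overlapping discs. Fitting this density dependence yields the
apparent radius R_app and, after subtracting the lipid tracer radius
(R_lipid = 0.49 nm), the apparent in-plane protein radius
R_POI,app = R_app − R_lipid, which contains the steric protein
cross-section *plus* any co-immobilized lipid shell. Comparing R_POI,app
with the radius computed from a membrane-oriented structure (vdW-buffered
convex hull of the outer-leaflet z-projection) localizes the
nanoenvironment contribution. An extended model with a ring of width
d_NERD and mobility factor f_NERD (a "nanoenvironment with reduced
diffusivity", NERD) is scanned over a 7 × 19 = 133-combination grid and
each combination is classified as consistent / borderline / not consistent
with the measured radius.

Intended users: membrane biophysicists analyzing single-particle tracking
data from micropatterned cells, and anyone who needs the building blocks —
pooled MSD analysis with motion-blur correction, single-fluorophore
molecular counting, continuum percolation simulation, or in-plane protein
radii from OPM-oriented PDB files.

## Worked example

A fully synthetic study mirroring a β2-adrenergic-receptor-like dataset:
88 cells, obstacle densities 0–2000 µm⁻², 5% relative measurement errors
on density and mobility ratio, generated at a planted combined radius of
2.60 nm (R_POI = 2.11 nm + R_lipid = 0.49 nm):

```r
library(nerdmap)

truth <- nerd_params(r_poi = 2.11, r_lipid = 0.49)   # no NERD ring
ds <- generate_cell_dataset(truth, function(n) runif(n, 0, 2000),
                            rel_err_density = 0.05, rel_err_ratio = 0.05,
                            n_cells = 88, seed = 1, label = "beta2AR-like")
fit <- fit_apparent_radius(ds, cp = 0.676, r_lipid = 0.49)
fit <- estimate_fit_error(fit, ds, n_sim = 1000, seed = 2)
print(fit)
#> Apparent combined radius R_app  = 2.605 +/- 0.063 nm (n = 88 cells)
#> Apparent protein radius R_POI,app = 2.115 +/- 0.063 nm (R_lipid = 0.49 nm)
```

The fit recovers the planted 2.60 nm within its error, and the simulated
fit error (±0.063 nm) is the same order as the per-protein errors reported
for this assay. Scanning the NERD grid against the fitted radius:

```r
prof <- profile_from_dataset(ds, r_poi = 1.94)
grid <- scan_nerd_grid(prof, c(fit$r_poi_app, fit$r_poi_app_error), seed = 3)
print(grid)
#> NERD classification matrix: 133 combinations vs R_POI,app = 2.12 +/- 0.06 nm
#>
#>     consistent     borderline not_consistent
#>             27             30             76
```

Wide rings with strongly reduced mobility are excluded (red cells);
narrow/mild rings remain consistent — the expected degeneracy ridge.
The percolation constant behind C_P can be recomputed from scratch:

```r
estimate_percolation_coverage(core_radius = 5, n_reps = 200, seed = 4)
#> Percolation threshold coverage: 0.6688 +/- 0.0005 (box = 150 R, 200 reps/density)
```

and the lipid tracer radius from the area per lipid (0.625 nm²) plus the
label headgroup area:

```r
lipid_tracer_radius()
#>     r_min     r_max     r_mid
#> 0.4460310 0.5396791 0.4928551
```

Other entry points: `simulate_tracers()` (Brownian dynamics among
reflecting obstacles with motion blur and localization noise),
`classify_trajectories()` / `compute_msd()` / `fit_diffusion()` /
`bootstrap_diffusion()` (tracking analysis), `single_molecule_brightness()`
/ `mgfp_density()` / `obstacle_density()` (molecular counting), and
`load_oriented_structure()` / `select_leaflet()` / `inplane_hull_radius()`
(structural radii). A thin CLI over these functions is shipped at
`inst/scripts/nerdmap-cli.R`.

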