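Package: nerdmap
Title: Lipid Nanoenvironments of Immobilized Membrane Proteins from
    Single-Molecule Tracer Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative assay for mapping the lipid nanoenvironment of
    micropatterned, immobilized transmembrane proteins. Turns single-molecule
    lipid-tracer trajectories and patterned protein-density images into
    per-cell mobility ratios (D_ON/D_OFF), fits a continuum-percolation model
    of obstructed diffusion to obtain an apparent in-plane protein radius, and
    scans ring-shaped nanoenvironments with reduced diffusivity (NERDs,
    parameterized by ring width d_NERD and mobility factor f_NERD) for
    consistency with the data. Includes a Brownian-dynamics simulator of
    tracers among reflecting disc obstacles, a union-find estimator of the
    continuum percolation threshold of overlapping discs, molecular-counting
    utilities for single-fluorophore brightness calibration, and computation
    of in-plane protein radii from membrane-oriented structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
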