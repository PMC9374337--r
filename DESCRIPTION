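Package: smdmr
Title: Single-Molecule Displacement Mapping of Protein Diffusion in Confined Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Analysis of single-molecule displacement mapping (SMdM) data from
    small, confined cells such as bacteria. Pairs stroboscopic localizations
    into fixed-lag displacements, segments cells by Voronoi-density clustering,
    rotates them onto their major axis, and estimates local diffusion
    coefficients by maximum-likelihood fitting of a truncated Rayleigh
    displacement distribution with a linear mispairing background. Includes a
    Brownian-dynamics simulator for reflective spherocylinders to quantify
    confinement bias, pole/center diffusion-ratio ensembles, and downstream
    statistics relating diffusion coefficients to protein complex mass,
    abundance, interaction loneliness, and perceived cytoplasmic viscosity.
License: GPL (>= 3)
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    minpack.lm,
    igraph
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
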