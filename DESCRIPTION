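Package: vascox
Title: Stochastic Tumour Vasculature and Oxygen Transport Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates stochastic macro- and microvessel trees by inverse-transform
    sampling of branching angles, rasterizes them into 3D voxel grids with
    Bresenham's line algorithm and spherical dilation, and computes steady-state
    tissue oxygen fields by iterated Green's-function (Gaussian) diffusion with
    Michaelis-Menten consumption. Implements two whole-tumour oxygen computation
    schemes, the Combined Tree Method (joint high-resolution solve) and the
    Individual Tree Method (per-tree precomputed fields max-combined on a coarse
    grid), together with the evaluation statistics used to compare them: hypoxic
    and vascular fractions, pO2 distribution summaries, RMSD between cumulative
    distributions, large-sample two-sample Kolmogorov-Smirnov tests and property
    correlation matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
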