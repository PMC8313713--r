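Package: mismatchlab
Title: Membrane Hydrophobic-Mismatch Energetics and Umbrella-Sampling Free-Energy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for protein-induced membrane perturbation and
    binding thermodynamics from molecular-dynamics-style data. Builds gridded
    2D membrane-thickness and protein-occupancy maps from lipid phosphorus and
    protein coordinates, computes deuterium order parameters (S_CD) with
    block-averaged uncertainties, segments membrane regions thinned beyond a
    threshold and converts perimeter changes on protein complexation into
    line-tension free energies, and reconstructs potentials of mean force from
    umbrella-sampling window time series via the weighted histogram analysis
    method (WHAM) with autocorrelation-aware Monte-Carlo bootstrap errors.
    Includes synthetic-data generators with exactly known ground truth
    (Gaussian thinning wells, prescribed chain order, umbrella series from
    analytic 1D free-energy profiles) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    withr,
    pracma,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
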