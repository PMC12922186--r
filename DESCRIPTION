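Package: stacksas
Title: Coarse-Grained Amphiphile Self-Assembly Analysis and Small-Angle
    Scattering Ensemble Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build and analyse coarse-grained bead models of
    self-assembling triskelion amphiphiles with a rigid aromatic core and
    alternating hydrophobic/hydrophilic arms.  Generates synthetic ensembles
    of dissolved monomers, face-alternating pi-stacks and larger
    prolate/oblate aggregates in periodic boxes; detects aggregates by
    single-linkage clustering with minimum-image distances; computes
    mass-weighted size distributions, centre-of-mass radial distribution
    functions, solvent-accessible surface areas, inertia-tensor shape
    classes and cylindrical distribution functions with their perpendicular
    radial profiles; forward-models SAXS and SANS intensities with the
    Debye equation and Gaussian resolution smearing; and refines ensemble
    weights against scattering curves with a metainference-style Monte
    Carlo sampler of per-point effective uncertainties, scale and offset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    igraph,
    jsonlite,
    pracma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
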