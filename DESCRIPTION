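Package: smlmdomains
Title: Nanodomain, Colocalization and Single-Molecule Diffusion Analysis for
    Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of single-molecule localization microscopy (PALM/dSTORM)
    point patterns and single-particle trajectories from plasma-membrane
    leaflet imaging. Implements Voronoi-tessellation cluster segmentation of
    localization maps with a Monte Carlo threshold against complete spatial
    randomness, a per-localization degree-of-colocalization (DoC) statistic
    for dual-colour data with a randomized-shift control, mean-square
    displacement and effective diffusion coefficient estimation for
    single-molecule trajectories, and detection of transient confinement
    (temporary arrest of lateral diffusion, TALL) events. A synthetic-data
    module generates clustered point patterns, coupled two-channel patterns
    and Brownian/confined/hop/immobile trajectories with ground truth so
    every stage is testable without raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deldir,
    igraph,
    RANN,
    tibble,
    stats,
    graphics,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
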