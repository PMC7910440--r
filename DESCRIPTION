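Package: radH2
Title: Radiolytic Hydrogen and Oxidant Production in Marine Sediment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the radiolysis of porewater by the decay of U, Th and K
    in marine sediment. Converts bulk radionuclide content into decay-series
    activities at secular equilibrium, evaluates volumetric radiolytic H2 and
    oxidant production with lithology-specific, experimentally amplified
    yields, depth-integrates 1-m discretized sediment columns with Athy-type
    compaction, predicts steady-state dissolved-H2 diffusion profiles
    (closed-form, two-layer and finite-difference solvers), inverts measured
    porewater O2 and DIC profiles into net reaction rates via Akima-spline
    flux divergence with Monte-Carlo uncertainty, evaluates in situ Gibbs
    energies of aerobic H2 oxidation, compares radiolytic electron supply to
    organic-fuelled respiration as a function of sediment age, and rolls
    volumetric rates up to a gridded global production estimate. Includes
    seeded synthetic-data generators so the whole chain is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
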