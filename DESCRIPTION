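Package: spindyn
Title: Variable-Temperature Solid-State NMR Dynamics and Polymorph Thermodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for segmental dynamics in molecular crystals
    from variable-temperature solid-state NMR and calorimetry. Fits T1/T1rho
    magnetization decays, extracts Arrhenius activation energies from
    relaxation-rate series, converts rates to correlation times through BPP
    spectral densities, measures effective one-bond C-H dipolar couplings
    from Pake powder patterns under Lee-Goldburg scaling, maps dipolar order
    parameters onto motional models (small-amplitude wobble, N-site jumps,
    uniaxial rotation), integrates DSC transition enthalpies and entropies,
    regresses experimental chemical shifts on GIPAW shieldings, and computes
    crystal-geometry descriptors (cell volumes, periodic contacts,
    probe-occupiable void fractions). A synthetic-data generator produces
    every input with known ground truth so the whole pipeline is testable
    without a spectrometer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
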