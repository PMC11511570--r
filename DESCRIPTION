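Package: hsspme
Title: Cooled Headspace SPME Equilibrium Modelling, Retention Indexing,
    and Bioanalytical Method Validation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computational toolkit for cooled headspace solid-phase
    microextraction (HS-SPME) GC-MS method development. Estimates
    coating/headspace and headspace/liquid partition coefficients from
    Henry's law constants, octanol-water partition coefficients, van't
    Hoff parameters, or linear temperature-programmed retention indices
    (LTPRI); predicts three-phase equilibrium analyte uptake on the
    fiber; computes retention indices from alkane ladders with basic
    peak detection and integration; constructs exact D-optimal designs
    on small candidate grids with saturated response-surface fitting,
    test-point validation and multi-response optimum selection; and
    derives calibration and performance statistics (LOD/LOQ from the
    standard deviation of the intercept, RSD, accuracy, recovery,
    inter-/intra-day aggregation). Seeded synthetic-data generators
    emulate chromatograms, calibration campaigns, design-of-experiments
    response tables and uptake kinetics so the full pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
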