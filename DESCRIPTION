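Package: diufba
Title: Diurnal Flux Balance Analysis for Phototrophic Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constraint-based analysis of metabolic networks over a diurnal
    (light/dark) cycle. The network is replicated per phase and coupled by
    transfer reactions for carry-over (storage) species and by export
    reactions for long-term accumulation, so that a single linear program
    spanning the whole cycle decides how much storage metabolite to lay
    down during the light phase. Includes readers and writers for SBML
    Level 3 FBC, COBRA-style JSON and a plain TSV reaction-table dialect,
    diurnal phenotypic phase plane scans with metabolic-mode
    classification, a built-in bounded-variable simplex solver, a worked
    two-phase example model with closed-form optima, and a sequential
    (static-optimization) dynamic-FBA comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    xml2,
    methods,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
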