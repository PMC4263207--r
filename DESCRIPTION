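Package: fluxkit
Title: Constraint-Based Flux Analysis for Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Load constraint-based metabolic models (SBML or a documented CSV
    dialect), layer user constraints on top of them (environmental conditions,
    measured fluxes, linearized flux-ratio constraints, gene and reaction
    knockouts), classify the resulting system by its degrees of freedom, and
    run the applicable flux-analysis method: algebraic solving and (weighted)
    least squares for determined and over-determined systems, and flux balance
    analysis, parsimonious FBA, quadratic-programming measurement fitting,
    tight flux bounds, flux variability analysis under optimality, robustness
    analysis and knockout phenotype simulation for underdetermined systems.
    Results are returned as S4 objects with steady-state and bound diagnostics
    and can be rendered as structured text or JSON reports including net
    conversions and an audit of the bounds actually applied.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'accessors.R'
    'equation-parse.R'
    'gpr.R'
    'read-csv.R'
    'read-sbml.R'
    'constraints.R'
    'system-analysis.R'
    'lp.R'
    'qp.R'
    'algebraic.R'
    'optimization.R'
    'reporting.R'
    'fixtures.R'
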