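Package: symbioFBA
Title: Host-Symbiont Community Flux Balance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constraint-based metabolic modeling of insect-bacterial
    symbioses. Assembles multi-compartment stoichiometric models of a host
    and its bacterial symbionts coupled through a shared hemolymph pool with
    biomass-ratio scaling, solves them by flux balance analysis and
    parsimonious FBA, and sweeps symbiont biomass to predict histidine
    synthesis flux and AICAR by-product overflow. Also provides supporting
    numeric procedures for such studies: cell-number to biomass ratio
    conversions, 13C isotopologue enrichment summaries, aphid performance
    metrics (relative growth rate, intrinsic rate of increase), and a
    two-stage metabolite screening pipeline (per-feature t tests, mixed
    model with genotype random effect, Benjamini-Hochberg correction),
    together with synthetic-data generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml,
    xml2,
    withr,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
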