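Package: capnoflux
Title: Constraint-Based Analysis of Succinate-Fermenting Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constraint-based modelling of capnophilic succinate
    fermenters such as Actinobacillus succinogenes. Provides an in-memory
    metabolic model representation with media and bound manipulation, SBML
    (Level 3 + FBC) and tabular model input/output, network curation checks
    (elemental and charge balancing with proton/water repair, dead-end and
    blocked-reaction detection), biomass objective construction from
    macromolecular composition, flux balance analysis, parsimonious FBA and
    flux variability analysis on a built-in deterministic simplex solver,
    theoretical-yield and growth-phenotype scenario runners (carbon-source
    panels, CO2-availability scans, PTS versus symport transport, malic-enzyme
    reversibility), taxonomy-weighted EC-number functional scoring of homology
    hits, and seeded generators for reduced central-carbon fixture models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
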