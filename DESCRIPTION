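Package: pairfba
Title: Pairwise Bacterial Interactions from Metabolic Models Across Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies pairwise bacterial interactions (competition,
    cooperation and its obligate subtypes, commensalism, neutrality) from
    genome-scale metabolic models using flux balance analysis with a
    partner no-harm constraint. Environments are sets of extracellular
    compounds expressed as bounds on the net-change (right-hand-side)
    vector of the stoichiometric system. Includes identification of
    usable and essential compounds for a pair, random fixed-size
    environment generation, environment screening with cooperation
    subtyping, single-compound-removal stability scans, sequential
    environment-degradation experiments with path summaries,
    cross-environment statistics (Jaccard distances, compound-appearance
    bias, switch frequencies, metabolic-complexity terciles), a small
    SBML reader/writer, and a synthetic toy-model generator with designed
    ground-truth interaction topologies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    boot,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
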