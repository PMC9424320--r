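Package: pathranker
Title: Evaluation, Scoring and Ranking of Heterologous Metabolic Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate, score and rank candidate heterologous metabolic
    pathways for a chassis organism. Pathways are exchanged as enriched SBML
    Level 3 documents carrying chemical structures (InChI, SMILES, InChIKey),
    reaction-rule provenance and computed properties in a dedicated annotation
    namespace. The package enumerates complete reaction pathways from
    rule-level master pathways by template completion and cofactor re-addition,
    computes theoretical target production flux under a biomass burden
    constraint (fraction-of-reaction flux balance analysis), estimates reaction
    and pathway Gibbs free energies through a stoichiometric-multiplier
    pseudo-reaction linear program, scores pathways directly or with a
    gradient-boosted classifier over Morgan-fingerprint features, matches
    predictions against literature reference pathways, and enumerates
    combinatorial BASIC-style genetic construct designs. A synthetic-fixture
    generator provides fully self-contained toy chassis models, rule databases
    and labeled pathway collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    ChemmineR,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    boot,
    ChemmineOB,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
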