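Package: driverHMM
Title: Cancer-Weighted Profile HMM Scoring of Amino Acid Substitutions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores missense substitutions by contrasting mutant and
    wild-type amino acid emission probabilities at profile hidden Markov
    model match states, adjusted by cancer-specific pathogenicity weights
    built from labelled variant catalogues, and classifies driver versus
    passenger/neutral mutations at a fixed threshold. Includes readers and
    a fixture writer for HMMER3 ASCII profiles, residue-to-match-state
    mapping through domain assignments, Kullback-Leibler model selection
    against a background amino acid composition, weight-table construction
    with leave-one-out semantics, normalized six-parameter performance
    metrics, cumulative ROC curves, threshold derivation, stratified
    cross-validation of the weighting scheme, odds-ratio comparison of
    weighting schemes, and a deterministic synthetic fixture generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'alphabet.R'
    'assignments.R'
    'driverHMM-package.R'
    'evaluation.R'
    'profilehmm.R'
    'scoring.R'
    'select.R'
    'synthetic.R'
    'variants.R'
    'weights.R'
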