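Package: apmswalk
Title: Context-Specific AP-MS Interactome Filtering, Functional Analysis,
    and Biased Random Walks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for context-specific affinity-purification
    mass-spectrometry (AP-MS) interactomics. Calls high-confidence bait
    interactors from label-free quantification (LFQ) matrices via a
    five-step filter with mixed missing-value imputation and an empirical
    Bayes moderated test against bead-only controls; collapses LFQ
    intensities onto Gene Ontology terms and scans them with factorial
    ANOVA under Hommel correction, with gene set enrichment, Wang semantic
    similarity and binary-cut clustering; and attributes functional outputs
    to individual effector pathways by biased targeted random walks on a
    confidence-filtered protein-protein interaction network, backed by an
    exact path-enumeration oracle. Includes seeded synthetic-data
    generators for LFQ matrices, effector networks, ontologies and
    phenotype tables so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    car,
    jsonlite
Config/testthat/edition: 3
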