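Package: pathcurator
Title: Pathway Curation Assistant: Interaction-Based Pathway Prediction and
    Literature Triage for Knowledgebase Curation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A file-backed, provider-pluggable implementation of an
    LLM-assisted gene-to-pathway curation workflow. Given a query gene and a
    pathway-knowledgebase snapshot, the package predicts candidate pathways by
    binomial enrichment of the gene's interaction partners (with
    Benjamini-Hochberg false-discovery control), retrieves and scores candidate
    abstracts against pathway-context text with a two-way scheme (average
    embedding cosine similarity plus an LLM-judge score), assembles grounded
    curation summaries through pluggable language-model providers, extracts
    typed functional relationships from full-text documents, and validates
    generated summaries against curated ones with a permutation-background
    semantic-similarity statistic (Mann-Whitney U). Deterministic mock
    providers and a synthetic-fixture generator make the whole pipeline
    runnable and testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
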