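Package: cdmo
Title: Bilingual Medical Ontology Construction, Rule-Based Clinical
    Decision Support and Ontology-Augmented Question Answering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for semi-automated construction of a bilingual
    (Chinese/English) disease ontology and for applying it. Covers
    dictionary-automaton term harvesting from a clinical corpus with
    document-frequency and synonym-merge filters, cross-lingual mapping of
    Chinese concepts to English target ontologies with automatic is_a
    hierarchy induction from established mappings, an OWL-subset ontology
    model with Turtle/RDF-XML/JSON input and output and quality-control
    reports, a forward-chaining evaluator for SWRL-style clinical decision
    rules with subsumption-aware class matching and numeric builtins, and
    BM25 retrieval of concept definitions with ROUGE-1/2/L scoring for
    question-answering evaluation. Deterministic seeded generators produce
    all synthetic inputs with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
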