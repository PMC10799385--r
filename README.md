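# cdmo — bilingual medical ontology construction and application

Chinese clinical knowledge has no mature, openly available disease
ontologies, and translating English ontologies wholesale does not fit
Chinese clinical practice. `cdmo` packages a semi-automated workflow for
building a bilingual (Chinese/English) disease ontology — using diabetes
mellitus as the worked domain — together with the two application engines
such an ontology exists to power: rule-based clinical decision support and
ontology-knowledge injection for medical question answering.

It is aimed at biomedical knowledge engineers and ontology curators who
work with Chinese clinical text but want to anchor their terminology in
established English ontologies (SNOMED CT, NCIT, …).

## What the package does

**Term harvesting** (`build_matcher`, `scan_corpus`, `harvest_terms`).
Candidate terms are extracted from a clinical corpus with an Aho–Corasick
dictionary automaton (all overlapping hits in one pass), then filtered:
grade/degree surfaces (数字 + 级/期/度/型, e.g. "1级") and stoplisted
surfaces are excluded; a candidate survives only if it has a lexicon entry
**and** appears in at least `min_docs = 3` distinct documents
(document-level, not occurrence-level counting); literal synonyms that
share an English name (e.g. 黑棘皮症 / 黑棘皮病 → "acanthosis nigricans")
are merged by union–find.

**Cross-lingual mapping and hierarchy induction** (`propose_mappings`,
`induce_hierarchy`). English names of Chinese concepts are looked up in a
target ontology's lexical index, exactly or through a normalized key
(lowercased, punctuation stripped, semantic-tag suffixes such as
"(disorder)" removed, tokens sorted, so "hyperosmolar hyperglycemic state"
and "hyperglycemic hyperosmolar state" collide). Established mappings then
transfer hierarchy: if two mapped concepts' target classes stand in an
is_a relation within one target ontology, the corresponding source edge
`child is_a parent` is proposed — transitively reduced, with cycle and
conflict guards, and never chaining evidence across two different target
ontologies. Similarity scores are metadata only; there is no automatic
acceptance threshold.

**Ontology model and QC** (`load_ontology`, `save_ontology`, `qc_report`).
A named-class OWL subset (classes, is_a, labels with `zh`/`en` tags,
synonyms, sourced definitions, annotation and object properties with
domains/ranges) reads and writes Turtle, RDF/XML and a JSON dialect.
QC reports cycles, orphans, missing definitions, duplicate Chinese labels
and ABox domain/range violations. Definition selection follows a fixed
source priority: termonline > encyclopedia > CHPO > MedDRA > manual.

**Rule engine** (`parse_rules`, `forward_chain`, `explain`). A parser for a
SWRL-style plain-text dialect (`name: atom ^ … -> atom ^ …`, builtins as
`swrlb:greaterThanOrEqual(?v, 7.0)`) and a set-at-a-time forward-chaining
fixpoint over a TBox+ABox knowledge base. Class atoms match
subsumption-aware (an individual typed `2型糖尿病` satisfies
`diabetes_mellitus(?d)`), builtins compare numeric values exactly and
refuse mismatched units, and every derivation carries a trace (rule,
variable binding, natural-language comment) for clinician-facing
explanation. Four diabetes rules — diagnosis, therapy, drug
contraindication, diet — ship in `inst/rules/diabetes_core.rules`.

**QA knowledge injection** (`retrieve_evidence`, `build_prompt`,
`rouge_scores`). Concept definitions are ranked against a question with
Okapi BM25,

    score(D, Q) = Σ_t  IDF(t) · f(t,D)·(k1+1) / (f(t,D) + k1·(1 − b + b·|D|/avgdl)),
    IDF(t) = log(1 + (N − df(t) + 0.5)/(df(t) + 0.5)),

with defaults k1 = 1.5, b = 0.75 and character-bigram tokens (Chinese has
no word boundaries). The top-n definitions are concatenated into the exact
prompt template `Question: {Q}, Evidences: {D1}, …, {Dn}`. Generated
answers are scored with character-level ROUGE-1/2 (clipped n-gram F1) and
ROUGE-L (longest-common-subsequence F1).

**Fixtures** (`make_micro_ontology`, `make_target_ontology`, `make_corpus`,
`make_patients`, `write_fixtures`). Deterministic seeded generators produce
every input with planted ground truth: a ~50-concept bilingual
micro-ontology under a SNOMED-style first level, an English target with 14
planted subsumptions and its ground-truth mapping table, a corpus with
controlled document frequencies, and patient ABoxes with values placed
around the rule thresholds — always including the two literal worked
scenarios (four symptoms with fasting glucose 8.0 mmol/L; type 2 diabetes
with BMI 28).

## Worked example

```r
library(cdmo)
g     <- make_micro_ontology()
rules <- parse_rules(diabetes_rules_path())
pat   <- make_patients(seed = 42, n = 2)   # the two worked scenarios only
res   <- forward_chain(pat$kb, rules)
print(res)
#> <inference: 5 derived assertion(s) in 2 pass(es)>
#>   patient_has_diagnosis(patient_a, diabetes_mellitus)
#>   patient_has_diagnosis(patient_a, type_2_diabetes_mellitus)
#>   patient_has_therapy(patient_b, lifestyle_therapy)
#>   patient_has_therapy_drug(patient_b, orlistat)
#>   patient_has_therapy_drug(patient_b, glp1_receptor_agonist)
```

`patient_a` (polyphagia, polyuria, polydipsia, weight loss; fasting
glucose 8.0 mmol/L) is diagnosed with diabetes mellitus — and, because
class matching is subsumption-aware, with every diabetes-typed canonical
individual in the knowledge base. `patient_b` (type 2 diabetes, BMI 28)
receives lifestyle therapy plus the rule's two drug recommendations.
Every derivation is explainable:

```r
explain(res, list(kind = "object", property = "patient_has_diagnosis",
                  subject = "patient_a", object = "diabetes_mellitus"))[[1]]
#> $rule      : "Diagnosis_1"
#> $binding$v1: 8          # the glucose value that satisfied the builtin
#> $comment   : "Patients with symptoms of polyphagia, polyuria, polydipsia
#>               and weight loss, and fasting blood glucose greater than or
#>               equal to 7 mmol/L, are predicted to have diabetes mellitus"
```

Evidence retrieval and scoring:

```r
ev <- retrieve_evidence("什么是二甲双胍？", g, retrieval_config(n = 2))
build_prompt("什么是二甲双胍？", ev)
#> "Question: 什么是二甲双胍？, Evidences: 二甲双胍（metformin）：临床实践指南所涉概念。, ..."
rouge_scores("糖尿病要控制饮食", "糖尿病需要控制饮食")
#> ROUGE-1 0.9412  ROUGE-2 0.8000  ROUGE-L 0.9412
```

A command-line front end over the same functions lives at
`inst/cli/cdmo.R` (subcommands `qc`, `harvest`, `map`, `induce`, `infer`,
`retrieve`, `rouge`, `fixtures`).

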