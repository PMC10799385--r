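---
title: "Building and applying a bilingual disease ontology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and applying a bilingual disease ontology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdmo)
```

This vignette is the package's account of its methods: the models and
procedures each module implements, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the design decisions
taken where the design was genuinely open.

## The workflow

A bilingual disease ontology is built in five stages — term collection,
concept definition, cross-lingual mapping, hierarchy construction,
property construction — followed by quality control, and is then applied
in two engines: a forward-chaining rule evaluator for clinical decision
support and BM25-based definition retrieval for question answering.
`cdmo` implements each stage as an explicit, testable operation over plain
data structures; expert-judgment steps (translation, review) appear as
interfaces (e.g. a "needs translation" signal), never as automation.

## Term harvesting

Dictionary matching uses an Aho–Corasick automaton built from the lexicon:
a trie with failure links, matching all entries — including overlapping
and nested occurrences — in one pass over the text. Matching is on raw
Unicode codepoints; Chinese clinical text has no case, and we assume the
corpus reader has already produced consistent UTF-8 (an NFC pass upstream
is advisable when texts come from OCR).

Filters, in order:

1. **Exclusion.** A candidate whose entire surface is a numeral
   (Arabic or Chinese) followed by 级/期/度/型 is a grade/degree
   expression ("1级", "3期") and is dropped, as are stoplist entries
   (seeded with "全部"). The suffix set generalizes from the attested
   examples; the stoplist is user-editable precisely because the pattern
   is a heuristic.
2. **Lexicon presence and document frequency.** A candidate survives iff
   it has an entry in the supplied lexicon-presence set *and* appears in
   at least `min_docs` distinct documents (default 3). Counting is
   document-level: three occurrences in one document count once. Both
   conditions are conjunctive.
3. **Synonym merging.** Union–find over "shares an English name" plus
   explicitly listed pairs. The canonical member is the bytewise-smallest
   surface (UTF-8 radix order — locale-independent, hence reproducible);
   the canonical row re-aggregates the group's document sets.

An open point we had to fix: whether the frequency threshold applies
before or after merging. The package counts *before* merging and
re-aggregates document ids per group afterwards; merging first would let
two sub-threshold spellings pool their counts, which changes survivors.
The retention percentage reported by `harvest_report()` is
`round(100 * retained / recognized, 2)`.

## Cross-lingual mapping

Name normalization lowercases, strips punctuation, removes parenthesized
semantic-tag suffixes ("(disorder)") and sorts tokens, so translation
variants that permute word order collide on one key. Token sorting is on
by default; an exact-order mode exists for vocabularies where word order
is distinctive. Proposal policy, per English name: exact
(case-insensitive) label hits win; the normalized index is consulted only
when a name has no exact hit; all hits are returned, exact before
normalized, sorted by target id. We deliberately do not auto-accept on
string similarity: lexical scores are known to rate wrong pairs highly
(a stage-2/stage-4 confusion can score above 0.93), so `similarity` is
carried as metadata for a human reviewer.

Hierarchy induction transfers subsumption: for two source concepts mapped
into the *same* target ontology, a target-side is_a relation between
their images proposes the corresponding source edge. Evidence is never
chained across target ontologies, because different English ontologies
disagree about hierarchy and mixing them manufactures edges no single
authority asserts. Two modes exist because a target's subsumption can be
read directly (asserted parent) or transitively (reachability); the
default is transitive with transitive reduction, which recovers exactly
the cover relation among mapped classes and keeps the source graph
minimal. Neither mode is claimed to be "the" correct reading — the choice
is documented here and switchable. Guards: an edge whose reverse is
already asserted in the source is `rejected_conflict`; an edge that would
close a cycle through previously accepted edges is `rejected_cycle`;
accepted edges are applied incrementally so the output graph is acyclic
by construction, and this is asserted after every application.

## Ontology model, I/O and QC

The model is a named-class OWL subset: classes with `zh`/`en` labels,
synonyms, one sourced definition, annotation values, is_a links;
object/annotation properties with their own hierarchy and domains/ranges.
Class expressions and restrictions are outside the subset and are skipped
with a warning on load — the workflow uses its ontology at this level of
expressivity, and silently erroring on published OWL files would make
round-tripping real inputs impossible. Turtle output is deterministic
(sorted by IRI; repeated saves are byte-identical), and load→save→load is
the identity. Declared roots are serialized as `rdfs:subClassOf
owl:Thing`, which is what lets QC distinguish a root from an orphan.

Definition selection is a pure priority rule over sources — termonline >
encyclopedia > CHPO > MedDRA > manual — with list order breaking ties
within a source. Fixture IRIs hash the Chinese label (31-bit polynomial
hash, hex-printed) so labels can be edited without breaking links.

QC checks: is_a cycles (every cycle reported), orphans (non-root concepts
with zero parents), missing definitions, duplicate Chinese preferred
labels (exact string equality only; near-duplicate detection is out of
scope), and — given an ABox — object assertions whose subject/object
types are not subsumed by the property's declared domain/range. An
unrestricted (empty) domain or range never violates.

## The rule engine

Rules are positive Horn clauses in a plain-text dialect:
`name: atom ^ … -> atom ^ …`, with `?x` variables, bare numeric literals,
and `swrlb:`-prefixed comparison builtins. The parser is
whitespace-insensitive and additionally absorbs two typesetting artifacts
that appear when rule text is copied from print: an em-dash arrow (`—>`)
and stray typographic quotes inside predicate names. `CDMO:`/`cdmo:`
prefixes are stripped. Invariants enforced at parse time: every
consequent variable is antecedent-bound, and builtins cannot appear in
consequents. One shipped rule (`Diet_1`) asserts a diagnosis property over
a class-atom-bound symptom variable; the engine runs it exactly as
written rather than guessing an intended symptom property.

Evaluation is set-at-a-time: each antecedent atom contributes a binding
table (class atoms via subsumption-aware individual lookup; property
atoms from the assertion tables; builtins as row filters), joined on
shared variables; each pass evaluates every rule against the current
knowledge base and asserts new consequents; passes repeat to fixpoint.
Full re-evaluation per pass is deliberate — fixture knowledge bases stay
under ~50 individuals, where a delta-restricted pass buys nothing and the
simpler evaluator is easier to verify against the naive tuple-at-a-time
oracle kept in the test suite. A `max_iterations` guard (default 100)
reports the last-added assertions if a rule set fails to converge.

Semantic choices:

* **Class atoms are subsumption-aware** (an individual typed with a
  subtype satisfies the supertype atom); **object-property atoms match
  only the asserted property** by default, because the shipped rules use
  leaf properties. Sub-property expansion along the declared property
  hierarchy is available behind a flag.
* **Units.** Data assertions carry a unit string; builtins compare raw
  numbers and error when the two sides carry different non-empty units.
  No conversion is attempted — the rule base assumes mmol/L and BMI
  consistently, and silent conversion is how threshold bugs are born.
  Comparisons are exact (`>=` at 7.0 fires at exactly 7.0).
* **Diagnosable conditions are canonical individuals.** A consequent like
  `patient_has_diagnosis(?p, ?d1)` needs `?d1` bound to something; the
  knowledge base therefore contains one canonical individual per
  diagnosable class. A consequence worth knowing: subsumption-aware
  matching diagnoses a qualifying patient with *every* diabetes-typed
  canonical individual present, which is the standard instance-level
  reading of such rules.
* No negation, retraction or priorities: the closure is monotone,
  idempotent, and independent of rule/assertion order, and the test suite
  asserts all three.

## QA knowledge injection

Retrieval is Okapi BM25 with the smoothed non-negative IDF
`log(1 + (N − df + 0.5)/(df + 0.5))`; defaults `k1 = 1.5`, `b = 0.75` are
the standard Okapi values, and the evidence count defaults to `n = 3` —
all three are config values, since no principled domain-specific value is
available. Tokenization defaults to overlapping character bigrams, the
robust choice for Chinese without a segmenter. Ties in score are broken
by document order, making retrieval fully deterministic. The prompt
template is exact and invertible: `Question: {Q}, Evidences: {D1}, …,
{Dn}` with evidences joined by `", "`; truncation is the caller's
concern. ROUGE-1/2 are clipped n-gram F1 and ROUGE-L is LCS F1, computed
over characters (whitespace ignored) — the unit standardly used for
Chinese. Model fine-tuning and inference are out of scope: the module's
contract ends at the prompt string and at scoring supplied
candidate/reference pairs, and the generic 80/20 + dev split utility is
provided for dataset preparation.

## Synthetic fixtures: what they emulate, and what they don't

Every generator is seeded, bit-reproducible, runs on its own PRNG stream
(so adding a generator never shifts another's output), and emits its
planted ground truth alongside the data; downstream recovery tests
consume only that truth, never the module under test.

* `make_micro_ontology()`: ~50 concepts under a SNOMED-style first level
  (clinical finding, procedure, substance, pharmaceutical/biologic
  product, observable entity, body structure), covering every class the
  shipped rules mention, each with zh label, English name(s) and a
  sourced definition. Content is hard-coded: the worked clinical
  scenarios must not depend on randomness. The patient class sits under
  observable entity — a pragmatic placement, since the minimal first
  level has no person branch.
* `make_target_ontology()`: an English target whose hierarchy plants 14
  child–parent pairs aligned to micro-ontology concepts (including the
  retinopathy pair), built so that the planted set is exactly the
  transitive reduction of target subsumption restricted to mapped
  classes — which is what makes "precision = recall = 1" a theorem of the
  construction rather than an empirical accident.
* `make_corpus()` (default 20 documents): plants each term in a chosen
  number of distinct documents, with grade/degree and stoplist noise
  attested *above* threshold (so exclusion, not rarity, removes them) and
  one well-attested term absent from the lexicon (so presence, not
  frequency, removes it). Ground-truth document sets are recomputed from
  the final texts by naive substring scan — independent of the automaton
  being tested. Filler text contains no lexicon surface.
* `make_patients()` (default 10 patients): random symptom subsets and
  test values at threshold ± margins (default −1…+1, 0 included, so
  exactly-at-boundary cases always occur), plus the two hard-coded
  literal scenarios. Ground truth is computed from explicit per-rule
  conditions — including the diagnosis-then-therapy chaining — not by
  running the engine.

What passing these tests shows: the algorithms are correct on inputs
whose structure and bookkeeping are fully known. What it does not show:
robustness to real clinical text (OCR noise, segmentation ambiguity,
near-duplicate labels), real ontology scale (thousands of classes,
annotation heterogeneity), or the judgment-laden parts of mapping. The
fixtures are study conditions, not simulations of the real corpus.

## Numerical and determinism choices

Numeric rule comparisons are exact doubles (thresholds like 7.0 and
scanned values like `seq(5, 10, by = 0.1)` are rounded to one decimal
before use); retention percentages round half-even to two decimals via
`round()`; all orderings that affect output (Turtle serialization,
candidate tables, mapping proposals, induced-edge processing) use
bytewise UTF-8 radix order, never locale collation. Problem sizes in the
test suite — 200 random automaton cases, knowledge bases of ~10 patients,
50-node subsumption DAGs, 10-document BM25 fixtures — were chosen as the
smallest sizes at which the properties under test are non-trivial while
the whole suite stays comfortably interactive.

## Known limitations

* The OWL subset ignores class expressions; an ontology whose hierarchy
  lives in restrictions will load as flatter than it is (with warnings).
* Aho–Corasick matching is pure R; it is ample for corpora of hundreds of
  documents but not engineered for gigabyte-scale text.
* The rule dialect covers the comparison builtins the shipped rules need;
  the wider SWRL builtin library (string, math, date) is out of scope.
* Lexicon presence stands in for live terminology-service lookups; no
  network access is performed anywhere in the package.
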