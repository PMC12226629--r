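---
title: "Rule-based report classification with radex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based report classification with radex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radex)
```

## The problem

Clinical and radiology reports bury most of their information in free text.
For audits, cohort building, and assembling labelled datasets for imaging
models, that text has to be turned into structured labels — and manual chart
review does not scale. radex implements a rule-based alternative: a clinician
writes a *search strategy* in a small query language of keywords, wildcard
modifiers, proximity operators and boolean connectors; the package compiles
each expression into word-boundary-aware regular expressions, applies them to
preprocessed report text, and classifies every report for one or more labels
with character-level evidence for each decision. Rules stay readable,
auditable and shareable without moving any patient text.

## The query language

An expression is built from:

* **keywords** with modifiers: `*` matches zero or more word characters
  (`thyr*` covers thyroid, thyroidectomy, thyroiditis), `?` matches zero or
  one (`h?emoglobin`, `wom?n`, `node?`);
* **phrases**: adjacent bare words (`thyroglossal cyst`) must occur
  adjacently in the text;
* **proximity**: `NEAR/X` (order-independent) and `THEN/X` (order-dependent)
  accept at most `X` intervening words between two term patterns;
* **connectors**: `AND`, `OR`, `NOT`, and `EXCEPT` (sugar for `AND NOT`),
  with precedence `NOT > AND > OR` and parentheses to override it;
* **shorthand**: `&`, `|`, `¬`, and `~X` are interchangeable with the
  verbose spellings, as in printed strategy tables;
* **class references**: a double-quoted name (`"Thyroid nodule(s)"`) refers
  to the boolean result of a class defined earlier in the same strategy, so
  *derived* classes reuse the one grammar and one evaluator.

```{r}
parse_query('nodul* & ¬(nodul*~2cartilage)')
compile_term("thyr*")$pattern
compile_proximity("thyroid NEAR/2 nodules")$pattern
```

`?` deliberately compiles to *zero-or-one* word character rather than
exactly one: `h?emoglobin` must cover both British and American spellings.
The side effect is that `wom?n` also matches the typo "womn"; for a
screening tool that over-match is the safer direction.

Proximity gaps compile to `{0,X}` intervening words with a lazy quantifier,
so reported spans are minimal, which keeps highlighting tight. `NEAR/X`
is the alternation of both `THEN/X` directions, which makes the symmetry
`NEAR(a,b) == NEAR(b,a)` and monotonicity in `X` testable properties rather
than accidents.

Word characters are letters and digits only. Hyphen and slash act as word
separators, so after standardisation "post-op" reads "post op" and "u2/u3"
reads "u2 u3". Two entries of the packaged strategy rely on this: the
combined-grading exclusions are written as the adjacent phrase `u2 u3` and
as `u2~1?3` (which also catches "u2 or 3" and "u2 3"). These two spellings
normalise typographically garbled variants of the same exclusions; the
intent — suppressing a single-grade label when a combined grading such as
"U2/U3" is reported — is preserved, and the packaged file documents the
normalisation.

## Preprocessing

Reports are filtered (date ranges, age, exam codes, most-recent-per-patient
deduplication), split into sections at configurable literal headers
("Clinical history:", "Findings:"), lowercased, punctuation-mapped, and
sentence-tokenised. Every standardised sentence carries an offset map back
to the raw report, so all evidence spans are reported in raw-text
coordinates (1-based, inclusive, the natural convention for R's `substr`)
and highlighting never drifts.

Sentence boundaries are `.`, `!`, `?` and blank lines, with two guards for
terse clinical prose: a period after a single letter (initials) or after a
unit token such as "mm" does not split, and decimal points inside numbers
are preserved.

Stopword removal is **off** by default and available behind a flag. The
reason is proximity semantics: `thyroid NEAR/2 nodules` is meant to count
the actual words between the terms ("thyroid contains multiple nodules"
has two). Removing stopwords would silently shrink those distances; when
the flag is on, gap counts refer to the surviving tokens only, and that
behaviour is tested against the brute-force evaluator on the reduced token
stream.

## Negation

Negated findings must not produce positive labels. radex implements the
classic trigger-based scheme: pre-negation triggers ("no", "without",
"no evidence of") negate matches up to `scope` tokens after them;
post-negation triggers ("not seen", "ruled out") act backwards;
pseudo-triggers ("no change", "not only") look like triggers but never
negate and mask the real triggers they contain; terminators ("but",
"however") break scope; and negation never crosses a sentence boundary.
The default scope is 5 tokens — the convention for this family of
algorithms, since no other value is mandated by the method itself — and the
packaged trigger file is an editable plain-text table seeded with the
standard trigger set.

Hypothetical and uncertain phrasings ("query nodule", "possible
malignancy") are *not* treated as negation: an uncertainty lexicon flags
such matches but never suppresses them, which mirrors how rule-based
systems typically fail on hypothetical sentences and keeps those failures
visible for review. Whether negation applies to a class is configurable
per class: the packaged strategy disables it for the two examination
classes, because "no abnormal lymph nodes" still documents that the lymph
nodes were examined.

## The engine

A strategy is an ordered list of named classes plus post-processing rules.
Non-derived classes are evaluated over their configured sections; if none
of a class's sections exists in a report, the class falls back to the
`body` section, so unstructured reports still classify. `AND` is evaluated
at section scope by default — its children may match in different
sentences, which is what concept-level rules like `surgery & ¬refer*~2surgery`
need — and can be switched to sentence scope per run. A bare `NOT` query is
legal and evaluates against the class's whole section set.

Derived classes are ordinary queries over quoted class references and are
computed after the searched classes. Post-processing rules are implications
("if BTA U3 then Thyroid nodule(s)") applied in file order; derived classes
are then re-evaluated once and the engine asserts that a second pass
changes nothing. Labels forced by a post rule are recorded in the result's
`forced` field, since they are positive without textual evidence — every
other positive non-derived label is backed by at least one non-negated
span. When a boolean branch is absent its spans are dropped, so evidence
under a failed `AND` (for example a wholly negated branch) does not leak
into the output; negated matches of top-level branches are kept, flagged,
and drawn distinctly in highlights.

The packaged strategy (`thyroid_strategy()`) classifies neck/thyroid
ultrasound reports for fourteen features: thyroid and lymph-node
examination, thyroid nodule(s), multiple and solitary nodules, altered
echotexture, goitre, previous thyroid surgery, the British Thyroid
Association gradings U1–U5, and normal thyroid. Beyond the four
grading-implies-nodule rules, it adds one more consistency implication of
the same kind — multiple nodules imply nodule presence — because
"multinodular goitre" alone never matches the nodule query's stems, and a
dataset stating multiple nodules without nodule presence would be
internally inconsistent.

## The synthetic corpus

`generate_corpus()` is a seeded template grammar over phrase banks:
openings, normal descriptions, negated findings, solitary/multiple nodule
findings, BTA gradings, echotexture and goitre phrases, surgery history,
lymph-node sentences, distractor pathology (parotid, salivary,
submandibular and thyroglossal cysts), neutral filler, and deliberately
difficult hedged phrasings. Every phrase carries the labels it implies, so
each report's 14-class ground-truth vector is exact by construction and
satisfies the derived-class identities (solitary = nodule and not
multiple; normal = examination with no focal or diffuse abnormality;
gradings imply nodules).

Default rates are one fixed choice of what a radiology audit corpus
plausibly looks like: 85% thyroid examinations (the rest are other neck
studies), nodule status 45/30/25% none/solitary/multiple, gradings stated
for half of nodule reports, lymph nodes mentioned in half, roughly one
report in ten unstructured without headers, and a mean report length of 93
words, matching the kind of terse UK ultrasound reporting the packaged
strategy targets. Reports containing phrases that defeat purely lexical
rules — "thyroid gland appears slightly enlarged" (hedged goitre), "query
small nodule" (hypothetical), "thyroglossal duct cyst" (an exclusion
phrase interrupted by "duct") — are tagged `ambiguous`; they are generated
on purpose, excluded from exact-agreement checks, and kept as regression
material, because they reproduce the real failure modes of this method.

What passing the end-to-end test shows, therefore, is that the engine
implements the strategy's semantics exactly on text whose truth is known;
it does not show clinical accuracy. Real reports have typos, dictation
artefacts, idiosyncratic section headers and genuinely ambiguous findings
at rates a template grammar cannot estimate; the paper-and-pencil
refinement loop (`flag_discrepancies()`, highlight review, edit, re-run)
exists precisely because real corpora disagree with any fixed rule set.

## Numerical and design choices

* Spans are 1-based inclusive on the raw text; `substr(raw, start, end)`
  reproduces every span exactly, and tests assert this for all generated
  cases.
* Parsing errors are structured conditions (kind, character position,
  class name) accumulated by `validate_strategy()` rather than raised one
  at a time, so a strategy file's problems are reported together.
* Undefined metric ratios (0/0) are `NA` with a warning, never silently 0;
  macro-averages exclude undefined classes and say so. Cohen's kappa with
  constant marginals is reported as undefined.
* Micro-averages are computed from pooled confusion counts and are
  asserted to equal `label_metrics()` of the summed counts exactly.
* The evaluator's correctness case is equivalence with a brute-force
  token-window oracle on randomly generated queries and sentences (1,000
  cases per suite, fixed seeds), plus algebraic properties: NEAR symmetry,
  gap monotonicity, De Morgan's law at presence level, and a
  precedence oracle that parses by lowest-precedence splitting.
* Problem sizes in the shipped checks — 200 labelled reports for
  end-to-end agreement and metric evaluation, 10,000 for the throughput
  run — keep the whole suite comfortably reproducible on a laptop-class
  single CPU.

## Known limitations

Lexical rules cannot read context: hedged or hypothetical language
produces false positives by design (flagged, not suppressed), and concepts
requiring information outside the report text are out of reach. The
sectioniser matches literal headers; OCR noise or free-form headings need
the fallback body path. No ontology expansion, spelling correction,
stemming or fuzzy matching is performed beyond `*` and `?` — widening a
concept is the strategy author's job, supported by the refinement loop.
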