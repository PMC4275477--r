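---
title: "Searching a monolingual PubMed subset: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searching a monolingual PubMed subset: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medlingua)
```

## Overview

`medlingua` is a compact, fully testable implementation of a
terminology-driven search engine for a monolingual subset of MEDLINE/PubMed,
together with the evaluation protocol used to compare such an engine against
alternative retrieval strategies. This vignette documents the model, its
tunable parameters, the numerical and design choices that were genuinely
open, what the synthetic-data generator does and does not emulate, and known
limitations.

## The retrieval model

### Query interpretation

A free-text query in the subset language is interpreted in three stages:

1. **Predefined queries first.** If the whole normalized string matches the
   label of a curated predefined query, its stored boolean expression of
   `descriptor[/qualifier]` terms wins outright ("natremia" →
   sodium/blood). This mirrors how curated mappings are meant to override
   word-level matching.
2. **Greedy longest-match segmentation.** Otherwise the token sequence is
   scanned left to right, always consuming the longest span that matches a
   concept label, synonym, acronym, or metaterm name in the query language.
   Ties between equal-length candidates of different kinds are broken by a
   configurable priority, default `predefined > metaterm > descriptor >
   supplementary > qualifier`. The literature on such engines does not fix
   a tie-break; we prefer broader concepts because metaterms exist
   precisely to widen overly-specific descriptor matching. Ambiguous
   acronyms keep their first-listed sense and log a message — no
   disambiguation rule is defined by the source material, so the choice is
   deliberately simple and visible.
3. **Residual words.** Unconsumed tokens become word terms after stop-word
   removal. Stop words are *never* removed from candidate concept spans, so
   "maladie de Crohn" matches as a whole; and a query made only of stop
   words keeps them as word terms rather than interpreting to nothing.

All terms are combined conjunctively (AND), matching the observable
behaviour of the field's mainstream engines; no explicit operator syntax is
supported.

### Normalization

Concept matching is mediated entirely by `normalize_text()`: NFC
composition, case folding, typographic-apostrophe unification, French
elision removal (`l'`, `d'`, `j'`, `n'`, `s'`, `t'`, `qu'` before an
apostrophe, the apostrophe then acting as a separator), ligature expansion
(œ → oe, æ → ae), diacritic stripping, and tokenization on remaining
non-alphanumerics. The function is idempotent, and the lookup tables are
keyed on its output, so matching is invariant under case, accentuation and
elision — the exact French particularities that defeat engines without
language-aware handling. Elision is the only language-specific step and is
active for French only.

### Scoring and ranking

Each conjunctive term earns the credit of the best channel through which it
matches a citation:

| channel                                    | credit |
|--------------------------------------------|--------|
| query word in the title                    | 1.0    |
| concept as major-topic annotation          | 1.0    |
| concept as minor-topic annotation          | 0.7    |
| word only in the abstract                  | 0.5    |
| concept annotated automatically            | × 0.8  |

and the score is `100 × Σ credit / n_terms`. The *anchor* of this table —
query words in the title and major topics giving a perfect 100 — and the
*ordering* of the criteria (title/major above minor topic, human above
automatic indexing, date as tie-break) are fixed by the engine being
modelled; the intermediate numeric values are this package's own choice,
selected once to make the stated orderings strict, and are overridable via
`credit_table()`. Equal scores are ordered by publication year descending,
then PMID descending; `lifo` ranking uses that date ordering alone.
Publication year (with PMID as within-year proxy) stands in for entry date,
which is not among the parsed fields. A missing year is kept (`NA`) and
sorts last within its score stratum — coverage must not silently drop
citations.

### Strategies

* `semantic` — concept terms match concept postings (metaterms expanded to
  their linked concepts, descriptors exploded over the hierarchy) *or*
  their label tokens in the title; residual words match the configured
  fields (default title + abstract; the field set is configurable because
  the engine being modelled does not document whether words reach
  abstracts).
* `title_only` — every normalized query token must appear in the
  vernacular (transliterated) title; no concept mapping. This models
  searching the `[TT]` field.
* `all_fields` — case-folded tokens without diacritic folding or elision
  splitting, matched across all text fields plus the English preferred
  labels of each citation's annotations. This deliberately weak
  normalization emulates an engine whose poor coverage of French queries
  stems from exactly those gaps, and makes the coverage-gap pattern a
  testable property rather than an anecdote.

Hierarchy explosion happens at query time (not index time), default on, so
the index stays small and the behaviour is switchable per call. Metaterm
links are exploded too — metaterms exist to broaden retrieval, so the
broader reading is the default; `explode = FALSE` turns both off.

Both rankings return the same boolean match set; `total_hits` (the coverage
number) is ranking-invariant, which the test suite asserts.

### Annotation origin

MEDLINE XML carries no per-heading origin, so the citation-level
`IndexingMethod` attribute (`"Automated"`/`"Curated"` → automatic; absent →
human) is read and applied to all of a citation's headings. This is the
finest origin signal available in the input format.

## The evaluation protocol

Relevance is judged on a 3-level scale. Strict precision counts only fully
relevant citations among those retrieved (at most the first 20); relaxed
precision also counts partially relevant ones. Pooling across queries is
**micro-averaged**: `Σ relevant / Σ retrieved`, with zero-result queries
contributing to neither sum. Micro-averaging is the only pooling rule that
reproduces all five published totals of the packaged benchmark, including
the arms where some queries retrieved far fewer than 20 citations; with
balanced retrieved counts it coincides with the macro average (asserted as
a property test).

The packaged benchmark tables store per-query precisions to the two
printed decimals; integer relevant counts are recovered as
`round(precision × retrieved)` and the recovery is verified to round-trip
back to the printed value when the tables are loaded.

Statistical companions:

* `pearson_with_ci()` — sample correlation with the standard Fisher-z 95%
  interval (delegated to `stats::cor.test`).
* `mann_whitney()` — rank-sum U with mid-ranks; exact p by full enumeration
  of group assignments when `n + m ≤ 16` (the enumeration handles ties,
  which the standard exact implementation does not), otherwise the normal
  approximation with tie and continuity corrections. Two-sided and
  unpaired by default: the benchmark comparisons are between per-query
  coverage columns, and neither sidedness nor pairing is documented for
  them, so the conventional two-sided unpaired form is used and named.
* `fisher_exact()` — the two-sided p as the sum of hypergeometric
  probabilities no larger than the observed table's. The benchmark's
  pooled strict-precision contrast is reconstructed as
  `((372, 28), (370, 10))` from the per-query cells; the exact 2×2 behind
  the published p-value is not recoverable from the printed data, so this
  reconstruction is documented as an assumption and the acceptance check
  allows for it.

Three sensitivity scenarios (`sensitivity_reanalysis()`) recompute pooled
precision with a problem query excluded, zeroed for named strategies, or
assumed fully relevant — the standard way to bound the bias introduced by a
query that an engine silently rewrote.

## The synthetic-data generator

`generate_mini_mesh()` emits a small but structurally complete terminology:
a descriptor forest with dotted tree numbers, per-language labels and
synonyms (French forms always carry a diacritic or ligature, so
normalization is genuinely exercised), acronyms including one ambiguous
one, qualifiers, metaterms, bilingual predefined queries, and an
untranslated supplementary concept. Each language draws its labels from
its own pseudo-words, so a label never collides across languages — the
translation gap that the `all_fields` emulation must be able to expose.

`generate_corpus()` plants, for each of `n_queries` leaf descriptors,
exactly `planted_per_query` relevant citations: all carry the concept as an
annotation, half (by default) also carry its label verbatim in the
vernacular title, and the rest are reachable only through the annotation.
All other text is drawn from a pseudo-word vocabulary whose consonant
inventory is disjoint from the terminology's, so the planted sets are
*exactly* the retrievable sets and recovery oracles are exact. Leaf
descriptors are used so hierarchy explosion cannot drag one query's records
into another's. Default study conditions — 150 citations, 3 queries, 10–12
planted records each, 50% title evidence, 20% partially relevant, 30%
automatic annotations, years 1995–2014, ~10% other-language and ~4%
mislabeled records — are sized so that the full pipeline (generate → parse
→ filter → index → search → judge) runs in seconds while still exercising
every branch; they are the package's fixed reference conditions, not knobs
to tune per run.

What the generator does **not** emulate: natural-language titles and
abstracts (text is closed-vocabulary nonsense), realistic term frequency
distributions, partial or fuzzy label overlap between queries and
citations, translation errors, or corpus scale. Passing the planted-recovery
tests therefore demonstrates the correctness of the matching, indexing and
ranking machinery — not retrieval quality on real literature, which is what
the packaged benchmark tables speak to.

## Numerical choices and degenerate inputs

* Ties in ranking are broken deterministically (year, then PMID
  descending), so all outputs are reproducible for a given input order.
* A citation without a PMID is skipped with a warning; a malformed XML
  stream aborts with a parse error.
* `precision_at_k` on an empty retrieval returns `NA` (and pooled precision
  over an all-empty strategy errors) rather than silently reporting 0 or 1.
* `fisher_exact` returns p = 1 with a warning on a zero margin; the
  hypergeometric summation uses a `1 + 1e-7` relative guard against
  floating-point misclassification of equal-probability tables, matching
  standard practice.
* The Mann-Whitney exact branch caps at `n + m ≤ 16` (12,870 enumerated
  assignments) — exact where the benchmark needs it, cheap everywhere.
* Seeds: every stochastic component (`generate_mini_mesh`,
  `generate_corpus`, test properties) runs under an explicit seed via
  `withr::with_seed`; identical seeds give byte-identical fixture files.

## Scope and limitations

* The plausibility screen for mislabeled language tags (require a
  vernacular title) is a documented proxy, off by default: no authoritative
  exclusion rule exists for the discrepancy it addresses.
* `see_also` relations are stored and exposed but play no retrieval role.
* No spelling correction, wildcard/truncation syntax, boolean OR/NOT user
  syntax, or automatic cross-language fallback of failed queries: the last
  is deliberately a non-feature, since silent query translation is exactly
  the failure mode the sensitivity analyses quantify.
* Supplementary concepts match only in languages where a translation
  exists; untranslated ones match via English.
* The package holds indexes in memory as tidy tables; it is sized for
  method development and evaluation corpora (10²–10⁵ citations), not for
  serving a production database.
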