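# medlingua

Monolingual search of multilingual bibliographic subsets with a MeSH-style
terminology, plus the evaluation protocol to compare retrieval strategies.

## The problem

PubMed/MEDLINE contains hundreds of thousands of citations written in
languages other than English (about 680,000 tagged French alone), but its
query handling is built for English: French users hit the wall of
accentuation, elision ("l'angine"), and untranslated MeSH vocabulary, and
either retrieve almost nothing or fall back on weak workarounds such as
restricting queries to the transliterated-title (`[TT]`) field.

`medlingua` implements, end to end, the machinery needed to search one
language's subset *in that language*:

* **Subset extraction** — a `PubmedArticleSet` XML parser, a language
  filter (with an optional plausibility screen for mislabeled records), and
  a line-delimited persistence format (`parse_citations()`,
  `filter_language()`, `write_subset()`/`read_subset()`).
* **Terminology** — a multilingual MeSH-style store (descriptors with tree
  numbers, qualifiers, supplementary concepts) enriched with per-language
  synonyms, acronyms (including ambiguous ones), specialty-level
  *metaterms* (e.g. psychiatry → {psychiatry, psychiatric hospital}), and
  curated *predefined queries* (e.g. natremia → sodium/blood)
  (`read_terminology()`, `match_label()`, `mesh_explode()`,
  `expand_metaterm()`, `resolve_predefined_query()`).
* **Query interpretation** — language-aware normalization (case,
  diacritics, ligatures œ/æ, French elision) and greedy longest-match
  segmentation of free text into concept terms plus residual words
  (`normalize_text()`, `interpret_query()`).
* **Ranked retrieval** — an inverted index over words and concept
  annotations, three strategies (`semantic`, `title_only`, and a
  deliberately weaker `all_fields` emulation of an engine without
  language-aware normalization), relevance and LIFO rankings, and faceted
  refinement (`build_index()`, `search_citations()`, `refine_facet()`).
* **Evaluation** — strict/relaxed precision at 20 on a 3-level relevance
  scale, coverage, pooled (micro-averaged) precision, sensitivity
  re-analyses, Pearson correlation with a Fisher-z interval, an exact
  Mann-Whitney test and Fisher's exact test (`precision_at_k()`,
  `pooled_precision()`, `coverage_total()`, `mann_whitney()`,
  `fisher_exact()`), plus packaged per-query benchmark tables from a
  published evaluation of five French retrieval strategies
  (`benchmark_tables()`).
* **Synthetic fixtures** — deterministic generators for mini terminologies
  and citation corpora with *planted relevance*, so every pipeline stage is
  testable without any download (`generate_mini_mesh()`,
  `generate_corpus()`).

## The ranking model

A query is a conjunction of terms (concepts and residual words). A matching
citation's score is

```
score = 100 × Σ_t credit(t) / n_terms
```

where each term takes the credit of the best channel through which it
matches: a query word in the title or a human-assigned major-topic MeSH
annotation earns 1.0; a minor-topic annotation 0.7; a word found only in
the abstract 0.5; concept credit is multiplied by 0.8 when the annotation
was assigned automatically rather than by a librarian. A query perfectly
matched in the title and as major topics therefore scores exactly 100;
among equal scores the most recent citation ranks first. The individual
weights are tunable through `credit_table()`.

## Worked example

```r
library(medlingua)

mesh <- file.path(tempdir(), "mesh"); generate_mini_mesh(mesh, seed = 42)
store <- read_terminology(mesh)
store
#> <terminology> 12 descriptors, 3 qualifiers, 2 supplementary concepts,
#> 2 metaterms, 2 predefined queries; languages: eng, fre

corpus <- generate_corpus(corpus_spec(seed = 42, n_citations = 120),
                          store, file.path(tempdir(), "corpus"))
subset <- parse_citations(corpus$xml) |> filter_language("fre")
index  <- build_index(subset, store, "fre")

q <- corpus$queries$query[[1]]          # "pïcogu", a planted French label
interpret_query(q, "fre", store)
#> <structured_query> "pïcogu" [fre]
#>   concept terms:
#>     D003 (descriptor, via preferred: "picogu")

search_citations(index, q, strategy = "semantic", ranking = "relevance", k = 5)
#> <search_result> "pïcogu" (semantic, relevance): 10 hits
#> # A tibble: 5 × 4
#>    rank pmid   score  year
#>   <int> <chr>  <dbl> <int>
#> 1     1 100001   100  2012
#> 2     2 100006   100  2006
#> 3     3 100003   100  2006
#> 4     4 100007   100  1999
#> 5     5 100004   100  1999
```

Ten citations were planted relevant to this query; the semantic strategy
retrieves all ten (`total_hits`), even though only five carry the label in
their title — a `title_only` search over the same index finds exactly those
five. Scores of 100 are titles/major topics perfectly matching the query;
ties are ordered by year, then PMID.

The packaged benchmark tables reproduce the published aggregates:

```r
tabs <- benchmark_tables()
cells <- dplyr::filter(tabs$precision, strategy == "multilingual_french")
pooled_precision(cells, "strict")   # 0.93
pooled_precision(cells, "relaxed")  # 0.95
coverage_total(tabs$coverage$multilingual_french)  # 42384
pearson_with_ci(tabs$response_times$seconds, tabs$response_times$citations)
#> # A tibble: 1 × 5
#>       r conf_low conf_high     n  p_value
#> 1 0.728    0.422     0.885    20 0.000271
```

`autoplot()` on a search result, `plot_precision_cells()` and
`plot_coverage()` on the evaluation tables give the standard figures;
`tidy()`/`glance()` methods return broom-style tibbles.

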