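Package: medlingua
Title: Monolingual Search of Multilingual Bibliographic Subsets with a
    MeSH-Style Terminology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to extract a monolingual subset from MEDLINE/PubMed
    citation XML, index it against a multilingual MeSH-style terminology
    enriched with synonyms, acronyms, metaterms and predefined queries,
    and run ranked concept-plus-word retrieval with faceted refinement.
    Includes an evaluation protocol for comparing retrieval strategies:
    strict and relaxed precision at 20, coverage, pooled (micro-averaged)
    precision, Pearson correlation with Fisher-z confidence intervals,
    exact Mann-Whitney and Fisher tests, and sensitivity re-analyses,
    together with deterministic generators for synthetic terminologies
    and citation corpora with planted relevance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
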