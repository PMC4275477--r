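#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a search result
#'
#' One row per ranked hit, broom-style.
#'
#' @param x A `search_result`.
#' @param ... Unused.
#' @return A tibble with columns `rank`, `pmid`, `score`, `year`.
#' @export
tidy.search_result <- function(x, ...) {
  x$hits
}

#' One-row summary of a search result
#'
#' @param x A `search_result`.
#' @param ... Unused.
#' @return A tibble with columns `query`, `strategy`, `ranking`,
#'   `total_hits`, `k`, `top_score`.
#' @export
glance.search_result <- function(x, ...) {
  tibble::tibble(
    query = x$query_text, strategy = x$strategy, ranking = x$ranking,
    total_hits = x$total_hits, k = x$k,
    top_score = if (nrow(x$hits) > 0L) x$hits$score[[1]] else NA_real_
  )
}

#' Tidy a structured query
#'
#' One row per conjunctive term (concept terms first, then word terms).
#'
#' @param x A `structured_query`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `type`, `ui`, `qualifier_ui`,
#'   `kind`, `source`.
#' @export
tidy.structured_query <- function(x, ...) {
  ct <- x$concept_terms
  dplyr::bind_rows(
    tibble::tibble(term = ct$text, type = "concept", ui = ct$ui,
                   qualifier_ui = ct$qualifier_ui, kind = ct$kind,
                   source = ct$source),
    tibble::tibble(term = x$word_terms, type = "word", ui = NA_character_,
                   qualifier_ui = NA_character_, kind = NA_character_,
                   source = NA_character_)
  )
}
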