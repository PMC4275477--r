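#' Structured query object
#'
#' The interpreted form of a free-text query: a conjunction of concept terms
#' (descriptor, optionally qualified; qualifier; supplementary concept;
#' metaterm) and residual word terms. Built by [interpret_query()] or
#' [resolve_predefined_query()].
#'
#' @param text Original query text.
#' @param lang Language the query was interpreted in.
#' @param concept_terms Tibble with columns `ui`, `qualifier_ui`, `kind`,
#'   `source`, `text` (the normalized matched span).
#' @param word_terms Character vector of residual normalized tokens.
#' @return An object of class `structured_query`.
#' @export
structured_query <- function(text, lang, concept_terms = empty_concept_terms(),
                             word_terms = character(0)) {
  structure(
    list(text = text, lang = lang, concept_terms = concept_terms,
         word_terms = word_terms, connective = "AND"),
    class = "structured_query"
  )
}

empty_concept_terms <- function() {
  tibble::tibble(ui = character(), qualifier_ui = character(),
                 kind = character(), source = character(), text = character())
}

#' @export
print.structured_query <- function(x, ...) {
  cat("<structured_query> \"", x$text, "\" [", x$lang, "]\n", sep = "")
  if (nrow(x$concept_terms) > 0L) {
    cat("  concept terms:\n")
    for (i in seq_len(nrow(x$concept_terms))) {
      ct <- x$concept_terms[i, ]
      cat("    ", ct$ui,
          if (!is.na(ct$qualifier_ui)) paste0("/", ct$qualifier_ui) else "",
          " (", ct$kind, ", via ", ct$source, ": \"", ct$text, "\")\n",
          sep = "")
    }
  }
  if (length(x$word_terms) > 0L) {
    cat("  word terms:", paste(x$word_terms, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of conjunctive terms in a query
#' @param query A `structured_query`.
#' @return Integer count of concept plus word terms.
#' @export
n_query_terms <- function(query) {
  nrow(query$concept_terms) + length(query$word_terms)
}

default_kind_priority <- c("predefined", "metaterm", "descriptor",
                           "supplementary", "qualifier")

#' Interpret a free-text query against the terminology
#'
#' Interpretation proceeds in three stages. (1) If the whole normalized
#' string matches a predefined-query label, that curated expression wins
#' outright. (2) Otherwise the token sequence is segmented greedily left to
#' right, always taking the longest span that matches a terminology label,
#' synonym, acronym or metaterm name; ties between equal-length candidates of
#' different concept kinds are broken by `priority`. An ambiguous acronym
#' keeps its first-listed sense (a message notes the discarded senses).
#' (3) Unconsumed tokens become residual word terms after stop-word removal —
#' stop words are never removed from candidate concept spans, so labels like
#' "maladie de Crohn" match whole. All terms are combined conjunctively.
#'
#' If the query consists solely of stop words, the tokens are kept as word
#' terms so a non-empty query never interprets to nothing.
#'
#' @param text Query text.
#' @param lang Three-letter language code declared in the store.
#' @param store A `terminology` object.
#' @param priority Concept-kind tie-break order for equal-length matches.
#' @return A [structured_query].
#' @export
interpret_query <- function(text, lang, store,
                            priority = default_kind_priority) {
  stopifnot(inherits(store, "terminology"))
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("query text must be a non-empty string", call. = FALSE)
  }
  pre <- resolve_predefined_query(store, text, lang)
  if (!is.null(pre)) return(pre)

  tokens <- normalize_text(text, lang)
  lookup <- store$lookup |> dplyr::filter(.data$lang == !!lang)
  max_span <- if (nrow(lookup) == 0L) 1L else {
    max(stringr::str_count(lookup$norm, stringr::fixed(" "))) + 1L
  }

  concept_rows <- list()
  residual <- character(0)
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    matched <- FALSE
    for (len in seq(min(max_span, n - i + 1L), 1L)) {
      key <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      cand <- lookup[lookup$norm == key, ]
      if (nrow(cand) > 0L) {
        cand <- cand[order(match(cand$concept_kind, priority)), ]
        if (nrow(cand) > 1L && any(cand$ambiguous)) {
          message("ambiguous match for \"", key, "\": keeping ",
                  cand$ui[[1]], ", discarding ",
                  paste(cand$ui[-1], collapse = ", "))
        }
        if (cand$concept_kind[[1]] == "predefined") {
          # a predefined label inside a longer query expands to its expression
          concept_rows[[length(concept_rows) + 1L]] <-
            resolve_predefined_query(store, key, lang)$concept_terms
        } else {
          concept_rows[[length(concept_rows) + 1L]] <- tibble::tibble(
            ui = cand$ui[[1]], qualifier_ui = NA_character_,
            kind = cand$concept_kind[[1]], source = cand$source[[1]],
            text = key
          )
        }
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      residual <- c(residual, tokens[[i]])
      i <- i + 1L
    }
  }

  sw <- stop_words(lang)
  word_terms <- setdiff(residual, sw)
  if (length(word_terms) == 0L && length(concept_rows) == 0L) {
    word_terms <- residual
  }
  structured_query(
    text = text, lang = lang,
    concept_terms = dplyr::bind_rows(empty_concept_terms(), concept_rows),
    word_terms = word_terms
  )
}
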