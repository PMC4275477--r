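#' Relevance credit table
#'
#' Per-term credits used by [score_citation()]. A term matched by a title
#' word or a major-topic concept earns full credit; a minor-topic concept and
#' an abstract-only word earn less; concept credit is discounted when the
#' annotation was assigned automatically rather than by a librarian. A query
#' whose every term is matched in the title or as a human-assigned major
#' topic therefore scores exactly 100. The individual weights are tunable;
#' the defaults keep the intended orderings strict
#' (title = major > minor > abstract; human > automatic).
#'
#' @param title Credit for a query word present in the title (default 1).
#' @param major Credit for a concept present as a major topic (default 1).
#' @param minor Credit for a concept present as a minor topic (default 0.7).
#' @param abstract Credit for a word present only in the abstract
#'   (default 0.5).
#' @param automatic Multiplier on concept credit when the annotation origin
#'   is automatic (default 0.8).
#' @return A named list of credits.
#' @export
credit_table <- function(title = 1, major = 1, minor = 0.7, abstract = 0.5,
                         automatic = 0.8) {
  stopifnot(title > 0, major > 0, minor > 0, abstract > 0,
            automatic > 0, automatic <= 1)
  list(title = title, major = major, minor = minor, abstract = abstract,
       automatic = automatic)
}

#' Build an inverted index over a monolingual subset
#'
#' Builds, deterministically for a given record order:
#' * normalized word postings per field (`title`, `tt` for the
#'   vernacular/transliterated title, `abstract`), tokens via
#'   [normalize_text()] in the subset language;
#' * case-folded raw postings over all text fields plus the English preferred
#'   labels of each citation's annotations, via [casefold_tokens()] — the
#'   substrate of the deliberately weaker `all_fields` strategy;
#' * concept postings, one row per MeSH annotation, with major flag, origin
#'   and qualifier list;
#' * facet tables (year, journal country, publication type, journal).
#'
#' @param citations Citation tibble (one language subset).
#' @param store A `terminology` object.
#' @param lang Three-letter language code of the subset.
#' @param strict Error on annotations whose descriptor is unknown to the
#'   store (default: drop them with a message).
#' @return An object of class `subset_index`.
#' @export
build_index <- function(citations, store, lang, strict = FALSE) {
  stopifnot(inherits(store, "terminology"))
  field_postings <- function(texts, field) {
    toks <- purrr::map(texts, function(t) {
      if (is.na(t)) character(0) else unique(normalize_text(t, lang))
    })
    tibble::tibble(
      field = rep(field, sum(lengths(toks))),
      token = as.character(unlist(toks)),
      pmid = rep(citations$pmid, lengths(toks))
    )
  }
  norm_postings <- dplyr::bind_rows(
    field_postings(citations$title, "title"),
    field_postings(citations$transliterated_title, "tt"),
    field_postings(citations$abstract, "abstract")
  )

  eng_label <- function(ui) {
    lab <- preferred_label(store, ui, "eng")
    if (is.na(lab)) "" else lab
  }
  raw_toks <- purrr::pmap(
    list(citations$title, citations$transliterated_title,
         citations$abstract, citations$annotations),
    function(title, tt, abstract, ann) {
      concept_text <- paste(purrr::map_chr(ann$descriptor_ui, eng_label),
                            collapse = " ")
      txt <- paste(c(title, tt, abstract, concept_text)[
        !is.na(c(title, tt, abstract, concept_text))], collapse = " ")
      unique(casefold_tokens(txt))
    }
  )
  raw_postings <- tibble::tibble(
    token = as.character(unlist(raw_toks)),
    pmid = rep(citations$pmid, lengths(raw_toks))
  )

  concept_postings <- dplyr::bind_rows(purrr::map2(
    citations$pmid, citations$annotations,
    function(pmid, ann) {
      if (nrow(ann) == 0L) return(NULL)
      dplyr::mutate(ann, pmid = pmid, .before = 1L)
    }
  ))
  if (nrow(concept_postings) == 0L) {
    concept_postings <- dplyr::mutate(empty_annotations(),
                                      pmid = character(), .before = 1L)
  }
  unknown <- !concept_postings$descriptor_ui %in%
    c(store$descriptors$ui, store$supplementary$ui)
  if (any(unknown)) {
    bad <- unique(concept_postings$descriptor_ui[unknown])
    if (strict) {
      stop("annotations reference unknown concepts: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    message("dropping annotations with unknown concepts: ",
            paste(bad, collapse = ", "))
    concept_postings <- concept_postings[!unknown, , drop = FALSE]
  }

  facets <- tibble::tibble(
    pmid = citations$pmid,
    year = citations$pub_year,
    country = citations$journal_country,
    journal = citations$journal_title,
    pub_types = citations$pub_types
  )

  structure(
    list(lang = lang, store = store, citations = citations,
         norm_postings = norm_postings, raw_postings = raw_postings,
         concept_postings = concept_postings, facets = facets),
    class = "subset_index"
  )
}

#' @export
print.subset_index <- function(x, ...) {
  cat("<subset_index> ", nrow(x$citations), " citations [", x$lang, "], ",
      nrow(x$norm_postings), " word postings, ",
      nrow(x$concept_postings), " concept postings\n", sep = "")
  invisible(x)
}

pmids_with_token <- function(index, token, fields) {
  p <- index$norm_postings
  unique(p$pmid[p$token == token & p$field %in% fields])
}

pmids_with_all_tokens <- function(index, tokens, fields) {
  if (length(tokens) == 0L) return(character(0))
  Reduce(intersect, purrr::map(tokens, pmids_with_token, index = index,
                               fields = fields))
}

# descriptor/qualifier uis a concept term reaches after metaterm expansion
# and (optionally) hierarchy explosion
term_target_uis <- function(index, term, explode) {
  store <- index$store
  base <- if (term$kind == "metaterm") {
    store$metaterms$linked[[match(term$ui, store$metaterms$ui)]]
  } else if (term$kind == "supplementary") {
    i <- match(term$ui, store$supplementary$ui)
    c(term$ui, store$supplementary$mapped_descriptors[[i]])
  } else {
    term$ui
  }
  if (explode) {
    base <- unique(unlist(purrr::map(base, function(u) {
      if (u %in% store$descriptors$ui) mesh_explode(store, u) else u
    })))
  }
  base
}

# concept postings matching one concept term (descriptor set + qualifier
# constraint for descriptor matches, direct qualifier matches for qualifier
# uis in the target set)
term_concept_postings <- function(index, term, explode) {
  uis <- term_target_uis(index, term, explode)
  cp <- index$concept_postings
  hit <- cp$descriptor_ui %in% uis
  if (!is.na(term$qualifier_ui)) {
    hit <- hit & purrr::map_lgl(cp$qualifier_ui, function(q) {
      term$qualifier_ui %in% q
    })
  }
  qual_uis <- intersect(uis, index$store$qualifiers$ui)
  if (length(qual_uis) > 0L) {
    hit <- hit | purrr::map_lgl(cp$qualifier_ui, function(q) {
      any(qual_uis %in% q)
    })
  }
  cp[hit, , drop = FALSE]
}

word_term_fields <- function(word_fields) {
  fields <- character(0)
  if ("title" %in% word_fields) fields <- c(fields, "title", "tt")
  if ("abstract" %in% word_fields) fields <- c(fields, "abstract")
  fields
}

#' Score one citation against a query
#'
#' Each conjunctive term contributes the credit of the best channel through
#' which it matches the citation: title word or major-topic concept (full
#' credit), minor-topic concept, abstract-only word; concept credit is
#' multiplied by the automatic-origin discount when applicable. The score is
#' `100 * sum(credits) / n_terms`, so a query perfectly matched in the title
#' and as human-assigned major topics scores 100.
#'
#' @param query A `structured_query`.
#' @param pmid PMID of a citation in the index (assumed to satisfy the
#'   query's boolean condition).
#' @param index A `subset_index`.
#' @param credits A [credit_table()].
#' @param explode Expand descriptor terms over the hierarchy.
#' @param word_fields Fields residual words may match (`"title"`,
#'   `"abstract"`).
#' @return A score in `[0, 100]`.
#' @export
score_citation <- function(query, pmid, index, credits = credit_table(),
                           explode = TRUE,
                           word_fields = c("title", "abstract")) {
  n_terms <- n_query_terms(query)
  if (n_terms == 0L) return(0)
  title_fields <- c("title", "tt")
  total <- 0
  for (i in seq_len(nrow(query$concept_terms))) {
    term <- query$concept_terms[i, ]
    credit <- 0
    # title channel: every token of the matched form present in the title
    toks <- strsplit(term$text, " ", fixed = TRUE)[[1]]
    if (length(toks) > 0L &&
        pmid %in% pmids_with_all_tokens(index, toks, title_fields)) {
      credit <- credits$title
    }
    cp <- term_concept_postings(index, term, explode)
    cp <- cp[cp$pmid == pmid, , drop = FALSE]
    if (nrow(cp) > 0L) {
      ann_credit <- max(
        ifelse(cp$major, credits$major, credits$minor) *
          ifelse(cp$origin == "automatic", credits$automatic, 1)
      )
      credit <- max(credit, ann_credit)
    }
    total <- total + credit
  }
  wf <- word_term_fields(word_fields)
  for (w in query$word_terms) {
    credit <- 0
    if (pmid %in% pmids_with_token(index, w, title_fields)) {
      credit <- credits$title
    } else if (pmid %in% pmids_with_token(index, w, "abstract") &&
               "abstract" %in% wf) {
      credit <- credits$abstract
    }
    total <- total + credit
  }
  100 * total / n_terms
}

#' Ranked retrieval over a subset index
#'
#' Three strategies:
#' * `semantic` — concept terms match the concept postings (metaterms
#'   expanded, descriptors exploded over the hierarchy when `explode` is on)
#'   *or* their label tokens in the title; residual words match the
#'   configured `word_fields`; everything conjoined.
#' * `title_only` — every normalized query token must appear in the
#'   vernacular (transliterated) title; no concept mapping.
#' * `all_fields` — case-folded tokens (no diacritic folding, no elision
#'   splitting) matched across all fields plus English concept labels,
#'   emulating an engine without language-aware normalization.
#'
#' Two rankings: `relevance` sorts by [score_citation()] score, then year
#' (most recent first, unknown year last), then PMID descending; `lifo`
#' sorts by year then PMID descending only. Both return the same boolean
#' match set — `total_hits` (the coverage number) is ranking-invariant.
#'
#' @param index A `subset_index`.
#' @param query A `structured_query`, or query text (interpreted in the
#'   index language for the `semantic` strategy, tokenized for the others).
#' @param strategy One of `"semantic"`, `"title_only"`, `"all_fields"`.
#' @param ranking `"relevance"` or `"lifo"`.
#' @param k Number of hits kept in the ranked list (coverage still counts
#'   all matches).
#' @param explode Hierarchy-expand descriptor terms (default `TRUE`).
#' @param word_fields Fields residual word terms may match.
#' @param credits A [credit_table()].
#' @return An object of class `search_result`: a ranked `hits` tibble
#'   (`rank`, `pmid`, `score`, `year`) truncated at `k`, with `total_hits`,
#'   the strategy and ranking used, and the full match set for facet
#'   refinement.
#' @export
search_citations <- function(index, query,
                             strategy = c("semantic", "title_only", "all_fields"),
                             ranking = c("relevance", "lifo"), k = 20,
                             explode = TRUE,
                             word_fields = c("title", "abstract"),
                             credits = credit_table()) {
  stopifnot(inherits(index, "subset_index"), k >= 1)
  strategy <- match.arg(strategy)
  ranking <- match.arg(ranking)
  query_text <- if (is.character(query)) query else query$text

  if (strategy == "semantic") {
    if (is.character(query)) {
      query <- interpret_query(query, index$lang, index$store)
    }
    sets <- list()
    title_fields <- c("title", "tt")
    for (i in seq_len(nrow(query$concept_terms))) {
      term <- query$concept_terms[i, ]
      by_concept <- unique(term_concept_postings(index, term, explode)$pmid)
      toks <- strsplit(term$text, " ", fixed = TRUE)[[1]]
      by_title <- pmids_with_all_tokens(index, toks, title_fields)
      sets[[length(sets) + 1L]] <- union(by_concept, by_title)
    }
    wf <- word_term_fields(word_fields)
    for (w in query$word_terms) {
      sets[[length(sets) + 1L]] <- pmids_with_token(index, w, wf)
    }
    if (length(sets) == 0L) {
      matches <- character(0)
    } else {
      matches <- Reduce(intersect, sets)
    }
    scores <- purrr::map_dbl(matches, function(p) {
      score_citation(query, p, index, credits, explode, word_fields)
    })
  } else if (strategy == "title_only") {
    toks <- normalize_text(query_text, index$lang)
    matches <- pmids_with_all_tokens(index, toks, "tt")
    scores <- rep(100, length(matches))
  } else { # all_fields
    toks <- casefold_tokens(query_text)
    sets <- purrr::map(toks, function(t) {
      unique(index$raw_postings$pmid[index$raw_postings$token == t])
    })
    matches <- if (length(sets) == 0L) character(0) else Reduce(intersect, sets)
    scores <- rep(100, length(matches))
  }

  years <- index$facets$year[match(matches, index$facets$pmid)]
  all_matches <- tibble::tibble(pmid = matches, score = scores, year = years)
  # unknown year sorts last within its score stratum
  yr <- ifelse(is.na(all_matches$year), -Inf, all_matches$year)
  ord <- if (ranking == "relevance") {
    order(-all_matches$score, -yr, -as.numeric(all_matches$pmid))
  } else {
    order(-yr, -as.numeric(all_matches$pmid))
  }
  all_matches <- all_matches[ord, , drop = FALSE]

  hits <- utils::head(all_matches, k)
  hits <- dplyr::mutate(hits, rank = dplyr::row_number(), .before = 1L)
  structure(
    list(hits = hits, total_hits = nrow(all_matches),
         strategy = strategy, ranking = ranking, k = k,
         query_text = query_text, all_matches = all_matches),
    class = "search_result"
  )
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result> \"", x$query_text, "\" (", x$strategy, ", ",
      x$ranking, "): ", x$total_hits, " hits\n", sep = "")
  print(x$hits, ...)
  invisible(x)
}

#' Refine a search result by a facet value
#'
#' Keeps the hits whose metadata matches a facet value; the hit order is
#' preserved and `total_hits` is recomputed over the full match set, so
#' refinement reports the refined coverage, not just the survivors of the
#' visible page. Refinements commute.
#'
#' @param result A `search_result`.
#' @param index The `subset_index` the result came from.
#' @param facet One of `"year"`, `"country"`, `"publication_type"`,
#'   `"journal"`.
#' @param value Facet value to keep (year may be numeric).
#' @return A `search_result`.
#' @export
refine_facet <- function(result, index, facet, value) {
  stopifnot(inherits(result, "search_result"), inherits(index, "subset_index"))
  facet <- match.arg(facet, c("year", "country", "publication_type", "journal"))
  f <- index$facets
  keep_pmids <- switch(
    facet,
    year = f$pmid[!is.na(f$year) & f$year == as.integer(value)],
    country = f$pmid[!is.na(f$country) & f$country == value],
    journal = f$pmid[!is.na(f$journal) & f$journal == value],
    publication_type = f$pmid[purrr::map_lgl(f$pub_types, function(pt) {
      value %in% pt
    })]
  )
  out <- result
  out$all_matches <- result$all_matches[result$all_matches$pmid %in% keep_pmids, ,
                                        drop = FALSE]
  out$hits <- result$hits[result$hits$pmid %in% keep_pmids, , drop = FALSE]
  out$total_hits <- nrow(out$all_matches)
  out
}

#' Facet value counts for a search result
#'
#' Summarizes the full match set of a result along one facet, the counts a
#' faceted interface would display next to each refinement value.
#'
#' @inheritParams refine_facet
#' @return A tibble with columns `value` and `n`, most frequent first.
#' @export
facet_counts <- function(result, index, facet) {
  facet <- match.arg(facet, c("year", "country", "publication_type", "journal"))
  f <- index$facets[match(result$all_matches$pmid, index$facets$pmid), ]
  values <- switch(
    facet,
    year = as.character(f$year),
    country = f$country,
    journal = f$journal,
    publication_type = unlist(f$pub_types)
  )
  values <- values[!is.na(values)]
  tibble::as_tibble(table(value = values)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$value)
}
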