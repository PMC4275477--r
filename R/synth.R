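#' Deterministic pseudo-word generator
#'
#' Builds pronounceable nonsense words from a consonant/vowel syllable
#' inventory. Synthetic terminologies and synthetic corpora use disjoint
#' consonant inventories, so a corpus word can never collide with a concept
#' label — which makes token-count and planted-relevance oracles exact.
#'
#' @param n Number of distinct words.
#' @param consonants,vowels Syllable inventory.
#' @param syllables Range of syllables per word.
#' @return Character vector of `n` unique words.
#' @keywords internal
pseudo_words <- function(n, consonants, vowels, syllables = 2:3) {
  out <- character(0)
  while (length(out) < n) {
    k <- sample(syllables, 1)
    w <- paste0(
      paste0(sample(consonants, k, replace = TRUE),
             sample(vowels, k, replace = TRUE)),
      collapse = ""
    )
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

term_words <- function(n) pseudo_words(n, strsplit("bcdfgmprs", "")[[1]], c("a", "e", "i", "o", "u"))
corpus_words <- function(n) pseudo_words(n, strsplit("klvwxz", "")[[1]], c("a", "e", "i", "o", "u"))

# decorate an ascii word into a French-looking accented form whose
# normalization recovers the original; always introduces at least one
# diacritic (or ligature) so French labels exercise normalization
frenchify <- function(word) {
  w <- word
  if (grepl("oe", w)) {
    w <- sub("oe", "œ", w)
  } else if (grepl("e", w)) {
    w <- sub("e", sample(c("é", "è"), 1), w)
  } else if (grepl("i", w)) {
    w <- sub("i", "ï", w)
  } else if (grepl("o", w)) {
    w <- sub("o", "ô", w)
  } else if (grepl("a", w)) {
    w <- sub("a", "â", w)
  } else {
    w <- sub("u", "û", w)
  }
  w
}

#' Generate a synthetic mini terminology
#'
#' Writes a small, fully valid multilingual terminology (see
#' [read_terminology()] for the file schemas): a descriptor forest with
#' well-formed dotted tree numbers, per-language preferred labels and
#' synonyms (the French forms carry diacritics so normalization is
#' exercised), acronyms including one deliberately ambiguous acronym shared
#' by two descriptors, qualifiers, metaterms linking several descriptors,
#' bilingual predefined queries, supplementary concepts (one untranslated,
#' English-only), and a couple of see-also relations. Output bytes are a
#' deterministic function of `seed`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_descriptors,n_qualifiers,n_metaterms Sizes (>= 1; at least 4
#'   descriptors are needed for the metaterm/acronym structure).
#' @param synonyms_per_descriptor Synonyms per descriptor per language.
#' @param n_supplementary,n_predefined Sizes of the optional tables.
#' @param languages Language codes to label (first is the "native" one).
#' @return `dir`, invisibly.
#' @export
generate_mini_mesh <- function(dir, seed = 1L, n_descriptors = 12L,
                               n_qualifiers = 3L, n_metaterms = 2L,
                               synonyms_per_descriptor = 2L,
                               n_supplementary = 2L, n_predefined = 2L,
                               languages = c("fre", "eng")) {
  stopifnot(n_descriptors >= 4L, n_qualifiers >= 1L, n_metaterms >= 1L,
            synonyms_per_descriptor >= 1L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(seed, {
    d_ui <- sprintf("D%03d", seq_len(n_descriptors))
    q_ui <- sprintf("Q%03d", seq_len(n_qualifiers))
    s_ui <- sprintf("S%03d", seq_len(n_supplementary))
    m_ui <- sprintf("MT%02d", seq_len(n_metaterms))
    p_ui <- sprintf("PQ%02d", seq_len(n_predefined))

    # forest of tree numbers: up to 3 roots, children attach to any placed node
    n_roots <- min(3L, n_descriptors)
    tree <- character(n_descriptors)
    tree[seq_len(n_roots)] <- sprintf("C%02d", seq_len(n_roots))
    child_count <- integer(n_descriptors)
    for (i in seq(n_roots + 1L, length.out = max(0L, n_descriptors - n_roots))) {
      parent <- sample(i - 1L, 1)
      child_count[parent] <- child_count[parent] + 1L
      tree[i] <- paste0(tree[parent], ".", child_count[parent])
    }

    n_units <- n_descriptors * (1L + synonyms_per_descriptor) +
      n_qualifiers * 2L + n_metaterms + n_predefined + n_supplementary * 2L
    pool <- term_words((length(languages) + 1L) * n_units)
    take <- local({
      i <- 0L
      function(k) {
        i <<- i + k
        pool[(i - k + 1L):i]
      }
    })

    labels <- list()
    add_label <- function(ui, lang, kind, text, ambiguous = FALSE) {
      labels[[length(labels) + 1L]] <<- tibble::tibble(
        ui = ui, lang = lang, kind = kind, text = text,
        ambiguous = as.integer(ambiguous)
      )
    }
    # every language gets its own base words, so a label in one language
    # never equals (or normalizes to) a label in another — the translation
    # gap the all_fields strategy is meant to expose
    label_concept <- function(ui, n_syn = 0L) {
      first_base <- NULL
      for (lang in languages) {
        base <- take(1L + n_syn)
        if (is.null(first_base)) first_base <- base[[1]]
        decorate <- if (lang == "fre") frenchify else identity
        add_label(ui, lang, "preferred", decorate(base[[1]]))
        for (s in seq_len(n_syn)) {
          add_label(ui, lang, "synonym", decorate(base[[1L + s]]))
        }
      }
      first_base
    }

    d_base <- vapply(d_ui, label_concept, character(1),
                     n_syn = synonyms_per_descriptor)
    for (ui in q_ui) label_concept(ui, n_syn = 1L)
    for (ui in m_ui) label_concept(ui)
    for (ui in p_ui) label_concept(ui)
    # supplementary: first gets all languages, the rest English only
    for (j in seq_len(n_supplementary)) {
      langs <- if (j == 1L) languages else "eng"
      for (lang in langs) {
        base <- take(2L)
        decorate <- if (lang == "fre") frenchify else identity
        add_label(s_ui[[j]], lang, "preferred", decorate(base[[1]]))
        add_label(s_ui[[j]], lang, "synonym", decorate(base[[2]]))
      }
    }

    # unambiguous acronyms for the first two descriptors, one ambiguous
    # acronym shared by descriptors 3 and 4
    for (lang in languages) {
      add_label(d_ui[[1]], lang, "acronym", toupper(substr(d_base[[1]], 1, 3)))
      add_label(d_ui[[2]], lang, "acronym", toupper(substr(d_base[[2]], 1, 3)))
      add_label(d_ui[[3]], lang, "acronym", "ZZA", ambiguous = TRUE)
      add_label(d_ui[[4]], lang, "acronym", "ZZA", ambiguous = TRUE)
    }

    descriptors <- tibble::tibble(
      ui = d_ui, tree_numbers = tree,
      see_also = c(d_ui[[2]], d_ui[[1]], rep("", n_descriptors - 2L))
    )
    qualifiers <- tibble::tibble(ui = q_ui)
    supplementary <- tibble::tibble(
      ui = s_ui,
      mapped_descriptors = d_ui[1L + (seq_len(n_supplementary) %% n_descriptors)]
    )
    metaterms <- tibble::tibble(
      ui = m_ui,
      linked = vapply(seq_len(n_metaterms), function(j) {
        linked <- d_ui[(2L * j - 1L):min(2L * j, n_descriptors)]
        if (j == 1L) linked <- c(linked, q_ui[[1]])
        paste(linked, collapse = ";")
      }, character(1))
    )
    predefined <- tibble::tibble(
      ui = p_ui,
      expression = vapply(seq_len(n_predefined), function(j) {
        paste0(d_ui[[(j %% n_descriptors) + 1L]], "/", q_ui[[1]])
      }, character(1))
    )
    labels <- dplyr::bind_rows(labels)

    readr::write_tsv(descriptors, file.path(dir, "descriptors.tsv"))
    readr::write_tsv(qualifiers, file.path(dir, "qualifiers.tsv"))
    readr::write_tsv(supplementary, file.path(dir, "supplementary.tsv"))
    readr::write_tsv(metaterms, file.path(dir, "metaterms.tsv"))
    readr::write_tsv(predefined, file.path(dir, "predefined.tsv"))
    readr::write_tsv(labels, file.path(dir, "labels.tsv"))
  })
  invisible(dir)
}

#' Specification of a synthetic citation corpus
#'
#' Collects the knobs of [generate_corpus()]: corpus size, language mix, the
#' planted-relevance design (how many records are constructed relevant to
#' each query, and what share of them carry the evidence in the vernacular
#' title versus only as an indexed synonym), the share of partially relevant
#' records among the planted ones, the share of automatically assigned
#' annotations, and the publication-year range.
#'
#' @param seed Integer seed.
#' @param n_citations Corpus size.
#' @param lang Subset language of interest.
#' @param other_lang_frac Fraction of citations in other languages.
#' @param mislabeled_frac Fraction tagged `lang` but lacking a vernacular
#'   title (emulating mislabeled records).
#' @param n_queries Number of planted queries.
#' @param planted_per_query Relevant records planted per query.
#' @param title_evidence_frac Share of planted records whose vernacular
#'   title contains the query concept's label (the rest are reachable only
#'   through their MeSH annotation / synonyms).
#' @param partial_frac Share of planted records judged only partially
#'   relevant.
#' @param automatic_frac Share of citations whose annotations are
#'   automatically assigned.
#' @param year_range Two-element integer vector.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(seed = 1L, n_citations = 150L, lang = "fre",
                        other_lang_frac = 0.10, mislabeled_frac = 0.04,
                        n_queries = 3L, planted_per_query = 10L,
                        title_evidence_frac = 0.5, partial_frac = 0.2,
                        automatic_frac = 0.3, year_range = c(1995L, 2014L)) {
  spec <- list(seed = seed, n_citations = n_citations, lang = lang,
               other_lang_frac = other_lang_frac,
               mislabeled_frac = mislabeled_frac, n_queries = n_queries,
               planted_per_query = planted_per_query,
               title_evidence_frac = title_evidence_frac,
               partial_frac = partial_frac, automatic_frac = automatic_frac,
               year_range = as.integer(year_range))
  fracs <- c(other_lang_frac, mislabeled_frac, title_evidence_frac,
             partial_frac, automatic_frac)
  stopifnot(all(fracs >= 0 & fracs <= 1), n_citations >= 1L,
            length(year_range) == 2L)
  if (n_queries * planted_per_query > n_citations) {
    stop("infeasible corpus spec: planted records exceed corpus size",
         call. = FALSE)
  }
  structure(spec, class = "corpus_spec")
}

#' Generate a synthetic citation corpus with planted relevance
#'
#' Emits a `PubmedArticleSet` XML file parseable by [parse_citations()],
#' together with a relevance key. For each planted query (a leaf descriptor
#' of the terminology, queried by its native-language preferred label)
#' exactly `planted_per_query` records are constructed relevant: all carry
#' the concept as a MeSH annotation, a `title_evidence_frac` share also
#' carries the label verbatim in the vernacular title, and the rest are
#' reachable only through the annotation. All other text is drawn from a
#' pseudo-word vocabulary disjoint from every concept label, so the planted
#' sets are exactly the retrievable sets. Deterministic per seed.
#'
#' @param spec A [corpus_spec()].
#' @param store A `terminology` object (typically from
#'   [generate_mini_mesh()] + [read_terminology()]).
#' @param dir Output directory; `citations.xml`, `key.tsv` and
#'   `queries.tsv` are written there.
#' @return Invisibly, a list with `xml` (path), `key` (tibble: `query`,
#'   `concept_ui`, `pmid`, `level`, `evidence`) and `queries` (tibble:
#'   `query`, `concept_ui`).
#' @export
generate_corpus <- function(spec, store, dir) {
  stopifnot(inherits(spec, "corpus_spec"), inherits(store, "terminology"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lang <- spec$lang

  # planted queries: leaf descriptors, so hierarchy explosion cannot drag in
  # records planted for other queries
  leaves <- store$descriptors$ui[
    vapply(store$descriptors$ui, function(u) {
      length(mesh_explode(store, u)) == 1L
    }, logical(1))
  ]
  if (length(leaves) < spec$n_queries) {
    stop("terminology has too few leaf descriptors for ", spec$n_queries,
         " planted queries", call. = FALSE)
  }

  out <- withr::with_seed(spec$seed, {
    query_uis <- sample(leaves, spec$n_queries)
    query_labels <- vapply(query_uis, function(u) {
      preferred_label(store, u, lang)
    }, character(1))
    synonyms <- lapply(query_uis, function(u) {
      syn <- store$labels |>
        dplyr::filter(.data$ui == !!u, .data$lang == !!lang,
                      .data$kind == "synonym")
      if (nrow(syn) == 0L) preferred_label(store, u, lang) else syn$text
    })
    distractor_pool <- setdiff(store$descriptors$ui, query_uis)

    vocab <- corpus_words(120L)
    n <- spec$n_citations
    pmids <- as.character(100000L + seq_len(n))
    n_planted <- spec$n_queries * spec$planted_per_query
    planted_idx <- seq_len(n_planted)
    planted_query <- rep(seq_len(spec$n_queries), each = spec$planted_per_query)
    n_title <- round(spec$planted_per_query * spec$title_evidence_frac)

    rest <- setdiff(seq_len(n), planted_idx)
    n_other <- round(spec$other_lang_frac * n)
    n_mislab <- round(spec$mislabeled_frac * n)
    other_idx <- utils::head(rest, n_other)
    mislab_idx <- utils::head(setdiff(rest, other_idx), n_mislab)

    journals <- tibble::tibble(
      title = c("Revue synthetique de medecine", "Synthetic Medical Journal",
                "Zeitschrift fur synthetische Medizin"),
      country = c("France", "England", "Germany")
    )
    pub_type_pool <- c("Journal Article", "Review", "Letter")

    key_rows <- list()
    records <- vector("list", n)
    for (i in seq_len(n)) {
      planted <- i <= n_planted
      qj <- if (planted) planted_query[[i]] else NA_integer_
      within_query <- if (planted) (i - 1L) %% spec$planted_per_query + 1L else NA_integer_
      title_evidence <- planted && within_query <= n_title
      langs <- if (i %in% other_idx) {
        sample(c("eng", "ger", "spa"), 1)
      } else {
        lang
      }
      mislabeled <- i %in% mislab_idx
      year <- sample(seq(spec$year_range[[1]], spec$year_range[[2]]), 1)
      automatic <- stats::runif(1) < spec$automatic_frac
      jr <- journals[sample(nrow(journals), 1), ]

      vt_words <- sample(vocab, 5)
      if (title_evidence) {
        pos <- sample(5, 1)
        vt_words <- append(vt_words, query_labels[[qj]], after = pos)
      }
      vernacular <- paste(vt_words, collapse = " ")
      title <- paste0("[", paste(sample(vocab, 5), collapse = " "), "].")
      ab_words <- sample(vocab, 15)
      if (planted && !title_evidence) {
        ab_words <- append(ab_words, sample(synonyms[[qj]], 1),
                           after = sample(15, 1))
      }
      abstract <- paste(ab_words, collapse = " ")

      ann_uis <- sample(distractor_pool, sample(1:2, 1))
      major_flags <- stats::runif(length(ann_uis)) < 0.3
      if (planted) {
        ann_uis <- c(query_uis[[qj]], ann_uis)
        major_flags <- c(stats::runif(1) < 0.8, major_flags)
      }

      records[[i]] <- list(
        pmid = pmids[[i]], languages = langs,
        vernacular = if (langs[[1]] != "eng" && !mislabeled) vernacular,
        title = title, abstract = abstract, year = year,
        journal = jr$title, country = jr$country,
        pub_types = sample(pub_type_pool, sample(1:2, 1)),
        automatic = automatic,
        annotations = tibble::tibble(ui = ann_uis, major = major_flags)
      )
      if (planted) {
        key_rows[[length(key_rows) + 1L]] <- tibble::tibble(
          query = query_labels[[qj]], concept_ui = query_uis[[qj]],
          pmid = pmids[[i]],
          level = if (stats::runif(1) < spec$partial_frac) {
            "partially_relevant"
          } else {
            "relevant"
          },
          evidence = if (title_evidence) "title" else "synonym"
        )
      }
    }

    doc <- xml2::xml_new_root("PubmedArticleSet")
    for (rec in records) {
      art <- xml2::xml_add_child(doc, "PubmedArticle")
      cit <- xml2::xml_add_child(art, "MedlineCitation")
      if (rec$automatic) xml2::xml_set_attr(cit, "IndexingMethod", "Automated")
      xml2::xml_add_child(cit, "PMID", rec$pmid)
      a <- xml2::xml_add_child(cit, "Article")
      j <- xml2::xml_add_child(a, "Journal")
      xml2::xml_add_child(j, "Title", rec$journal)
      ji <- xml2::xml_add_child(j, "JournalIssue")
      pd <- xml2::xml_add_child(ji, "PubDate")
      xml2::xml_add_child(pd, "Year", as.character(rec$year))
      xml2::xml_add_child(a, "ArticleTitle", rec$title)
      ab <- xml2::xml_add_child(a, "Abstract")
      xml2::xml_add_child(ab, "AbstractText", rec$abstract)
      for (l in rec$languages) xml2::xml_add_child(a, "Language", l)
      ptl <- xml2::xml_add_child(a, "PublicationTypeList")
      for (pt in rec$pub_types) xml2::xml_add_child(ptl, "PublicationType", pt)
      if (!is.null(rec$vernacular)) {
        xml2::xml_add_child(a, "VernacularTitle", rec$vernacular)
      }
      mji <- xml2::xml_add_child(cit, "MedlineJournalInfo")
      xml2::xml_add_child(mji, "Country", rec$country)
      mhl <- xml2::xml_add_child(cit, "MeshHeadingList")
      for (k in seq_len(nrow(rec$annotations))) {
        mh <- xml2::xml_add_child(mhl, "MeshHeading")
        dn <- xml2::xml_add_child(mh, "DescriptorName",
                                  rec$annotations$ui[[k]])
        xml2::xml_set_attr(dn, "UI", rec$annotations$ui[[k]])
        xml2::xml_set_attr(dn, "MajorTopicYN",
                           if (rec$annotations$major[[k]]) "Y" else "N")
      }
    }
    xml_path <- file.path(dir, "citations.xml")
    xml2::write_xml(doc, xml_path)

    key <- dplyr::bind_rows(key_rows)
    queries <- tibble::tibble(query = query_labels, concept_ui = query_uis)
    readr::write_tsv(key, file.path(dir, "key.tsv"))
    readr::write_tsv(queries, file.path(dir, "queries.tsv"))
    list(xml = xml_path, key = key, queries = queries)
  })
  invisible(out)
}
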