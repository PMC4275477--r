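#' Load a multilingual terminology from tab-separated tables
#'
#' The terminology directory holds a MeSH-style vocabulary as plain UTF-8 TSV
#' tables, hand-writable and diffable:
#'
#' * `descriptors.tsv` — `ui`, `tree_numbers` (semicolon-separated dotted
#'   positions, at least one), `see_also` (semicolon-separated descriptor
#'   uis, may be empty).
#' * `qualifiers.tsv` — `ui`.
#' * `supplementary.tsv` — `ui`, `mapped_descriptors` (semicolon-separated
#'   descriptor uis). Optional file.
#' * `metaterms.tsv` — `ui`, `linked` (semicolon-separated descriptor and/or
#'   qualifier uis, non-empty).
#' * `predefined.tsv` — `ui`, `expression`: a conjunction of
#'   `descriptor[/qualifier]` terms joined by `" AND "`
#'   (e.g. `D012964/Q000097`). Optional file.
#' * `labels.tsv` — `ui`, `lang`, `kind` (`preferred`, `synonym`, `acronym`),
#'   `text`, `ambiguous` (0/1, meaningful for acronyms). Labels attach to any
#'   concept kind, including metaterms and predefined queries.
#' * `scope_notes.tsv` — `ui`, `lang`, `text`. Optional file.
#'
#' Every referenced ui (tree relations aside) must resolve; dangling
#' references abort the load with a message listing the offenders. A
#' normalized-label lookup table is built over every label, synonym and
#' acronym via [normalize_text()], so lookup inherits its invariance under
#' case, diacritics, ligatures and elision.
#'
#' @param dir Directory containing the tables.
#' @return An object of class `terminology`: a list of tibbles
#'   (`descriptors`, `qualifiers`, `supplementary`, `metaterms`,
#'   `predefined`, `labels`, `scope_notes`, `lookup`) plus the declared
#'   `languages`.
#' @export
read_terminology <- function(dir) {
  if (!dir.exists(dir)) stop("terminology directory not found: ", dir, call. = FALSE)
  tsv <- function(name, cols, required = TRUE) {
    path <- file.path(dir, name)
    if (!file.exists(path)) {
      if (required) stop("missing terminology table: ", name, call. = FALSE)
      return(tibble::as_tibble(stats::setNames(
        purrr::map(cols, ~character(0)), cols)))
    }
    out <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    missing <- setdiff(cols, names(out))
    if (length(missing) > 0L) {
      stop(name, " lacks column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    out
  }
  split_semi <- function(x) {
    purrr::map(x, function(v) {
      if (is.na(v) || !nzchar(v)) character(0) else strsplit(v, ";", fixed = TRUE)[[1]]
    })
  }

  descriptors <- tsv("descriptors.tsv", c("ui", "tree_numbers", "see_also")) |>
    dplyr::mutate(
      tree_numbers = split_semi(.data$tree_numbers),
      see_also = split_semi(.data$see_also)
    )
  qualifiers <- tsv("qualifiers.tsv", "ui")
  supplementary <- tsv("supplementary.tsv", c("ui", "mapped_descriptors"),
                       required = FALSE) |>
    dplyr::mutate(mapped_descriptors = split_semi(.data$mapped_descriptors))
  metaterms <- tsv("metaterms.tsv", c("ui", "linked")) |>
    dplyr::mutate(linked = split_semi(.data$linked))
  predefined <- tsv("predefined.tsv", c("ui", "expression"), required = FALSE)
  labels <- tsv("labels.tsv", c("ui", "lang", "kind", "text", "ambiguous")) |>
    dplyr::mutate(ambiguous = .data$ambiguous %in% c("1", "TRUE", "true"))
  scope_notes <- tsv("scope_notes.tsv", c("ui", "lang", "text"), required = FALSE)

  validate_terminology(descriptors, qualifiers, supplementary, metaterms,
                       predefined, labels)

  kind_of <- c(
    stats::setNames(rep("descriptor", nrow(descriptors)), descriptors$ui),
    stats::setNames(rep("qualifier", nrow(qualifiers)), qualifiers$ui),
    stats::setNames(rep("supplementary", nrow(supplementary)), supplementary$ui),
    stats::setNames(rep("metaterm", nrow(metaterms)), metaterms$ui),
    stats::setNames(rep("predefined", nrow(predefined)), predefined$ui)
  )
  lookup <- labels |>
    dplyr::mutate(
      norm = purrr::map2_chr(.data$text, .data$lang, normalize_key),
      concept_kind = unname(kind_of[.data$ui])
    ) |>
    dplyr::distinct(.data$norm, .data$lang, .data$ui, .keep_all = TRUE) |>
    dplyr::select("norm", "lang", "ui", "concept_kind", source = "kind",
                  "text", "ambiguous")

  structure(
    list(
      descriptors = descriptors, qualifiers = qualifiers,
      supplementary = supplementary, metaterms = metaterms,
      predefined = predefined, labels = labels, scope_notes = scope_notes,
      lookup = lookup, languages = sort(unique(labels$lang))
    ),
    class = "terminology"
  )
}

validate_terminology <- function(descriptors, qualifiers, supplementary,
                                 metaterms, predefined, labels) {
  problems <- character(0)
  if (anyDuplicated(descriptors$ui)) problems <- c(problems, "duplicate descriptor ui")
  if (anyDuplicated(qualifiers$ui)) problems <- c(problems, "duplicate qualifier ui")
  no_tree <- lengths(descriptors$tree_numbers) == 0L
  if (any(no_tree)) {
    problems <- c(problems, paste0("descriptor without tree number: ",
                                   paste(descriptors$ui[no_tree], collapse = ", ")))
  }
  known <- c(descriptors$ui, qualifiers$ui, supplementary$ui,
             metaterms$ui, predefined$ui)
  dangle <- function(uis, where) {
    bad <- setdiff(uis, known)
    if (length(bad) > 0L) {
      paste0("dangling ui in ", where, ": ", paste(bad, collapse = ", "))
    }
  }
  problems <- c(
    problems,
    dangle(unlist(metaterms$linked), "metaterms"),
    dangle(unlist(supplementary$mapped_descriptors), "supplementary"),
    dangle(unlist(descriptors$see_also), "see_also"),
    dangle(labels$ui, "labels"),
    dangle(unlist(purrr::map(predefined$expression, expression_uis)),
           "predefined expressions")
  )
  empty_mt <- lengths(metaterms$linked) == 0L
  if (any(empty_mt)) {
    problems <- c(problems, paste0("metaterm without links: ",
                                   paste(metaterms$ui[empty_mt], collapse = ", ")))
  }
  if (length(problems) > 0L) {
    stop("invalid terminology:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(TRUE)
}

expression_uis <- function(expression) {
  terms <- strsplit(expression, " AND ", fixed = TRUE)[[1]]
  unlist(strsplit(terms, "/", fixed = TRUE))
}

#' @export
print.terminology <- function(x, ...) {
  cat("<terminology> ", nrow(x$descriptors), " descriptors, ",
      nrow(x$qualifiers), " qualifiers, ", nrow(x$supplementary),
      " supplementary concepts, ", nrow(x$metaterms), " metaterms, ",
      nrow(x$predefined), " predefined queries; languages: ",
      paste(x$languages, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Match a text fragment against the terminology
#'
#' Exact lookup of the normalized fragment over preferred labels, synonyms
#' and acronyms in one language. Ambiguous acronyms return every candidate
#' sense, each flagged `ambiguous`.
#'
#' @param store A `terminology` object.
#' @param text The fragment to match.
#' @param lang Three-letter language code; must be declared in the store.
#' @return A tibble with columns `ui`, `kind`, `source`, `matched`,
#'   `ambiguous` (zero rows when nothing matches).
#' @export
match_label <- function(store, text, lang) {
  stopifnot(inherits(store, "terminology"))
  if (!lang %in% store$languages) {
    stop("language not declared in terminology: ", lang, call. = FALSE)
  }
  key <- normalize_key(text, lang)
  store$lookup |>
    dplyr::filter(.data$lang == !!lang, .data$norm == !!key) |>
    dplyr::transmute(
      ui = .data$ui, kind = .data$concept_kind, source = .data$source,
      matched = .data$text, ambiguous = .data$ambiguous
    )
}

#' Expand a descriptor to its hierarchy descendants
#'
#' Returns the descriptor itself plus every descriptor having any tree
#' number that extends any of its tree numbers (dotted-prefix rule), i.e. the
#' standard MeSH "explode" used before retrieval.
#'
#' @param store A `terminology` object.
#' @param ui Descriptor ui.
#' @return Character vector of descriptor uis (always includes `ui`).
#' @export
mesh_explode <- function(store, ui) {
  stopifnot(inherits(store, "terminology"))
  i <- match(ui, store$descriptors$ui)
  if (is.na(i)) stop("unknown descriptor: ", ui, call. = FALSE)
  roots <- store$descriptors$tree_numbers[[i]]
  hit <- purrr::map_lgl(store$descriptors$tree_numbers, function(tns) {
    any(purrr::map_lgl(roots, function(r) {
      any(tns == r | startsWith(tns, paste0(r, ".")))
    }))
  })
  store$descriptors$ui[hit]
}

#' Expand a metaterm to its linked concepts
#'
#' Resolves a metaterm (specialty-level superconcept) by its normalized label
#' in one language and returns exactly the linked descriptor/qualifier uis.
#' Hierarchy explosion, when wanted, happens at retrieval time.
#'
#' @param store A `terminology` object.
#' @param name Metaterm label in `lang`.
#' @param lang Three-letter language code.
#' @return Character vector of linked concept uis.
#' @export
expand_metaterm <- function(store, name, lang) {
  m <- match_label(store, name, lang) |>
    dplyr::filter(.data$kind == "metaterm")
  if (nrow(m) == 0L) stop("unknown metaterm: ", name, call. = FALSE)
  i <- match(m$ui[[1]], store$metaterms$ui)
  store$metaterms$linked[[i]]
}

#' Preferred label of a concept in one language
#'
#' @param store A `terminology` object.
#' @param ui Concept ui.
#' @param lang Three-letter language code.
#' @param fallback Language tried when no label exists in `lang`
#'   (supplementary concepts are often untranslated); `NULL` to disable.
#' @return The label text, or `NA` when absent in both languages.
#' @export
preferred_label <- function(store, ui, lang, fallback = "eng") {
  lab <- store$labels |>
    dplyr::filter(.data$ui == !!ui, .data$lang == !!lang,
                  .data$kind == "preferred")
  if (nrow(lab) > 0L) return(lab$text[[1]])
  if (!is.null(fallback) && !identical(fallback, lang)) {
    return(preferred_label(store, ui, fallback, fallback = NULL))
  }
  NA_character_
}

#' Resolve a predefined query label
#'
#' Curated mappings from lay or clinical labels (e.g. "natremia") to boolean
#' descriptor\[/qualifier\] expressions (e.g. sodium/blood). Matching is by
#' normalized label in the requested language; the stored expression is
#' language-independent.
#'
#' @param store A `terminology` object.
#' @param text Candidate label.
#' @param lang Three-letter language code.
#' @return A [structured_query] whose concept terms carry
#'   `source = "predefined"`, or `NULL` when the label is not a predefined
#'   query.
#' @export
resolve_predefined_query <- function(store, text, lang) {
  m <- match_label(store, text, lang) |>
    dplyr::filter(.data$kind == "predefined")
  if (nrow(m) == 0L) return(NULL)
  i <- match(m$ui[[1]], store$predefined$ui)
  expr <- store$predefined$expression[[i]]
  terms <- strsplit(expr, " AND ", fixed = TRUE)[[1]]
  parts <- strsplit(terms, "/", fixed = TRUE)
  uis <- purrr::map_chr(parts, 1)
  concept_terms <- tibble::tibble(
    ui = uis,
    qualifier_ui = purrr::map_chr(parts, function(p) {
      if (length(p) > 1L) p[[2]] else NA_character_
    }),
    kind = "descriptor",
    source = "predefined",
    # the title-match channel sees the descriptor's label in this language
    text = purrr::map_chr(uis, function(u) {
      lab <- preferred_label(store, u, lang)
      if (is.na(lab)) u else normalize_key(lab, lang)
    })
  )
  structured_query(
    text = text, lang = lang, concept_terms = concept_terms,
    word_terms = character(0)
  )
}
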