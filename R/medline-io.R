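#' Parse MEDLINE/PubMed citation XML into a citation tibble
#'
#' Reads the `PubmedArticleSet` dialect and returns one row per citation with
#' the fields the search engine and facet tables need. Nested metadata is kept
#' in list-columns: `languages` and `pub_types` hold character vectors,
#' `annotations` holds one tibble of MeSH headings per citation with columns
#' `descriptor_ui`, `major`, `origin` and list-columns `qualifier_ui`,
#' `qualifier_major`.
#'
#' The heading origin is taken from the citation-level `IndexingMethod`
#' attribute on `MedlineCitation` (`"Automated"` or `"Curated"` map to
#' `"automatic"`, anything else or absent to `"human"`) and applied to all of
#' that citation's headings.
#'
#' Citations without a PMID are skipped with a warning. A missing publication
#' year is kept as `NA` (such records sort last under date ordering rather
#' than being dropped).
#'
#' @param xml_source Path to an XML file, or a literal XML string.
#' @return A tibble with columns `pmid`, `title`, `transliterated_title`,
#'   `abstract`, `languages` (list), `journal_title`, `journal_country`,
#'   `pub_year`, `pub_types` (list), `doi`, `annotations` (list).
#' @examples
#' xml <- paste0(
#'   "<PubmedArticleSet><PubmedArticle><MedlineCitation>",
#'   "<PMID>1</PMID><Article>",
#'   "<ArticleTitle>[A title].</ArticleTitle>",
#'   "<Language>fre</Language></Article>",
#'   "<MedlineJournalInfo><Country>France</Country></MedlineJournalInfo>",
#'   "</MedlineCitation></PubmedArticle></PubmedArticleSet>")
#' parse_citations(xml)
#' @export
parse_citations <- function(xml_source) {
  doc <- tryCatch(
    xml2::read_xml(xml_source),
    error = function(e) stop("malformed XML: ", conditionMessage(e), call. = FALSE)
  )
  arts <- xml2::xml_find_all(doc, ".//MedlineCitation")
  rows <- purrr::map(arts, parse_one_citation)
  skipped <- sum(purrr::map_lgl(rows, is.null))
  if (skipped > 0L) {
    warning(skipped, " citation(s) without a PMID skipped", call. = FALSE)
  }
  rows <- purrr::compact(rows)
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(empty_citations())
  if (anyDuplicated(out$pmid)) {
    warning("duplicate PMIDs present in input", call. = FALSE)
  }
  out
}

empty_citations <- function() {
  tibble::tibble(
    pmid = character(), title = character(),
    transliterated_title = character(), abstract = character(),
    languages = list(), journal_title = character(),
    journal_country = character(), pub_year = integer(),
    pub_types = list(), doi = character(), annotations = list()
  )
}

xml_text1 <- function(node, xpath) {
  n <- xml2::xml_find_first(node, xpath)
  if (inherits(n, "xml_missing")) NA_character_ else xml2::xml_text(n)
}

parse_one_citation <- function(cit) {
  pmid <- xml_text1(cit, "./PMID")
  if (is.na(pmid) || !nzchar(pmid)) return(NULL)
  origin <- xml2::xml_attr(cit, "IndexingMethod")
  origin <- if (!is.na(origin) && origin %in% c("Automated", "Curated")) {
    "automatic"
  } else {
    "human"
  }
  langs <- xml2::xml_text(xml2::xml_find_all(cit, "./Article/Language"))
  year <- xml_text1(cit, "./Article/Journal/JournalIssue/PubDate/Year")
  if (is.na(year)) year <- xml_text1(cit, "./Article/Journal/JournalIssue/PubDate/MedlineDate")
  year <- suppressWarnings(as.integer(stringr::str_extract(year, "\\d{4}")))
  abstract <- xml2::xml_find_all(cit, "./Article/Abstract/AbstractText")
  abstract <- if (length(abstract) == 0L) {
    NA_character_
  } else {
    paste(xml2::xml_text(abstract), collapse = " ")
  }
  doi <- xml_text1(
    xml2::xml_parent(cit),
    ".//PubmedData/ArticleIdList/ArticleId[@IdType='doi']"
  )
  headings <- xml2::xml_find_all(cit, "./MeshHeadingList/MeshHeading")
  ann <- dplyr::bind_rows(purrr::map(headings, function(h) {
    d <- xml2::xml_find_first(h, "./DescriptorName")
    quals <- xml2::xml_find_all(h, "./QualifierName")
    tibble::tibble(
      descriptor_ui = xml2::xml_attr(d, "UI"),
      major = identical(xml2::xml_attr(d, "MajorTopicYN"), "Y"),
      origin = origin,
      qualifier_ui = list(xml2::xml_attr(quals, "UI")),
      qualifier_major = list(xml2::xml_attr(quals, "MajorTopicYN") == "Y")
    )
  }))
  if (nrow(ann) == 0L) ann <- empty_annotations()
  tibble::tibble(
    pmid = pmid,
    title = xml_text1(cit, "./Article/ArticleTitle"),
    transliterated_title = xml_text1(cit, "./Article/VernacularTitle"),
    abstract = abstract,
    languages = list(langs),
    journal_title = xml_text1(cit, "./Article/Journal/Title"),
    journal_country = xml_text1(cit, "./MedlineJournalInfo/Country"),
    pub_year = year,
    pub_types = list(xml2::xml_text(xml2::xml_find_all(
      cit, "./Article/PublicationTypeList/PublicationType"))),
    doi = doi,
    annotations = list(ann)
  )
}

empty_annotations <- function() {
  tibble::tibble(
    descriptor_ui = character(), major = logical(), origin = character(),
    qualifier_ui = list(), qualifier_major = list()
  )
}

#' Extract a monolingual subset
#'
#' Keeps citations whose `languages` include `lang`. A citation tagged with
#' several languages belongs to every listed language's subset. With
#' `plausibility = TRUE` a record must additionally carry a non-empty
#' vernacular (transliterated) title — a proxy for genuinely non-English text
#' that screens out citations mislabeled with the target language. The
#' plausibility screen is off by default.
#'
#' @param citations Citation tibble from [parse_citations()].
#' @param lang Three-letter language code (e.g. `"fre"`).
#' @param plausibility Apply the vernacular-title screen? Default `FALSE`.
#' @return The filtered citation tibble, input order preserved.
#' @export
filter_language <- function(citations, lang, plausibility = FALSE) {
  stopifnot(is.character(lang), length(lang) == 1L, nzchar(lang))
  keep <- purrr::map_lgl(citations$languages, function(l) lang %in% l)
  if (plausibility) {
    keep <- keep & !is.na(citations$transliterated_title) &
      nzchar(citations$transliterated_title)
  }
  citations[keep, , drop = FALSE]
}

subset_format_version <- 1L

#' Persist / reload a citation subset
#'
#' The subset is stored as line-delimited JSON (one citation per line,
#' preceded by a one-line header carrying the format version), which keeps it
#' streamable and diffable. `read_subset(write_subset(x))` reproduces `x`
#' field for field, including absent optional fields.
#'
#' @param citations Citation tibble.
#' @param path File path.
#' @return `write_subset` returns `path` invisibly; `read_subset` returns the
#'   citation tibble.
#' @export
write_subset <- function(citations, path) {
  header <- jsonlite::toJSON(
    list(format = "medlingua-subset", version = subset_format_version),
    auto_unbox = TRUE
  )
  lines <- purrr::map_chr(seq_len(nrow(citations)), function(i) {
    row <- citations[i, ]
    ann <- row$annotations[[1]]
    rec <- list(
      pmid = row$pmid, title = row$title,
      transliterated_title = row$transliterated_title,
      abstract = row$abstract, languages = row$languages[[1]],
      journal_title = row$journal_title,
      journal_country = row$journal_country, pub_year = row$pub_year,
      pub_types = row$pub_types[[1]], doi = row$doi,
      annotations = purrr::map(seq_len(nrow(ann)), function(j) {
        list(
          descriptor_ui = ann$descriptor_ui[j], major = ann$major[j],
          origin = ann$origin[j],
          qualifier_ui = as.list(ann$qualifier_ui[[j]]),
          qualifier_major = as.list(ann$qualifier_major[[j]])
        )
      })
    )
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", na = "null")
  })
  readr::write_lines(c(header, lines), path)
  invisible(path)
}

#' @rdname write_subset
#' @export
read_subset <- function(path) {
  if (!file.exists(path)) stop("subset file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path, progress = FALSE)
  if (length(lines) == 0L) stop("empty subset file: ", path, call. = FALSE)
  header <- jsonlite::fromJSON(lines[[1]])
  if (!identical(header$format, "medlingua-subset") ||
      !identical(as.integer(header$version), subset_format_version)) {
    stop("unrecognized subset format/version in ", path, call. = FALSE)
  }
  body <- lines[-1]
  if (length(body) == 0L) return(empty_citations())
  rows <- purrr::map(body, function(line) {
    rec <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    chr1 <- function(v) if (is.null(v)) NA_character_ else as.character(v)
    ann <- dplyr::bind_rows(purrr::map(rec$annotations, function(a) {
      tibble::tibble(
        descriptor_ui = a$descriptor_ui, major = isTRUE(a$major),
        origin = a$origin,
        qualifier_ui = list(as.character(unlist(a$qualifier_ui))),
        qualifier_major = list(as.logical(unlist(a$qualifier_major)))
      )
    }))
    if (nrow(ann) == 0L) ann <- empty_annotations()
    tibble::tibble(
      pmid = rec$pmid, title = chr1(rec$title),
      transliterated_title = chr1(rec$transliterated_title),
      abstract = chr1(rec$abstract),
      languages = list(as.character(unlist(rec$languages))),
      journal_title = chr1(rec$journal_title),
      journal_country = chr1(rec$journal_country),
      pub_year = if (is.null(rec$pub_year)) NA_integer_ else as.integer(rec$pub_year),
      pub_types = list(as.character(unlist(rec$pub_types))),
      doi = chr1(rec$doi),
      annotations = list(ann)
    )
  })
  dplyr::bind_rows(rows)
}
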