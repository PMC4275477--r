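#' Packaged benchmark tables from the published French-subset evaluation
#'
#' The package ships, as plain TSV, the per-query data of a published
#' evaluation of five strategies for retrieving French-language PubMed
#' citations (a semantic engine over the French subset, a MeSH-translation
#' gateway, plain PubMed under LIFO and relevance ranking, and PubMed
#' restricted to the transliterated-title field), over 20 frequent clinical
#' queries:
#'
#' * `response_times` — query (English and French forms), server response
#'   time in seconds, and the number of citations retrieved by the semantic
#'   engine;
#' * `coverage` — per-query total citation counts for the four strategies
#'   whose coverage was recorded;
#' * `precision` — per-query precision cells: strict and relaxed precision
#'   over the first 20 citations plus the number actually retrieved (some
#'   queries returned fewer than 20, one returned none). Published
#'   precisions are printed to 2 decimals; relevant counts are recovered as
#'   `round(precision * retrieved)` and the recovery is verified to
#'   round-trip back to the printed value at load time.
#'
#' Loading validates the data against stored checksums (the published column
#' totals) and the structural invariants (strict <= relaxed, retrieved <=
#' 20) and aborts on any mismatch.
#'
#' @return A list of three tibbles: `response_times`, `coverage`, and
#'   `precision` (cells with columns `query`, `strategy`, `retrieved`,
#'   `relevant_strict`, `relevant_relaxed`, `strict`, `relaxed`).
#' @export
benchmark_tables <- function() {
  dir <- system.file("extdata", "benchmark", package = "medlingua")
  rt <- readr::read_tsv(file.path(dir, "response_times.tsv"),
                        col_types = "ccdi", progress = FALSE)
  cov <- readr::read_tsv(file.path(dir, "coverage.tsv"),
                         col_types = "ciiii", progress = FALSE)
  prec <- readr::read_tsv(file.path(dir, "precision.tsv"),
                          col_types = "ccddi", progress = FALSE)

  ok <- nrow(rt) == 20L && nrow(cov) == 20L && nrow(prec) == 100L &&
    identical(colSums(cov[, -1]),
              c(babelmesh = 50894, multilingual_french = 42384,
                pubmed = 34047, pubmed_tt = 10716)) &&
    isTRUE(all.equal(sum(rt$seconds), 12.97)) &&
    sum(prec$retrieved) == 400L + 400L + 257L + 257L + 380L
  if (!ok) stop("packaged benchmark tables failed their checksum", call. = FALSE)

  prec <- prec |>
    dplyr::mutate(
      relevant_strict = as.integer(round(.data$strict * .data$retrieved)),
      relevant_relaxed = as.integer(round(.data$relaxed * .data$retrieved)),
      relevant_strict = ifelse(.data$retrieved == 0L, 0L, .data$relevant_strict),
      relevant_relaxed = ifelse(.data$retrieved == 0L, 0L, .data$relevant_relaxed)
    )
  recon_ok <- with(prec, retrieved == 0L | (
    round(relevant_strict / retrieved, 2) == strict &
      round(relevant_relaxed / retrieved, 2) == relaxed &
      relevant_strict <= relevant_relaxed & retrieved <= 20L
  ))
  if (!all(recon_ok)) {
    stop("relevant-count reconstruction does not round-trip for: ",
         paste(prec$query[!recon_ok], collapse = ", "), call. = FALSE)
  }
  list(response_times = rt, coverage = cov, precision = prec)
}
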