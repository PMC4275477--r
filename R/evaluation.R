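#' Precision at k under strict or relaxed judging
#'
#' Relevance is judged on a 3-level scale (`relevant`,
#' `partially_relevant`, `not_relevant`). Strict precision counts only fully
#' relevant citations as true positives; relaxed precision also counts
#' partially relevant ones. The denominator is the number of citations
#' actually retrieved (at most the inspected cutoff), so a query returning
#' fewer than `k` hits is scored over what it returned.
#'
#' @param pmids Ranked retrieved PMIDs (the inspected prefix, length <= k).
#' @param judgments Tibble with columns `pmid` and `level`; every retrieved
#'   PMID must be judged.
#' @param mode `"strict"` or `"relaxed"`.
#' @return A one-row tibble: `retrieved`, `relevant`, `precision`
#'   (`NA` when nothing was retrieved).
#' @export
precision_at_k <- function(pmids, judgments, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  stopifnot(all(c("pmid", "level") %in% names(judgments)))
  bad <- !judgments$level %in% c("relevant", "partially_relevant", "not_relevant")
  if (any(bad)) {
    stop("unknown judgment level(s): ",
         paste(unique(judgments$level[bad]), collapse = ", "), call. = FALSE)
  }
  unjudged <- setdiff(pmids, judgments$pmid)
  if (length(unjudged) > 0L) {
    stop("retrieved PMIDs without a judgment: ",
         paste(unjudged, collapse = ", "), call. = FALSE)
  }
  levels <- judgments$level[match(pmids, judgments$pmid)]
  positive <- if (mode == "strict") "relevant" else c("relevant", "partially_relevant")
  retrieved <- length(pmids)
  relevant <- sum(levels %in% positive)
  tibble::tibble(
    retrieved = retrieved, relevant = relevant,
    precision = if (retrieved == 0L) NA_real_ else relevant / retrieved
  )
}

#' Per-query precision cells for a set of runs
#'
#' Builds one precision cell per (query, strategy) from ranked run data and
#' judgments: the retrieved count and both strict and relaxed relevant
#' counts, the unit of all pooled statistics.
#'
#' @param runs Tibble with columns `query`, `strategy`, `rank`, `pmid` (at
#'   most the first 20 ranks of each run are used).
#' @param judgments Tibble with columns `query`, `pmid`, `level`.
#' @return A tibble with columns `query`, `strategy`, `retrieved`,
#'   `relevant_strict`, `relevant_relaxed`.
#' @export
precision_cells <- function(runs, judgments) {
  stopifnot(all(c("query", "strategy", "rank", "pmid") %in% names(runs)))
  runs |>
    dplyr::group_by(.data$query, .data$strategy) |>
    dplyr::group_modify(function(df, key) {
      top <- df$pmid[order(df$rank)][seq_len(min(nrow(df), 20L))]
      j <- judgments[judgments$query == key$query, c("pmid", "level")]
      strict <- precision_at_k(top, j, "strict")
      relaxed <- precision_at_k(top, j, "relaxed")
      tibble::tibble(
        retrieved = strict$retrieved,
        relevant_strict = strict$relevant,
        relevant_relaxed = relaxed$relevant
      )
    }) |>
    dplyr::ungroup()
}

#' Pooled (micro-averaged) precision over queries
#'
#' The pooled precision of a strategy is the micro-average
#' `sum(relevant) / sum(retrieved)` over its per-query cells; queries that
#' retrieved nothing contribute to neither sum. With equal retrieved counts
#' everywhere, this equals the arithmetic mean of per-query precisions.
#'
#' @param cells Precision-cell tibble (columns `retrieved`,
#'   `relevant_strict`, `relevant_relaxed`), typically one strategy's rows.
#' @param mode `"strict"` or `"relaxed"`.
#' @return The pooled precision as a fraction in `[0, 1]` (unrounded).
#' @export
pooled_precision <- function(cells, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  rel <- if (mode == "strict") cells$relevant_strict else cells$relevant_relaxed
  total_retrieved <- sum(cells$retrieved)
  if (total_retrieved == 0L) {
    stop("pooled precision undefined: no citations retrieved", call. = FALSE)
  }
  sum(rel) / total_retrieved
}

#' Total coverage over queries
#'
#' Coverage of one query is the total number of citations a strategy
#' retrieves (not just the inspected prefix); the strategy's total coverage
#' is the exact sum over queries.
#'
#' @param totals Non-negative integer vector of per-query totals.
#' @return Integer sum.
#' @export
coverage_total <- function(totals) {
  stopifnot(is.numeric(totals), all(!is.na(totals)), all(totals >= 0))
  as.integer(round(sum(totals)))
}

#' Sensitivity re-analysis of pooled precision
#'
#' Recomputes pooled precision under one of three bias scenarios for a
#' problem query (e.g. one a search engine silently rewrote): drop the query
#' entirely; treat it as having retrieved nothing for the named strategies;
#' or assume everything it retrieved was fully relevant.
#'
#' @param cells Precision-cell tibble with a `query` and `strategy` column.
#' @param scenario `"exclude_query"`, `"zero_results"` or
#'   `"assume_relevant"`.
#' @param query Query label the scenario applies to.
#' @param strategies Strategies the scenario applies to (default: all).
#' @param mode `"strict"` or `"relaxed"`.
#' @return A tibble with columns `strategy` and `pooled_precision`.
#' @export
sensitivity_reanalysis <- function(cells,
                                   scenario = c("exclude_query", "zero_results",
                                                "assume_relevant"),
                                   query, strategies = NULL,
                                   mode = c("strict", "relaxed")) {
  scenario <- match.arg(scenario)
  mode <- match.arg(mode)
  if (!query %in% cells$query) stop("unknown query: ", query, call. = FALSE)
  affected <- cells$query == query &
    (is.null(strategies) | cells$strategy %in% (strategies %||% cells$strategy))
  adjusted <- cells
  if (scenario == "exclude_query") {
    adjusted <- adjusted[!affected, , drop = FALSE]
  } else if (scenario == "zero_results") {
    adjusted$retrieved[affected] <- 0L
    adjusted$relevant_strict[affected] <- 0L
    adjusted$relevant_relaxed[affected] <- 0L
  } else {
    adjusted$relevant_strict[affected] <- adjusted$retrieved[affected]
    adjusted$relevant_relaxed[affected] <- adjusted$retrieved[affected]
  }
  adjusted |>
    dplyr::group_by(.data$strategy) |>
    dplyr::summarise(pooled_precision = pooled_precision(
      dplyr::pick(dplyr::everything()), mode)) |>
    dplyr::ungroup()
}

#' Read run and judgment files
#'
#' Run files are tab-separated with columns `query`, `strategy`, `rank`,
#' `pmid` and optionally `total` (the query's full coverage). Judgment files
#' are tab-separated with columns `query`, `pmid`, `level` on the 3-level
#' scale.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_runs <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    query = "c", strategy = "c", rank = "i", pmid = "c", .default = "i"
  ), progress = FALSE)
  need <- c("query", "strategy", "rank", "pmid")
  if (!all(need %in% names(out))) {
    stop("run file lacks columns: ",
         paste(setdiff(need, names(out)), collapse = ", "), call. = FALSE)
  }
  out
}

#' @rdname read_runs
#' @export
read_judgments <- function(path) {
  out <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  if (!all(c("query", "pmid", "level") %in% names(out))) {
    stop("judgment file lacks query/pmid/level columns", call. = FALSE)
  }
  out
}

#' Write a precision / coverage report
#'
#' Emits delimited-text matrices shaped like the published evaluation
#' reports: a coverage matrix (query x strategy totals) and a precision
#' matrix (query x strategy, "strict-relaxed" cells), plus the pooled total
#' row.
#'
#' @param cells Precision cells (with `query` and `strategy`).
#' @param totals Optional tibble `query`, `strategy`, `total` of coverage.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(cells, totals = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prec <- cells |>
    dplyr::mutate(cell = ifelse(
      .data$retrieved == 0L, "-",
      sprintf("%.2f-%.2f", .data$relevant_strict / .data$retrieved,
              .data$relevant_relaxed / .data$retrieved))) |>
    dplyr::select("query", "strategy", "cell") |>
    tidyr::pivot_wider(names_from = "strategy", values_from = "cell")
  pooled <- cells |>
    dplyr::group_by(.data$strategy) |>
    dplyr::summarise(cell = sprintf(
      "%.2f-%.2f",
      pooled_precision(dplyr::pick(dplyr::everything()), "strict"),
      pooled_precision(dplyr::pick(dplyr::everything()), "relaxed"))) |>
    tidyr::pivot_wider(names_from = "strategy", values_from = "cell") |>
    dplyr::mutate(query = "Total", .before = 1L)
  readr::write_tsv(dplyr::bind_rows(prec, pooled),
                   file.path(dir, "precision.tsv"))
  if (!is.null(totals)) {
    cov <- totals |>
      tidyr::pivot_wider(names_from = "strategy", values_from = "total")
    pooled_cov <- totals |>
      dplyr::group_by(.data$strategy) |>
      dplyr::summarise(total = coverage_total(.data$total)) |>
      tidyr::pivot_wider(names_from = "strategy", values_from = "total") |>
      dplyr::mutate(query = "Total", .before = 1L)
    readr::write_tsv(dplyr::bind_rows(cov, pooled_cov),
                     file.path(dir, "coverage.tsv"))
  }
  invisible(dir)
}
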