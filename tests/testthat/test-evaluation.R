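make_judgments <- function(n_rel, n_part, n_not) {
  n <- n_rel + n_part + n_not
  tibble::tibble(
    pmid = as.character(seq_len(n)),
    level = c(rep("relevant", n_rel), rep("partially_relevant", n_part),
              rep("not_relevant", n_not))
  )
}

test_that("precision counts strict and relaxed true positives", {
  j <- make_judgments(13, 5, 2)
  pmids <- j$pmid
  expect_equal(precision_at_k(pmids, j, "strict")$precision, 0.65)
  expect_equal(precision_at_k(pmids, j, "relaxed")$precision, 0.90)
  j_all <- make_judgments(20, 0, 0)
  expect_equal(precision_at_k(j_all$pmid, j_all, "strict")$precision, 1)
  expect_equal(precision_at_k(j_all$pmid, j_all, "relaxed")$precision, 1)
  # fewer than 20 retrieved: denominator is what was retrieved
  expect_equal(precision_at_k(j$pmid[1:4], j, "strict")$precision, 1)
  expect_true(is.na(precision_at_k(character(0), j, "strict")$precision))
})

test_that("unjudged or malformed judgments are rejected by name", {
  j <- make_judgments(2, 1, 1)
  expect_error(precision_at_k(c("1", "99"), j), "99")
  j$level[[1]] <- "sort_of_relevant"
  expect_error(precision_at_k("1", j, "strict"), "sort_of_relevant")
})

test_that("relaxed precision never falls below strict precision", {
  withr::with_seed(21, {
    for (i in 1:30) {
      n <- sample(1:20, 1)
      j <- tibble::tibble(
        pmid = as.character(seq_len(n)),
        level = sample(c("relevant", "partially_relevant", "not_relevant"),
                       n, replace = TRUE)
      )
      expect_gte(precision_at_k(j$pmid, j, "relaxed")$precision,
                 precision_at_k(j$pmid, j, "strict")$precision)
    }
  })
})

test_that("pooled precision is the micro-average and equals the macro
           average on balanced cells", {
  cells <- tibble::tibble(
    retrieved = c(20L, 20L, 20L),
    relevant_strict = c(10L, 20L, 15L),
    relevant_relaxed = c(12L, 20L, 18L)
  )
  expect_equal(pooled_precision(cells, "strict"), 45 / 60)
  expect_equal(pooled_precision(cells, "strict"),
               mean(cells$relevant_strict / cells$retrieved))
  # single cell
  expect_equal(pooled_precision(cells[3, ], "strict"), 0.75)
  # unbalanced: micro differs from macro, zero-retrieved queries drop out
  cells2 <- tibble::tibble(retrieved = c(20L, 2L, 0L),
                           relevant_strict = c(10L, 2L, 0L),
                           relevant_relaxed = c(10L, 2L, 0L))
  expect_equal(pooled_precision(cells2, "strict"), 12 / 22)
  expect_error(pooled_precision(cells2[3, ], "strict"), "undefined")
})

test_that("coverage totals are exact sums", {
  expect_equal(coverage_total(c(1, 2, 3)), 6L)
  expect_equal(coverage_total(rep(0, 20)), 0L)
  tabs <- benchmark_tables()
  expect_equal(coverage_total(tabs$coverage$multilingual_french), 42384L)
})

test_that("sensitivity scenarios adjust the pooled bookkeeping as stated", {
  cells <- benchmark_tables()$precision
  base <- pooled_precision(cells[cells$strategy == "multilingual_french", ],
                           "strict")
  # dropping the one imperfect translated query can only help
  excl <- sensitivity_reanalysis(cells, "exclude_query", "Pharyngitis")
  expect_gte(excl$pooled_precision[excl$strategy == "multilingual_french"],
             base)
  # assuming relevance for an already-perfect query changes nothing
  assume <- sensitivity_reanalysis(cells, "assume_relevant", "Constipation")
  expect_equal(
    assume$pooled_precision[assume$strategy == "multilingual_french"], base)
  # zeroing a query's results removes exactly its retrieved count
  zeroed <- cells
  z <- sensitivity_reanalysis(zeroed, "zero_results", "Hypertension",
                              strategies = "pubmed_lifo")
  lifo <- cells[cells$strategy == "pubmed_lifo", ]
  drop_n <- lifo$retrieved[lifo$query == "Hypertension"]
  expect_equal(
    z$pooled_precision[z$strategy == "pubmed_lifo"],
    sum(lifo$relevant_strict[lifo$query != "Hypertension"]) /
      (sum(lifo$retrieved) - drop_n)
  )
  expect_error(sensitivity_reanalysis(cells, "exclude_query", "Quinsy"),
               "unknown query")
})

test_that("all three bias scenarios keep the published strategy ordering", {
  cells <- benchmark_tables()$precision
  for (scenario in c("exclude_query", "zero_results", "assume_relevant")) {
    res <- sensitivity_reanalysis(
      cells, scenario, "Pharyngitis",
      strategies = if (scenario == "exclude_query") NULL else
        c("pubmed_lifo", "pubmed_relevance"))
    top <- res$pooled_precision[res$strategy %in%
                                  c("multilingual_french", "pubmed_tt")]
    rest <- res$pooled_precision[res$strategy %in%
                                   c("pubmed_lifo", "pubmed_relevance")]
    expect_true(min(top) > max(rest), info = scenario)
  }
})

test_that("precision cells assemble from run and judgment tables", {
  runs <- tibble::tibble(
    query = rep("q1", 6), strategy = rep(c("a", "b"), each = 3),
    rank = rep(1:3, 2), pmid = as.character(c(1, 2, 3, 1, 4, 5))
  )
  judgments <- tibble::tibble(
    query = "q1", pmid = as.character(1:5),
    level = c("relevant", "partially_relevant", "not_relevant",
              "relevant", "relevant")
  )
  cells <- precision_cells(runs, judgments)
  expect_equal(nrow(cells), 2L)
  a <- cells[cells$strategy == "a", ]
  expect_equal(a$retrieved, 3L)
  expect_equal(a$relevant_strict, 1L)
  expect_equal(a$relevant_relaxed, 2L)
  b <- cells[cells$strategy == "b", ]
  expect_equal(b$relevant_strict, 3L)
})

test_that("run/judgment files round-trip through their readers", {
  runs <- tibble::tibble(query = "q", strategy = "s", rank = 1:2,
                         pmid = c("10", "11"), total = 5L)
  jf <- withr::local_tempfile(fileext = ".tsv")
  rf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(runs, rf)
  expect_equal(read_runs(rf), runs)
  judgments <- tibble::tibble(query = "q", pmid = c("10", "11"),
                              level = c("relevant", "not_relevant"))
  readr::write_tsv(judgments, jf)
  expect_equal(read_judgments(jf), judgments)
  suppressWarnings(expect_error(read_runs(jf), "lacks"))
})

test_that("report writer emits the precision and coverage matrices", {
  cells <- benchmark_tables()$precision
  totals <- benchmark_tables()$coverage |>
    tidyr::pivot_longer(-"query", names_to = "strategy", values_to = "total")
  dir <- withr::local_tempdir()
  write_report(cells, totals, dir)
  prec <- readr::read_tsv(file.path(dir, "precision.tsv"),
                          show_col_types = FALSE)
  expect_equal(nrow(prec), 21L)   # 20 queries + pooled total row
  expect_equal(prec$multilingual_french[prec$query == "Total"], "0.93-0.95")
  cov <- readr::read_tsv(file.path(dir, "coverage.tsv"),
                         show_col_types = FALSE)
  expect_equal(cov$pubmed_tt[cov$query == "Total"], 10716L)
})
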