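# a tiny hand-built corpus with fully controlled annotations for scoring
scoring_citations <- function() {
  ann <- function(ui, major, origin = "human") {
    tibble::tibble(descriptor_ui = ui, major = major, origin = origin,
                   qualifier_ui = list(character(0)),
                   qualifier_major = list(logical(0)))
  }
  tibble::tibble(
    pmid = c("11", "12", "13", "14"),
    title = c("[A].", "[B].", "[C].", "[D]."),
    transliterated_title = c(
      "La sarcoïdose pulmonaire",      # title match for "sarcoïdose"
      "Une étude clinique",            # concept only (major)
      "Un autre sujet",                # concept only (minor)
      "Encore un sujet"                # abstract word only
    ),
    abstract = c(NA, NA, NA, "La sarcoïdose est discutée."),
    languages = list("fre", "fre", "fre", "fre"),
    journal_title = "Revue", journal_country = "France",
    pub_year = c(2013L, 2010L, 2013L, 2011L),
    pub_types = list("Journal Article", "Journal Article",
                     "Review", "Journal Article"),
    doi = NA_character_,
    annotations = list(
      ann("D001", TRUE),
      ann("D001", TRUE),
      ann("D001", FALSE),
      ann("D004", TRUE)
    )
  )
}

test_that("index postings agree with a brute-force token scan", {
  w <- toy_world()
  idx <- w$index
  tt <- idx$norm_postings[idx$norm_postings$field == "tt", ]
  # oracle: linear scan over all records
  for (tok in sample(unique(tt$token), 12)) {
    expected <- w$subset$pmid[vapply(w$subset$transliterated_title, function(t) {
      !is.na(t) && tok %in% normalize_text(t, "fre")
    }, logical(1))]
    expect_setequal(tt$pmid[tt$token == tok], expected)
  }
  # concept postings cover every annotation
  expect_equal(nrow(idx$concept_postings),
               sum(vapply(w$subset$annotations, nrow, integer(1))))
})

test_that("an empty corpus yields an index with zero hits for anything", {
  store <- toy_terminology()
  recs <- parse_citations(toy_citations_xml())[0, ]
  idx <- build_index(recs, store, "fre")
  r <- search_citations(idx, "sarcoïdose")
  expect_equal(r$total_hits, 0L)
  expect_equal(nrow(r$hits), 0L)
})

test_that("unknown annotation concepts error under strict validation", {
  store <- toy_terminology()
  recs <- parse_citations(toy_citations_xml())
  recs$annotations[[1]]$descriptor_ui <- "D876"
  expect_error(build_index(recs, store, "fre", strict = TRUE), "D876")
  expect_message(idx <- build_index(recs, store, "fre"), "D876")
  expect_false("D876" %in% idx$concept_postings$descriptor_ui)
})

test_that("scores follow the credit table", {
  store <- toy_terminology()
  idx <- build_index(scoring_citations(), store, "fre")
  q <- interpret_query("sarcoïdose", "fre", store)
  # title word + human major topic: the perfect match anchor
  expect_equal(score_citation(q, "11", idx), 100)
  # major topic only, human origin
  expect_equal(score_citation(q, "12", idx), 100)
  # minor topic only: 0.7 credit
  expect_equal(score_citation(q, "13", idx), 70)
  # two-term query: one title word (1.0) + one abstract-only word (0.5)
  q2 <- interpret_query("sujet discutée", "fre", store)
  expect_equal(length(q2$word_terms), 2L)
  expect_equal(score_citation(q2, "14", idx), 75)
})

test_that("automatic-origin annotations are discounted", {
  store <- toy_terminology()
  cits <- scoring_citations()
  cits$annotations[[2]]$origin <- "automatic"
  idx <- build_index(cits, store, "fre")
  q <- interpret_query("sarcoïdose", "fre", store)
  expect_equal(score_citation(q, "12", idx), 80)   # 1.0 * 0.8
  # but a title match overrides the discounted concept credit
  cits$annotations[[1]]$origin <- "automatic"
  idx2 <- build_index(cits, store, "fre")
  expect_equal(score_citation(q, "11", idx2), 100)
})

test_that("equal scores break ties by publication date, then pmid", {
  store <- toy_terminology()
  idx <- build_index(scoring_citations(), store, "fre")
  r <- search_citations(idx, "sarcoïdose", ranking = "relevance")
  # 11 (2013) and 12 (2010) both score 100: most recent first
  expect_equal(r$hits$pmid[1:2], c("11", "12"))
  expect_true(all(diff(r$hits$score) <= 0))
})

test_that("lifo ordering equals a (year, pmid) descending sort oracle", {
  w <- toy_world()
  q <- w$corpus$queries$query[[1]]
  r <- search_citations(w$index, q, ranking = "lifo")
  m <- r$all_matches
  oracle <- m$pmid[order(-m$year, -as.numeric(m$pmid))]
  expect_equal(m$pmid, oracle)
})

test_that("relevance and lifo return the same boolean match set", {
  w <- toy_world()
  for (q in w$corpus$queries$query) {
    r1 <- search_citations(w$index, q, ranking = "relevance")
    r2 <- search_citations(w$index, q, ranking = "lifo")
    expect_equal(r1$total_hits, r2$total_hits)
    expect_setequal(r1$all_matches$pmid, r2$all_matches$pmid)
  }
})

test_that("title-only strategy is blind to abstract-only evidence", {
  store <- toy_terminology()
  idx <- build_index(scoring_citations(), store, "fre")
  # "discutée" occurs only in an abstract
  r <- search_citations(idx, "discutée", strategy = "title_only")
  expect_equal(r$total_hits, 0L)
  r2 <- search_citations(idx, "discutée", strategy = "semantic")
  expect_equal(r2$total_hits, 1L)
})

test_that("the all_fields emulation misses accent/elision variants", {
  store <- toy_terminology()
  idx <- build_index(scoring_citations(), store, "fre")
  # accented query matches the accented vernacular title...
  expect_gt(search_citations(idx, "sarcoïdose",
                             strategy = "all_fields")$total_hits, 0L)
  # ...but the unaccented variant finds nothing (no diacritic folding),
  # while the semantic strategy is invariant
  expect_equal(search_citations(idx, "sarcoidose",
                                strategy = "all_fields")$total_hits, 0L)
  expect_gt(search_citations(idx, "sarcoidose",
                             strategy = "semantic")$total_hits, 0L)
})

test_that("hierarchy explosion is applied at query time and is switchable", {
  store <- toy_terminology()
  cits <- scoring_citations()
  cits$annotations[[4]]$descriptor_ui <- "D009"   # child of D008
  idx <- build_index(cits, store, "fre")
  on_ <- search_citations(idx, "infection", explode = TRUE)
  off <- search_citations(idx, "infection", explode = FALSE)
  expect_true("14" %in% on_$all_matches$pmid)
  expect_false("14" %in% off$all_matches$pmid)
})

test_that("conjunction is monotone: adding a term never adds matches", {
  w <- toy_world()
  q1 <- w$corpus$queries$query[[1]]
  r1 <- search_citations(w$index, q1)
  r12 <- search_citations(w$index, paste(q1, "kawa"))
  expect_true(all(r12$all_matches$pmid %in% r1$all_matches$pmid))
})

test_that("facet refinement filters, preserves order, commutes", {
  w <- toy_world()
  q <- w$corpus$queries$query[[1]]
  r <- search_citations(w$index, q, k = 20)
  years <- w$index$facets$year[match(r$all_matches$pmid, w$index$facets$pmid)]
  y <- years[[1]]
  ry <- refine_facet(r, w$index, "year", y)
  expect_true(all(w$index$facets$year[match(ry$all_matches$pmid,
                                            w$index$facets$pmid)] == y))
  expect_equal(ry$hits$pmid,
               r$hits$pmid[r$hits$pmid %in% ry$all_matches$pmid])
  # absent value empties the result
  expect_equal(refine_facet(r, w$index, "year", 1800)$total_hits, 0L)
  # commutativity
  ab <- refine_facet(refine_facet(r, w$index, "year", y),
                     w$index, "country", "France")
  ba <- refine_facet(refine_facet(r, w$index, "country", "France"),
                     w$index, "year", y)
  expect_equal(ab$all_matches, ba$all_matches)
  expect_error(refine_facet(r, w$index, "publisher", "x"))
})

test_that("unknown strategies and rankings are rejected", {
  w <- toy_world()
  expect_error(search_citations(w$index, "kawa", strategy = "fuzzy"))
  expect_error(search_citations(w$index, "kawa", ranking = "random"))
})

test_that("planted relevance is recovered with the expected coverage gap", {
  w <- toy_world()
  for (i in seq_len(nrow(w$corpus$queries))) {
    q <- w$corpus$queries$query[[i]]
    key <- w$corpus$key[w$corpus$key$query == q, ]
    sem <- search_citations(w$index, q, strategy = "semantic")
    tt <- search_citations(w$index, q, strategy = "title_only")
    expect_setequal(sem$all_matches$pmid, key$pmid)
    expect_setequal(tt$all_matches$pmid, key$pmid[key$evidence == "title"])
    expect_gt(sem$total_hits, tt$total_hits)
  }
})

test_that("search results tidy, glance and plot", {
  w <- toy_world()
  r <- search_citations(w$index, w$corpus$queries$query[[1]])
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("rank", "pmid", "score", "year"))
  g <- glance(r)
  expect_equal(g$total_hits, r$total_hits)
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
  fc <- facet_counts(r, w$index, "year")
  expect_equal(sum(fc$n), r$total_hits)
})
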