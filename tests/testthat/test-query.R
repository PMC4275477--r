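test_that("queries interpret to concept terms via labels, synonyms, acronyms", {
  store <- toy_terminology()
  q <- interpret_query("allaitement maternel", "fre", store)
  expect_equal(q$concept_terms$ui, "D003")
  expect_length(q$word_terms, 0L)

  # acronym route
  q_avc <- interpret_query("AVC", "fre", store)
  expect_equal(q_avc$concept_terms$ui, "D002")
  expect_equal(q_avc$concept_terms$source, "acronym")

  # synonym and diacritic-stripped synonym land on the same concept
  forms <- c("allaitement maternel", "allaitement au sein",
             "ALLAITEMENT MATERNEL", "allaitement au sein")
  for (f in forms) {
    qi <- interpret_query(f, "fre", store)
    expect_equal(qi$concept_terms$ui, "D003", info = f)
    expect_equal(nrow(qi$concept_terms), 1L, info = f)
  }

  # unmatched tokens become word terms
  q_w <- interpret_query("xyzzy grommulation", "fre", store)
  expect_equal(nrow(q_w$concept_terms), 0L)
  expect_equal(q_w$word_terms, c("xyzzy", "grommulation"))

  expect_error(interpret_query("", "fre", store), "non-empty")
})

test_that("stop words inside concept spans survive; residual stop words drop", {
  store <- toy_terminology()
  q <- interpret_query("la maladie de Crohn", "fre", store)
  expect_equal(q$concept_terms$ui, "D004")
  expect_length(q$word_terms, 0L)   # "la" is a residual stop word
  # a pure stop-word query still interprets to something
  q_sw <- interpret_query("de la", "fre", store)
  expect_gt(n_query_terms(q_sw), 0L)
})

test_that("every input token is consumed exactly once", {
  store <- toy_terminology()
  queries <- c("sarcoïdose pulmonaire évolutive", "l'angine de Vincent",
               "maladie de crohn et sarcoidose", "AVC massif")
  for (qq in queries) {
    tokens <- normalize_text(qq, "fre")
    q <- interpret_query(qq, "fre", store)
    consumed <- c(unlist(strsplit(q$concept_terms$text, " ")), q$word_terms)
    leftover <- setdiff(tokens, consumed)
    expect_true(all(leftover %in% stop_words("fre")), info = qq)
    expect_true(all(table(consumed) <= table(tokens)[names(table(consumed))]),
                info = qq)
  }
})

test_that("whole-string predefined match wins outright", {
  store <- toy_terminology()
  q <- interpret_query("natrémie", "fre", store)
  expect_equal(q$concept_terms$ui, "D007")
  expect_equal(q$concept_terms$qualifier_ui, "Q001")
  expect_equal(q$concept_terms$source, "predefined")
})

test_that("metaterms win ties over descriptors of the same span length", {
  store <- toy_terminology()
  # "psychiatrie" names both descriptor D005 and metaterm MT01
  q <- interpret_query("psychiatrie", "fre", store)
  expect_equal(q$concept_terms$kind, "metaterm")
  # with reversed priority the descriptor wins
  q2 <- interpret_query("psychiatrie", "fre", store,
                        priority = c("descriptor", "metaterm", "predefined",
                                     "supplementary", "qualifier"))
  expect_equal(q2$concept_terms$kind, "descriptor")
})

test_that("ambiguous acronyms keep the first-listed sense with a message", {
  store <- toy_terminology()
  expect_message(q <- interpret_query("zzv", "fre", store), "ambiguous")
  expect_equal(nrow(q$concept_terms), 1L)
})

test_that("greedy segmentation agrees with exhaustive best segmentation", {
  store <- toy_terminology()
  lookup <- store$lookup[store$lookup$lang == "fre", ]
  # oracle: enumerate all segmentations, keep those maximizing matched
  # tokens, then minimizing segment count
  all_segmentations <- function(tokens) {
    if (length(tokens) == 0L) return(list(list()))
    out <- list()
    for (len in seq_along(tokens)) {
      head_seg <- paste(tokens[seq_len(len)], collapse = " ")
      for (tail in all_segmentations(tokens[-seq_len(len)])) {
        out[[length(out) + 1L]] <- c(list(head_seg), tail)
      }
    }
    out
  }
  oracle_concepts <- function(text) {
    tokens <- normalize_text(text, "fre")
    segs <- all_segmentations(tokens)
    score <- vapply(segs, function(s) {
      spans <- unlist(s)
      matched <- spans %in% lookup$norm
      sum(lengths(strsplit(spans[matched], " ")))
    }, numeric(1))
    nseg <- lengths(segs)
    best <- segs[[order(-score, nseg)[1]]]
    spans <- unlist(best)
    sort(unique(lookup$ui[match(spans[spans %in% lookup$norm], lookup$norm)]))
  }
  for (qq in c("allaitement maternel", "sarcoïdose allaitement maternel",
               "maladie de crohn", "sodium sanguin",
               "accident vasculaire cérébral grave")) {
    q <- interpret_query(qq, "fre", store)
    expect_equal(sort(unique(q$concept_terms$ui)), oracle_concepts(qq),
                 info = qq)
  }
})
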