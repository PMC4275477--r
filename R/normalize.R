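#' Normalize free text into query tokens
#'
#' Normalization is the backbone of concept matching: a query only reaches the
#' terminology lookup tables through this function, and the lookup tables
#' themselves are keyed on its output, so matching is invariant under case,
#' accentuation, ligatures and (for French) elision.
#'
#' Steps, in order: Unicode NFC composition; case folding; typographic
#' apostrophes mapped to `'`; for French, elided articles before an apostrophe
#' (`l'`, `d'`, `j'`, `n'`, `s'`, `t'`, `qu'`) removed with the apostrophe
#' acting as a separator; ligatures expanded (following "oe" for \enc{œ}{oe},
#' "ae" for \enc{æ}{ae}); diacritics stripped; tokenization on any remaining
#' non-alphanumeric character. The function is idempotent: normalizing the
#' space-joined token output reproduces the tokens.
#'
#' Stop words are *not* removed here; the query interpreter drops them from
#' residual word terms only, after concept matching, so that multi-word
#' concept labels containing function words ("maladie de Crohn") still match
#' whole.
#'
#' @param text A character vector of raw query or field text.
#' @param lang Three-letter language code (`"fre"`, `"eng"`, ...). Only
#'   French currently activates elision handling; other languages get the
#'   language-neutral steps.
#' @return For length-1 input, a character vector of tokens; otherwise a list
#'   of token vectors, one per input element.
#' @examples
#' normalize_text("Maladie cœliaque")   # "maladie" "coeliaque"
#' normalize_text("l'angine")                # "angine"
#' @export
normalize_text <- function(text, lang = "fre") {
  stopifnot(is.character(text))
  x <- stringi::stri_trans_nfc(text)
  x <- stringr::str_to_lower(x)
  x <- stringr::str_replace_all(x, "[’ʼ′]", "'")
  if (identical(lang, "fre")) {
    # elided article + apostrophe at a word boundary: drop the article,
    # apostrophe becomes a separator
    x <- stringr::str_replace_all(x, "(?<![\\p{L}\\p{N}])(qu|l|d|j|n|s|t)'", " ")
  }
  x <- stringr::str_replace_all(x, c("œ" = "oe", "æ" = "ae"))
  x <- stringi::stri_trans_general(x, "Latin-ASCII")
  toks <- stringr::str_split(x, "[^a-z0-9]+")
  toks <- purrr::map(toks, function(t) t[nzchar(t)])
  if (length(toks) == 1L) toks[[1]] else toks
}

#' Normalized lookup key for a label
#'
#' Space-joined normalized tokens; the key under which every label, synonym
#' and acronym is stored in the terminology lookup table.
#'
#' @inheritParams normalize_text
#' @return Character vector of keys (one per input element).
#' @keywords internal
normalize_key <- function(text, lang = "fre") {
  toks <- normalize_text(text, lang)
  if (is.character(toks)) toks <- list(toks)
  vapply(toks, paste, character(1), collapse = " ")
}

#' Case-folded tokens without linguistic normalization
#'
#' The weak tokenizer used by the `all_fields` search strategy to emulate an
#' engine that handles neither accentuation nor elision: lower-cases and
#' splits on punctuation, but keeps diacritics and does not split on the
#' apostrophe (so "l'angine" stays one token and accented forms only match
#' themselves).
#'
#' @inheritParams normalize_text
#' @return Character vector of tokens (length-1 input) or list thereof.
#' @export
casefold_tokens <- function(text) {
  stopifnot(is.character(text))
  x <- stringi::stri_trans_nfc(text)
  x <- stringr::str_to_lower(x)
  x <- stringr::str_replace_all(x, "[’ʼ′]", "'")
  toks <- stringr::str_split(x, "[^\\p{L}\\p{N}']+")
  toks <- purrr::map(toks, function(t) {
    t <- stringr::str_remove_all(t, "^'+|'+$")
    t[nzchar(t)]
  })
  if (length(toks) == 1L) toks[[1]] else toks
}

#' Stop-word list for a language
#'
#' Small packaged per-language lists, applied by [interpret_query()] to
#' residual word terms only.
#'
#' @param lang Three-letter language code.
#' @return Character vector of (normalized) stop words; empty if no list is
#'   packaged for `lang`.
#' @export
stop_words <- function(lang = "fre") {
  path <- system.file("extdata", "stopwords", paste0(lang, ".txt"),
                      package = "medlingua")
  if (!nzchar(path)) return(character(0))
  words <- readr::read_lines(path, progress = FALSE)
  words <- words[nzchar(words) & !stringr::str_starts(words, "#")]
  unique(normalize_key(words, lang))
}
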