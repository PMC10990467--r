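#' Normalize raw utterance text
#'
#' Unicode NFKC normalization followed by lowercasing. All pattern matching
#' and tokenization operate on normalized text, which makes flagging
#' deterministic across platforms and independent of the tokenizer chosen.
#'
#' @param text character vector.
#' @return character vector of the same length.
#' @export
normalize_text <- function(text) {
  text[is.na(text)] <- ""
  stringi::stri_trans_tolower(stringi::stri_trans_nfkc(text))
}

#' Tokenize an utterance into lemmas
#'
#' The default tokenizer stands in for a morphological analyser: it
#' normalizes ([normalize_text()]), splits on whitespace and punctuation,
#' and folds conjugations through the lemma map. Any function with the
#' same signature can be substituted (e.g. one wrapping a true Japanese
#' morphological analyser) without changing downstream contracts, because
#' category flagging matches on the normalized text, not on tokens.
#'
#' @param text a single string (possibly empty or `NA`).
#' @param lemma_map named character vector, surface -> lemma (idempotent).
#' @return character vector of lemmas, in order of occurrence; empty text
#'   yields `character(0)`.
#' @examples
#' tokenize("Useless! Useless!")          # "useless" "useless"
#' tokenize("killed", c(killed = "kill")) # "kill"
#' @export
tokenize <- function(text, lemma_map = character()) {
  stopifnot(length(text) == 1)
  norm <- normalize_text(text)
  if (!nzchar(norm)) return(character())
  # split on anything that is not a letter, digit or in-word apostrophe
  toks <- stringi::stri_split_regex(norm, "[^\\p{L}\\p{N}']+")[[1]]
  toks <- gsub("^'+|'+$", "", toks)
  toks <- toks[nzchar(toks)]
  if (length(lemma_map)) {
    hit <- toks %in% names(lemma_map)
    toks[hit] <- unname(lemma_map[toks[hit]])
  }
  toks
}
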