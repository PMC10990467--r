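#' Flag one utterance with aggression categories
#'
#' An explicit category's flag is TRUE iff at least one of its patterns
#' matches the normalized utterance: literal patterns as case-insensitive
#' substrings, regex patterns by regex search. Matching is on the whole
#' utterance (not per token) so multi-word patterns such as "poor memory"
#' work. The residual flag `other` is TRUE iff no explicit category
#' matched. One utterance may carry several explicit flags.
#'
#' @param text utterance string (may be empty: an exposed participant who
#'   gave no example).
#' @param lex an [lexicon()] object.
#' @return list with elements `flags` (named logical over
#'   job_performance, personality_looks, life_threat, other) and
#'   `matched_patterns` (named list; the patterns that fired, non-empty
#'   exactly for the explicit categories whose flag is TRUE).
#' @export
flag_utterance <- function(text, lex) {
  stopifnot(inherits(lex, "aggr_lexicon"), length(text) == 1)
  norm <- normalize_text(text)
  flags <- stats::setNames(logical(length(ALL_CATEGORIES)), ALL_CATEGORIES)
  matched <- stats::setNames(vector("list", length(ALL_CATEGORIES)), ALL_CATEGORIES)
  for (cat_ in lex$categories) {
    p <- lex$patterns[[cat_]]
    hit <- vapply(seq_len(nrow(p)), function(i) {
      if (p$type[i] == "literal")
        grepl(normalize_text(p$pattern[i]), norm, fixed = TRUE)
      else
        grepl(p$pattern[i], norm, perl = TRUE, ignore.case = TRUE)
    }, logical(1))
    flags[[cat_]] <- any(hit)
    matched[[cat_]] <- p$pattern[hit]
  }
  flags[["other"]] <- !any(flags[AGGRESSION_CATEGORIES])
  matched[["other"]] <- character()
  list(flags = flags, matched_patterns = matched)
}

#' Classify a table of utterances at participant level
#'
#' Each row of `utterances` is one free-text example. A participant with
#' several utterances receives the union (logical OR) of the per-utterance
#' flags; `other` is residual per utterance, so a participant whose
#' examples include both a lexicon match and an unmatched utterance can
#' legitimately carry an explicit flag and `other` at the same time (the
#' per-category person counts may sum well above the number of flagged
#' participants, as in published exposure tabulations).
#'
#' @param utterances data.frame with columns `participant_id`, `text` and
#'   optionally `perpetrator` (carried through untouched).
#' @param lex an [lexicon()] object.
#' @return data.frame of class `utterance_flags`: one row per participant,
#'   columns `participant_id`, the four logical flag columns, and a
#'   list-column `matched_patterns`.
#' @export
classify_utterances <- function(utterances, lex) {
  stopifnot(is.data.frame(utterances),
            all(c("participant_id", "text") %in% names(utterances)))
  if (any(!nzchar(as.character(utterances$participant_id))) ||
      any(is.na(utterances$participant_id)))
    stop("participant_id must be non-empty")
  ids <- unique(as.character(utterances$participant_id))
  per_utt <- lapply(as.character(utterances$text), flag_utterance, lex = lex)
  by_id <- split(per_utt, factor(as.character(utterances$participant_id), levels = ids))
  rows <- lapply(by_id, function(fl) {
    flags <- Reduce(`|`, lapply(fl, `[[`, "flags"))
    matched <- stats::setNames(lapply(ALL_CATEGORIES, function(cat_)
      unique(unlist(lapply(fl, function(x) x$matched_patterns[[cat_]])))),
      ALL_CATEGORIES)
    list(flags = flags, matched = matched)
  })
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (cat_ in ALL_CATEGORIES)
    out[[cat_]] <- vapply(rows, function(r) r$flags[[cat_]], logical(1))
  out$matched_patterns <- I(unname(lapply(rows, `[[`, "matched")))
  class(out) <- c("utterance_flags", class(out))
  out
}

#' Conjugation-grouped word-frequency table for one category
#'
#' Tokenizes the texts of all utterances flagged with `category`,
#' accumulates lemma counts, and keeps only lemmas occurring at least
#' `min_frequency` times — the rule used for word-cloud rendering, where
#' only words with frequency two or higher are plotted. Rows are ordered
#' by descending count, ties broken lexicographically.
#'
#' @param utterances data.frame with columns `participant_id`, `text`.
#' @param category one of `"job_performance"`, `"personality_looks"`,
#'   `"life_threat"`, `"other"`.
#' @param lex an [lexicon()] object (supplies patterns and lemma map).
#' @param min_frequency integer >= 1; export threshold (default 2).
#' @param tokenizer function `(text, lemma_map) -> character` used to
#'   split utterances; defaults to [tokenize()].
#' @return data.frame of class `token_freq` with columns `lemma`, `count`;
#'   attribute `min_frequency`.
#' @export
build_frequency_table <- function(utterances, category, lex, min_frequency = 2,
                                  tokenizer = tokenize) {
  if (!category %in% ALL_CATEGORIES)
    stop("unknown category: ", category)
  stopifnot(min_frequency >= 1)
  texts <- as.character(utterances$text)
  in_cat <- vapply(texts, function(t) flag_utterance(t, lex)$flags[[category]],
                   logical(1), USE.NAMES = FALSE)
  toks <- unlist(lapply(texts[in_cat], tokenizer, lemma_map = lex$lemma_map))
  if (length(toks) == 0) {
    out <- data.frame(lemma = character(), count = integer())
  } else {
    tab <- table(toks)
    out <- data.frame(lemma = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
    out <- out[out$count >= min_frequency, , drop = FALSE]
    out <- out[order(-out$count, out$lemma), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "min_frequency") <- as.integer(min_frequency)
  class(out) <- c("token_freq", class(out))
  out
}

#' Export a frequency table as TSV (lemma, count)
#' @param freq a `token_freq` data.frame.
#' @param path output path.
#' @export
write_frequency_table <- function(freq, path) {
  utils::write.table(as.data.frame(freq)[, c("lemma", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Count exposed participants per aggression category
#'
#' Given person-level flags and a per-participant exposure indicator,
#' returns the number of exposed participants carrying each flag. Because
#' one participant may carry several flags, the per-category counts can
#' sum to more than the overall exposed count, which is reported
#' separately.
#'
#' @param flags an `utterance_flags` data.frame ([classify_utterances()]).
#' @param exposed logical vector, one element per row of `flags` (or named
#'   by participant_id).
#' @return list with `overall` (exposed count) and `by_category` (named
#'   integer vector over the four categories).
#' @export
tabulate_flag_counts <- function(flags, exposed) {
  ids <- as.character(flags$participant_id)
  if (anyDuplicated(ids))
    stop("duplicate participant_id in flags: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(names(exposed))) exposed <- exposed[ids]
  if (length(exposed) != nrow(flags))
    stop("`exposed` must have one value per participant")
  counts <- vapply(ALL_CATEGORIES,
                   function(cat_) sum(flags[[cat_]] & exposed), integer(1))
  list(overall = sum(exposed), by_category = counts)
}
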