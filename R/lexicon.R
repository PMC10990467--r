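#' Aggression-category lexicon
#'
#' A lexicon maps each explicit aggression category to a list of match
#' patterns (literal substrings or regular expressions) and carries a
#' lemma map that groups word conjugations onto a canonical form. The
#' residual category `"other"` never appears in a lexicon: an utterance is
#' "other" exactly when no explicit category matches.
#'
#' @param patterns named list, one element per explicit category. Each
#'   element is a data.frame with columns `pattern` (character, non-empty)
#'   and `type` (`"literal"` or `"regex"`), or a plain character vector
#'   (taken as literals).
#' @param lemma_map named character vector mapping surface token to lemma.
#'   Must be idempotent: every lemma that is itself a key must map to
#'   itself.
#' @return An object of class `aggr_lexicon`.
#' @seealso [default_lexicon()], [read_lexicon()], [flag_utterance()]
#' @export
lexicon <- function(patterns, lemma_map = character()) {
  if (!is.list(patterns) || is.null(names(patterns)) || any(names(patterns) == ""))
    stop("`patterns` must be a named list of per-category pattern sets")
  cats <- names(patterns)
  if ("other" %in% cats)
    stop("category \"other\" is residual by construction and may not carry patterns")
  missing_cats <- setdiff(AGGRESSION_CATEGORIES, cats)
  if (length(missing_cats))
    stop("lexicon must define every explicit category; missing: ",
         paste(missing_cats, collapse = ", "))
  # canonical order, regardless of input (or on-disk) order
  cats <- c(AGGRESSION_CATEGORIES, setdiff(cats, AGGRESSION_CATEGORIES))
  patterns <- patterns[cats]

  patterns <- lapply(patterns, function(p) {
    if (is.character(p)) p <- data.frame(pattern = p, type = "literal",
                                         stringsAsFactors = FALSE)
    if (!is.data.frame(p) || !all(c("pattern", "type") %in% names(p)))
      stop("each category's patterns must be a character vector or a ",
           "data.frame with columns pattern, type")
    p$pattern <- as.character(p$pattern)
    p$type <- as.character(p$type)
    if (any(!nzchar(p$pattern)))
      stop("empty pattern string in lexicon")
    bad <- setdiff(unique(p$type), c("literal", "regex"))
    if (length(bad))
      stop("unknown pattern type(s): ", paste(bad, collapse = ", "))
    p[, c("pattern", "type")]
  })

  # fail fast on malformed regexes, naming category and pattern
  for (cat in cats) {
    p <- patterns[[cat]]
    for (i in which(p$type == "regex")) {
      ok <- tryCatch({grepl(p$pattern[i], "", perl = TRUE); TRUE},
                     error = function(e) FALSE,
                     warning = function(w) FALSE)
      if (!ok)
        stop(sprintf("invalid regex in category \"%s\": %s", cat, p$pattern[i]))
    }
  }

  lemma_map <- validate_lemma_map(lemma_map)

  structure(list(categories = cats, patterns = patterns, lemma_map = lemma_map),
            class = "aggr_lexicon")
}

#' @export
print.aggr_lexicon <- function(x, ...) {
  cat("<aggr_lexicon>\n")
  for (cat_ in x$categories)
    cat(sprintf("  %-18s %d pattern(s)\n", cat_, nrow(x$patterns[[cat_]])))
  cat(sprintf("  lemma map: %d entries\n", length(x$lemma_map)))
  invisible(x)
}

# The three explicit categories; "other" is always residual.
AGGRESSION_CATEGORIES <- c("job_performance", "personality_looks", "life_threat")
ALL_CATEGORIES <- c(AGGRESSION_CATEGORIES, "other")

validate_lemma_map <- function(lemma_map) {
  if (length(lemma_map) == 0) return(stats::setNames(character(), character()))
  if (!is.character(lemma_map) || is.null(names(lemma_map)))
    stop("`lemma_map` must be a named character vector (surface -> lemma)")
  keys <- names(lemma_map)
  # idempotence: applying the map twice equals applying it once
  once <- unname(lemma_map)
  twice <- ifelse(once %in% keys, lemma_map[once], once)
  bad <- which(once != twice)
  if (length(bad))
    stop("lemma_map is not idempotent; chained entries: ",
         paste(sprintf("%s -> %s -> %s", keys[bad], once[bad], twice[bad]),
               collapse = "; "))
  lemma_map
}

#' Default lexicon seeded from the published category examples
#'
#' The deposited study's full supplementary regex list is not reproduced in
#' its main text, so this default carries only the example words printed
#' there: job-performance criticism ("idiot", "useless", "poor memory",
#' "quit", "resign"), attacks on personality and looks ("bald head",
#' "shit", "ugly") and threats on life ("die", "kill"). It is illustrative,
#' not authoritative; real analyses should supply their own lexicon via
#' [read_lexicon()].
#'
#' The bundled lemma map folds the obvious English conjugations of the
#' seed words (e.g. "killed" -> "kill", "dies" -> "die").
#'
#' @return An `aggr_lexicon`.
#' @export
default_lexicon <- function() {
  lexicon(
    patterns = list(
      job_performance   = c("idiot", "useless", "poor memory", "quit", "resign"),
      personality_looks = c("bald head", "shit", "ugly"),
      life_threat       = c("die", "kill")
    ),
    lemma_map = c(
      killed = "kill", kills = "kill", killing = "kill",
      died = "die", dies = "die", dying = "die",
      quits = "quit", quitting = "quit",
      resigns = "resign", resigned = "resign", resigning = "resign",
      idiots = "idiot"
    )
  )
}

#' Read / write a lexicon as TSV
#'
#' The on-disk format is a UTF-8 TSV with header
#' `category<TAB>pattern<TAB>pattern_type`, one row per pattern;
#' `pattern_type` is `literal` or `regex`.
#'
#' @param path file path.
#' @param lemma_map_path optional two-column TSV (`surface<TAB>lemma`, with
#'   header) holding the conjugation-grouping map.
#' @return [read_lexicon()]: an `aggr_lexicon`. [write_lexicon()]: `path`,
#'   invisibly.
#' @export
read_lexicon <- function(path, lemma_map_path = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("category", "pattern", "pattern_type")
  if (!all(need %in% names(tab)))
    stop("lexicon file must have columns category, pattern, pattern_type: ", path)
  pats <- split(tab, tab$category)
  pats <- lapply(pats, function(d)
    data.frame(pattern = d$pattern, type = d$pattern_type, stringsAsFactors = FALSE))
  lm <- character()
  if (!is.null(lemma_map_path)) lm <- read_lemma_map(lemma_map_path)
  lexicon(pats, lm)
}

#' @rdname read_lexicon
#' @param lex an `aggr_lexicon`.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "aggr_lexicon"))
  rows <- do.call(rbind, lapply(lex$categories, function(cat_) {
    p <- lex$patterns[[cat_]]
    data.frame(category = cat_, pattern = p$pattern, pattern_type = p$type,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_lexicon
#' @export
read_lemma_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (ncol(tab) < 2)
    stop("lemma map must be a two-column TSV (surface, lemma): ", path)
  validate_lemma_map(stats::setNames(as.character(tab[[2]]), as.character(tab[[1]])))
}

#' @rdname read_lexicon
#' @export
write_lemma_map <- function(lemma_map, path) {
  lemma_map <- validate_lemma_map(lemma_map)
  utils::write.table(
    data.frame(surface = names(lemma_map), lemma = unname(lemma_map)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
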