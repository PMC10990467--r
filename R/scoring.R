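#' Score the CES-D depression scale
#'
#' Sums the 20 items (each 0-3) after mapping reverse-scored items
#' v -> 3 - v, and applies the caseness cutoff (default total >= 16).
#' Reverse-scored positions default to the instrument-standard items
#' 4, 8, 12 and 16 (1-based).
#'
#' @param items numeric vector of length 20, or a matrix / data.frame with
#'   20 columns (one row per respondent); values in 0..3.
#' @param reverse integer positions of reverse-scored items.
#' @param cutoff caseness threshold (inclusive).
#' @return list with `total` (0..60) and `case` (logical), vectorized over
#'   rows for matrix input.
#' @export
score_cesd <- function(items, reverse = c(4, 8, 12, 16), cutoff = 16) {
  m <- as_item_matrix(items, 20, "CES-D item")
  if (length(reverse)) {
    stopifnot(all(reverse %in% seq_len(20)))
    m[, reverse] <- 3 - m[, reverse]
  }
  total <- as.integer(rowSums(m))
  list(total = total, case = total >= cutoff)
}

#' Score the Pittsburgh Sleep Quality Index
#'
#' Sums the 7 component scores (each 0-3) into the global score (0-21)
#' and applies the poor-sleep cutoff (default global >= 6). Component
#' derivation from the 18 raw items is out of scope; input is accepted at
#' component level.
#'
#' @param components numeric vector of length 7, or matrix / data.frame
#'   with 7 columns; values in 0..3.
#' @param cutoff poor-sleep threshold (inclusive).
#' @return list with `global` (0..21) and `poor_sleep` (logical).
#' @export
score_psqi <- function(components, cutoff = 6) {
  m <- as_item_matrix(components, 7, "PSQI component")
  global <- as.integer(rowSums(m))
  list(global = global, poor_sleep = global >= cutoff)
}

as_item_matrix <- function(x, k, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != k)
    stop(sprintf("expected %d %ss, got %d", k, what, ncol(x)))
  storage.mode(x) <- "double"
  bad <- which(is.na(x) | x < 0 | x > 3 | x != round(x), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("%s %d out of range 0..3 (row %d)", what, bad[1, 2], bad[1, 1]))
  x
}

#' Dichotomize the exposure Likert item
#'
#' The exposure question offers five frequencies: never (1), once or less
#' a month (2), a few times a month (3), one to a few times a week (4),
#' mostly every day (5). Any response above "never" counts as exposed.
#'
#' @param likert integer vector with values in 1..5.
#' @return logical vector: FALSE iff likert == 1.
#' @export
dichotomize_exposure <- function(likert) {
  likert <- as.numeric(likert)
  bad <- which(is.na(likert) | likert < 1 | likert > 5 | likert != round(likert))
  if (length(bad))
    stop("exposure Likert value out of range 1..5 at position ", bad[1])
  likert >= 2
}
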