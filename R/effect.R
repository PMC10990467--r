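#' 2x2 exposure-by-outcome contingency table
#'
#' Cells follow the epidemiological convention: `a` exposed cases, `b`
#' exposed non-cases, `c` unexposed cases, `d` unexposed non-cases.
#'
#' @param exposed,case logical vectors of equal length, same participant
#'   order.
#' @param exposure_label,outcome_label labels carried into estimates.
#' @return object of class `contingency_2x2`.
#' @export
build_2x2 <- function(exposed, case, exposure_label = "exposure",
                      outcome_label = "outcome") {
  if (length(exposed) != length(case))
    stop("exposed and case vectors differ in length (",
         length(exposed), " vs ", length(case), ")")
  if (anyNA(exposed) || anyNA(case))
    stop("exposed/case vectors must not contain NA")
  as_2x2(sum(exposed & case), sum(exposed & !case),
         sum(!exposed & case), sum(!exposed & !case),
         exposure_label, outcome_label)
}

#' @rdname build_2x2
#' @param a,b,c,d non-negative integer cell counts.
#' @export
as_2x2 <- function(a, b, c, d, exposure_label = "exposure",
                   outcome_label = "outcome") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  structure(list(a = a, b = b, c = c, d = d,
                 n = a + b + c + d,
                 exposed = a + b, cases = a + c,
                 exposure_label = exposure_label,
                 outcome_label = outcome_label),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("<2x2> %s x %s (n = %d)\n", x$exposure_label, x$outcome_label, x$n))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"), c("case", "non-case")))
  print(m)
  invisible(x)
}

#' Crude odds ratio with Woolf confidence interval
#'
#' OR = ad/bc; the CI is Woolf's: exp(ln OR +/- z * SE) with
#' SE = sqrt(1/a + 1/b + 1/c + 1/d); the p-value is the two-sided Wald
#' test of ln OR / SE against the standard normal. With
#' `zero_cell_correction = TRUE` and any empty cell, the Haldane-Anscombe
#' correction adds 0.5 to all four cells (off by default: the reference
#' tables this package reproduces contain no zeros).
#'
#' @param tab a `contingency_2x2`.
#' @param z normal quantile for the CI (default 1.959964, i.e. 95%).
#' @param zero_cell_correction apply +0.5 to all cells when any is zero.
#' @return object of class `effect_estimate` with fields `odds_ratio`,
#'   `ci_low`, `ci_high`, `log_or_se`, `p_value`, `method`
#'   (`"crude_woolf"`), `correction_applied`.
#' @export
crude_or <- function(tab, z = 1.959964, zero_cell_correction = FALSE) {
  stopifnot(inherits(tab, "contingency_2x2"))
  cells <- c(a = tab$a, b = tab$b, c = tab$c, d = tab$d)
  correction_applied <- FALSE
  if (any(cells == 0)) {
    if (!zero_cell_correction)
      stop("zero cell (", paste(names(cells)[cells == 0], collapse = ", "),
           ") in 2x2 table \"", tab$exposure_label, " x ", tab$outcome_label,
           "\"; enable zero_cell_correction to estimate")
    cells <- cells + 0.5
    correction_applied <- TRUE
  }
  log_or <- log(cells[["a"]]) + log(cells[["d"]]) -
            log(cells[["b"]]) - log(cells[["c"]])
  se <- sqrt(sum(1 / cells))
  effect_estimate(
    odds_ratio = exp(log_or), ci_low = exp(log_or - z * se),
    ci_high = exp(log_or + z * se), log_or_se = se,
    p_value = 2 * stats::pnorm(-abs(log_or / se)),
    method = "crude_woolf", correction_applied = correction_applied,
    exposure = tab$exposure_label, outcome = tab$outcome_label,
    n = tab$n, cells = c(a = tab$a, b = tab$b, c = tab$c, d = tab$d))
}

effect_estimate <- function(odds_ratio, ci_low, ci_high, log_or_se, p_value,
                            method, correction_applied = FALSE,
                            exposure = NA_character_, outcome = NA_character_,
                            n = NA_integer_, cells = NULL, converged = TRUE,
                            separation = FALSE) {
  structure(list(odds_ratio = odds_ratio, ci_low = ci_low, ci_high = ci_high,
                 log_or_se = log_or_se, p_value = p_value, method = method,
                 correction_applied = correction_applied, exposure = exposure,
                 outcome = outcome, n = n, cells = cells,
                 converged = converged, separation = separation),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s | %s vs %s: OR %s (95%% CI %s, %s), p %s\n",
              x$method, x$exposure, x$outcome,
              format_or(x$odds_ratio), format_or(x$ci_low),
              format_or(x$ci_high), format_p(x$p_value)))
  invisible(x)
}

# report-boundary rounding: OR/CI two decimals, p three ("<0.001" below 5e-4)
format_or <- function(x) sprintf("%.2f", x)
format_p <- function(p) ifelse(p < 5e-4, "<0.001", sprintf("%.3f", p))

#' Crude odds ratios for every exposure definition and outcome
#'
#' One estimate per exposure definition (overall exposure plus each
#' aggression category) crossed with each dichotomous outcome (CES-D
#' caseness, PSQI poor sleep). For a category, "exposed" means flagged
#' with that category; the reference group is everyone else in the
#' analysis set, including the unexposed.
#'
#' @param flags `utterance_flags` for the exposed participants
#'   ([classify_utterances()]); participants absent from `flags` carry no
#'   category flags.
#' @param exposed named logical vector (names = participant_id) over the
#'   full analysis set.
#' @param outcomes data.frame with columns `participant_id`, `cesd_case`,
#'   `psqi_poor` over the full analysis set.
#' @param z normal quantile for CIs.
#' @param zero_cell_correction passed to [crude_or()].
#' @return data.frame, one row per estimate, columns exposure, outcome, n,
#'   a, b, c, d, or, ci_low, ci_high, p, method, correction_applied.
#' @export
run_crude_battery <- function(flags, exposed, outcomes, z = 1.959964,
                              zero_cell_correction = FALSE) {
  if (nrow(outcomes) == 0) stop("empty cohort")
  ids <- as.character(outcomes$participant_id)
  if (is.null(names(exposed))) names(exposed) <- ids
  expo <- stats::setNames(rep(FALSE, length(ids)), ids)
  expo[names(exposed)[exposed]] <- TRUE
  flag_mat <- matrix(FALSE, length(ids), length(ALL_CATEGORIES),
                     dimnames = list(ids, ALL_CATEGORIES))
  if (!is.null(flags) && nrow(flags)) {
    fid <- as.character(flags$participant_id)
    keep <- fid %in% ids
    for (cat_ in ALL_CATEGORIES)
      flag_mat[fid[keep], cat_] <- flags[[cat_]][keep]
  }
  defs <- c(overall = NA, stats::setNames(ALL_CATEGORIES, ALL_CATEGORIES))
  out_defs <- c(cesd_case = "cesd_case", psqi_poor = "psqi_poor")
  rows <- list()
  for (dn in names(defs)) {
    ev <- if (dn == "overall") unname(expo[ids]) else unname(flag_mat[ids, dn])
    for (on in names(out_defs)) {
      cv <- outcomes[[out_defs[[on]]]]
      est <- crude_or(build_2x2(ev, cv, dn, on), z = z,
                      zero_cell_correction = zero_cell_correction)
      rows[[length(rows) + 1]] <- data.frame(
        exposure = dn, outcome = on, n = est$n,
        a = est$cells[["a"]], b = est$cells[["b"]],
        c = est$cells[["c"]], d = est$cells[["d"]],
        or = est$odds_ratio, ci_low = est$ci_low, ci_high = est$ci_high,
        p = est$p_value, method = est$method,
        correction_applied = est$correction_applied,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
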