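# Shared fixtures, built in code.

# Published exposure-by-outcome 2x2 cells: (a, b) pairs per exposure
# definition read off the reference tabulation, with (c, d) forced by the
# analysis-set totals n = 500, 125 depression cases, 186 poor-sleep cases
# at follow-up. Printed crude OR / CI / p alongside for golden checks;
# the overall-depression CI is omitted (typographic duplication of the
# sleep CI in the source; only its OR is checked).
paper_tables <- function() {
  rows <- list(
    list("overall", "cesd_case", 44, 64, or = 2.64, ci = NULL, p = NULL),
    list("job_performance", "cesd_case", 20, 17, or = 4.01, ci = c(2.03, 7.93), p = NULL),
    list("personality_looks", "cesd_case", 10, 11, or = 2.88, ci = c(1.19, 6.95), p = 0.019),
    list("life_threat", "cesd_case", 7, 2, or = 11.06, ci = c(2.27, 53.98), p = 0.003),
    list("other", "cesd_case", 24, 48, or = 1.62, ci = c(0.94, 2.77), p = 0.08),
    list("overall", "psqi_poor", 64, 44, or = 3.22, ci = c(2.07, 5.00), p = NULL),
    list("job_performance", "psqi_poor", 27, 10, or = 5.16, ci = c(2.44, 10.93), p = NULL),
    list("personality_looks", "psqi_poor", 12, 9, or = 2.34, ci = c(0.97, 5.66), p = 0.060),
    list("life_threat", "psqi_poor", 6, 3, or = 3.46, ci = c(0.85, 13.99), p = NULL),
    list("other", "psqi_poor", 42, 30, or = 2.76, ci = c(1.66, 4.60), p = NULL))
  lapply(rows, function(r) {
    cases <- if (r[[2]] == "cesd_case") 125 else 186
    list(exposure = r[[1]], outcome = r[[2]],
         a = r[[3]], b = r[[4]], c = cases - r[[3]],
         d = 500 - cases - r[[4]],
         or = r$or, ci = r$ci, p = r$p)
  })
}

# Expand a 2x2 table to one row per participant (exposed, case).
expand_2x2 <- function(a, b, c, d) {
  data.frame(
    exposed = rep(c(TRUE, TRUE, FALSE, FALSE), c(a, b, c, d)),
    case = rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c, d)))
}

# A 500-row cohort whose classified flags and caseness reproduce every
# published 2x2 cell simultaneously. Exposed groups (108 people):
#   31 x job+other (two utterances: a job-critical one and a neutral one)
#    6 x job only, 21 x personality only, 9 x life-threat only,
#   41 x other only.
# Per-group case counts solve the margin system for both outcomes
# (dual-flag group carries 17 depression / 23 poor-sleep cases).
paper_shaped_cohort <- function() {
  grp <- data.frame(
    text = c("you are useless|you are so slow today", "you are useless",
             "you look so ugly", "please die", "you are so slow today", ""),
    n    = c(31, 6, 21, 9, 41, 392),
    cesd = c(17, 3, 10, 7, 7, 81),
    psqi = c(23, 4, 12, 6, 19, 122),
    exposed = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(grp)), function(i) {
    g <- grp[i, ]
    data.frame(text = g$text, exposed = g$exposed,
               cesd_case = seq_len(g$n) <= g$cesd,
               psqi_poor = seq_len(g$n) <= g$psqi,
               stringsAsFactors = FALSE)
  }))
  n <- nrow(rows)
  # cycling covariates with pairwise-coprime periods so no dummy column is
  # an exact linear combination of the others (adjusted fits need full rank)
  data.frame(
    participant_id = sprintf("F%03d", seq_len(n)),
    sex = rep(c("male", "female"), length.out = n),
    age_class = rep(c("20s", "30s", "40s", "50s", "60-65"), length.out = n),
    job_class = rep(c("regular", "managerial", "board", "non_regular",
                      "self_employed", "regular", "managerial"),
                    length.out = n),
    night_shift = rep(c(FALSE, FALSE, FALSE, TRUE), length.out = n),
    marital = rep(c(TRUE, TRUE, FALSE), length.out = n),
    cesd_total_w1 = rep(c(5, 9, 13, 18), length.out = n),
    psqi_global_w1 = rep(c(2, 4, 5, 7, 9, 3), length.out = n),
    followed_up = TRUE,
    exposure_likert = ifelse(rows$exposed, 3L, 1L),
    utterance_text = rows$text,
    perpetrator = NA_character_,
    cesd_total_w2 = ifelse(rows$cesd_case, 20L, 10L),
    psqi_global_w2 = ifelse(rows$psqi_poor, 8L, 3L),
    stringsAsFactors = FALSE)
}

example_utterances_path <- function() {
  system.file("extdata", "example_utterances.csv", package = "verbalagg")
}
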