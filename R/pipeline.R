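#' Read a cohort CSV
#'
#' Accepts either pre-summed instrument scores (`cesd_total_w*`,
#' `psqi_global_w*`) or item/component-level columns
#' (`cesd_item_01..cesd_item_20`, `psqi_comp_1..psqi_comp_7`, optionally
#' suffixed `_w1`/`_w2`), which are scored with [score_cesd()] /
#' [score_psqi()] on read.
#'
#' @param path CSV path (UTF-8).
#' @return data.frame with at least the total-score columns plus the
#'   exposure/utterance fields present in the file.
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                       na.strings = c("NA", ""))
  for (w in c("w1", "w2")) {
    tot <- paste0("cesd_total_", w)
    items <- sprintf("cesd_item_%02d_%s", 1:20, w)
    if (!tot %in% names(d) && all(items %in% names(d)))
      d[[tot]] <- score_cesd(d[, items])$total
    glob <- paste0("psqi_global_", w)
    comps <- sprintf("psqi_comp_%d_%s", 1:7, w)
    if (!glob %in% names(d) && all(comps %in% names(d)))
      d[[glob]] <- score_psqi(d[, comps])$global
  }
  if ("utterance_text" %in% names(d))
    d$utterance_text[is.na(d$utterance_text)] <- ""
  d
}

#' Run configuration for the full analysis
#'
#' @param cohort path to the cohort CSV, or an in-memory cohort
#'   data.frame.
#' @param lexicon an `aggr_lexicon`, or path to a lexicon TSV.
#' @param lemma_map_path optional lemma-map TSV (ignored when `lexicon`
#'   is already an object).
#' @param out_dir directory for the report bundle (created if absent).
#' @param cutoffs named vector, caseness cutoffs (`cesd`, `psqi`).
#' @param z normal quantile for all CIs.
#' @param zero_cell_correction Haldane-Anscombe policy for crude tables.
#' @param min_frequency word-frequency export threshold.
#' @param covariates adjusted-model covariates (see [model_spec()]).
#' @param seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort, lexicon = default_lexicon(),
                       lemma_map_path = NULL, out_dir = "va_report",
                       cutoffs = c(cesd = 16, psqi = 6), z = 1.959964,
                       zero_cell_correction = FALSE, min_frequency = 2,
                       covariates = c("sex", "age_class", "job_class",
                                      "night_shift", "marital",
                                      "baseline_score"),
                       seed = NA_integer_) {
  stopifnot(all(cutoffs > 0), all(cutoffs == round(cutoffs)))
  structure(list(cohort = cohort, lexicon = lexicon,
                 lemma_map_path = lemma_map_path, out_dir = out_dir,
                 cutoffs = cutoffs, z = z,
                 zero_cell_correction = zero_cell_correction,
                 min_frequency = min_frequency, covariates = covariates,
                 seed = seed),
            class = "run_config")
}

#' Run the complete analysis and write the report bundle
#'
#' Pipeline: restrict to wave-2 responders (listwise, as in the reference
#' analysis) -> dichotomize exposure -> classify utterances -> score
#' caseness at both waves -> crude odds-ratio battery -> adjusted
#' logistic models (one exposure definition per model) -> per-category
#' word-frequency tables. Writes four report artefacts plus a
#' machine-readable run log:
#' `table1_demographics.tsv`, `table2_flag_counts.tsv`,
#' `table3_effects.csv`, `freq_<category>.tsv`, `run_log.json`.
#'
#' All statistics are computed at full precision; rounding (OR/CI to two
#' decimals, p to three, "<0.001" below 0.0005) happens only in the
#' formatted columns of the effect table.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with the in-memory results: `analysis`
#'   (per-participant frame), `flags`, `flag_counts`, `effects`
#'   (full-precision data.frame), `frequency_tables`, `files`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  lex <- config$lexicon
  if (is.character(lex)) lex <- read_lexicon(lex, config$lemma_map_path)
  cohort <- config$cohort
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (nrow(cohort) == 0) stop("stage=input: empty cohort")

  d <- cohort[which(cohort$followed_up %in% TRUE), , drop = FALSE]
  if (nrow(d) == 0) stop("stage=input: no wave-2 responders")
  d$exposed <- tryCatch(dichotomize_exposure(d$exposure_likert),
                        error = function(e) stop("stage=exposure: ",
                                                 conditionMessage(e)))
  d$cesd_case <- d$cesd_total_w2 >= config$cutoffs[["cesd"]]
  d$psqi_poor <- d$psqi_global_w2 >= config$cutoffs[["psqi"]]

  # one participant may report several utterances, separated by "|" in the
  # cohort CSV; each piece is classified separately and flags are OR'd
  texts <- ifelse(is.na(d$utterance_text), "", d$utterance_text)
  pieces <- strsplit(texts, "|", fixed = TRUE)
  pieces[lengths(pieces) == 0] <- list("")
  utt <- data.frame(
    participant_id = rep(d$participant_id, lengths(pieces)),
    text = trimws(unlist(pieces)), stringsAsFactors = FALSE)
  utt_exposed <- utt[utt$participant_id %in% d$participant_id[d$exposed], ,
                     drop = FALSE]
  flags <- classify_utterances(utt_exposed, lex)
  counts <- tabulate_flag_counts(flags, stats::setNames(rep(TRUE, nrow(flags)),
                                                        flags$participant_id))

  exposed_named <- stats::setNames(d$exposed, d$participant_id)
  outcomes <- d[, c("participant_id", "cesd_case", "psqi_poor")]
  crude <- run_crude_battery(flags, exposed_named, outcomes, z = config$z,
                             zero_cell_correction = config$zero_cell_correction)

  # person-level flag columns over the full analysis set, for the models
  for (cat_ in ALL_CATEGORIES) {
    v <- stats::setNames(rep(FALSE, nrow(d)), d$participant_id)
    v[flags$participant_id] <- flags[[cat_]]
    d[[cat_]] <- unname(v[as.character(d$participant_id)])
  }
  d$overall <- d$exposed

  adj <- list()
  for (expo in c("overall", ALL_CATEGORIES)) {
    for (oc in c("cesd_case", "psqi_poor")) {
      spec <- model_spec(outcome = oc, exposure = expo,
                         covariates = config$covariates)
      est <- tryCatch(adjusted_or(d, spec, z = config$z),
                      error = function(e) stop("stage=adjusted_model(",
                                               expo, " x ", oc, "): ",
                                               conditionMessage(e)))
      adj[[paste(expo, oc, sep = ".")]] <- est
    }
  }
  effects <- crude
  effects$adj_or <- effects$adj_ci_low <- effects$adj_ci_high <-
    effects$adj_p <- NA_real_
  effects$adj_converged <- NA
  for (i in seq_len(nrow(effects))) {
    est <- adj[[paste(effects$exposure[i], effects$outcome[i], sep = ".")]]
    effects$adj_or[i] <- est$odds_ratio
    effects$adj_ci_low[i] <- est$ci_low
    effects$adj_ci_high[i] <- est$ci_high
    effects$adj_p[i] <- est$p_value
    effects$adj_converged[i] <- est$converged
  }

  freq <- stats::setNames(lapply(ALL_CATEGORIES, function(cat_)
    build_frequency_table(utt_exposed, cat_, lex,
                          min_frequency = config$min_frequency)),
    ALL_CATEGORIES)

  files <- write_reports(d, counts, effects, freq, config)
  invisible(list(analysis = d, flags = flags, flag_counts = counts,
                 effects = effects, frequency_tables = freq, files = files))
}

write_reports <- function(d, counts, effects, freq, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- list()

  demo <- demographic_table(d)
  f$table1 <- file.path(config$out_dir, "table1_demographics.tsv")
  utils::write.table(demo, f$table1, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")

  t2 <- data.frame(exposure = c("overall", ALL_CATEGORIES),
                   n_exposed = c(counts$overall, unname(counts$by_category)))
  f$table2 <- file.path(config$out_dir, "table2_flag_counts.tsv")
  utils::write.table(t2, f$table2, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")

  t3 <- effects
  t3$crude_or_fmt <- format_or(t3$or)
  t3$crude_ci_fmt <- sprintf("(%s, %s)", format_or(t3$ci_low), format_or(t3$ci_high))
  t3$crude_p_fmt <- format_p(t3$p)
  t3$adj_or_fmt <- format_or(t3$adj_or)
  t3$adj_ci_fmt <- sprintf("(%s, %s)", format_or(t3$adj_ci_low),
                           format_or(t3$adj_ci_high))
  t3$adj_p_fmt <- format_p(t3$adj_p)
  f$table3 <- file.path(config$out_dir, "table3_effects.csv")
  utils::write.csv(t3, f$table3, row.names = FALSE, fileEncoding = "UTF-8")

  for (cat_ in names(freq)) {
    f[[paste0("freq_", cat_)]] <- file.path(config$out_dir,
                                            paste0("freq_", cat_, ".tsv"))
    write_frequency_table(freq[[cat_]], f[[paste0("freq_", cat_)]])
  }

  log <- list(schema_version = "1.0",
              n_analyzed = nrow(d),
              n_exposed = counts$overall,
              seed = config$seed,
              cutoffs = as.list(config$cutoffs),
              z = config$z,
              zero_cell_correction = config$zero_cell_correction,
              min_frequency = config$min_frequency,
              config_hash = config_hash(config),
              files = lapply(f, basename))
  f$run_log <- file.path(config$out_dir, "run_log.json")
  jsonlite::write_json(log, f$run_log, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  f
}

demographic_table <- function(d) {
  rows <- list()
  add <- function(var, level, all_n, ne_n, ex_n)
    rows[[length(rows) + 1]] <<- data.frame(
      characteristic = var, level = level, all = all_n,
      not_exposed = ne_n, exposed = ex_n, stringsAsFactors = FALSE)
  ex <- d$exposed
  add("n", "", nrow(d), sum(!ex), sum(ex))
  for (var in c("sex", "age_class", "job_class", "night_shift", "marital")) {
    v <- as.character(d[[var]])
    for (lv in sort(unique(v)))
      add(var, lv, sum(v == lv), sum(v == lv & !ex), sum(v == lv & ex))
  }
  add("cesd_case_w2", "TRUE", sum(d$cesd_case), sum(d$cesd_case & !ex),
      sum(d$cesd_case & ex))
  add("psqi_poor_w2", "TRUE", sum(d$psqi_poor), sum(d$psqi_poor & !ex),
      sum(d$psqi_poor & ex))
  do.call(rbind, rows)
}

# polynomial rolling hash over the JSON-serialized config (stable,
# dependency-free; identification only, not cryptographic)
config_hash <- function(config) {
  cfg <- config
  cfg$cohort <- if (is.character(cfg$cohort)) cfg$cohort else "<in-memory>"
  cfg$lexicon <- if (is.character(cfg$lexicon)) cfg$lexicon else "<object>"
  cfg$out_dir <- NULL  # analytic identity, not output location
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
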