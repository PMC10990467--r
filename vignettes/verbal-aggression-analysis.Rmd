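---
title: "Classifying workplace verbal aggression and estimating its mental-health effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying workplace verbal aggression and estimating its mental-health effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(verbalagg)
```

## The problem

Verbal aggression at work is usually measured as a frequency ("how often
were you yelled at?"). This package supports a design that additionally
asks *what was said*, collected as free text, and asks whether different
*contents* of aggression — criticism of one's job performance, attacks
on personality and looks, threats on life — carry different risks for
depressive symptoms (CES-D) and sleep disturbance (PSQI) one wave later.
The analysis chain is: classify the utterances, score the instruments,
cross-tabulate, and fit adjusted logistic models. Every stage is exposed
as a tested function, and a synthetic-cohort generator makes the whole
chain verifiable without access to any survey data.

## Classification model

An utterance is flagged for an explicit category if any of that
category's patterns matches the text. Design choices that matter:

* **Whole-utterance matching.** Patterns match the NFKC-normalized,
  lower-cased utterance as substrings (or regexes), not individual
  tokens, so multi-word patterns like "poor memory" work, and the result
  is independent of the tokenizer. The tokenizer (used only for
  frequency tables) is a pluggable function, so a genuine morphological
  analyser for Japanese can replace the default
  whitespace/punctuation splitter without touching any other contract.
* **Multi-label, residual "other".** One utterance may carry several
  explicit flags ("You idiot. I'll kill you." is both job-performance
  criticism and a life threat). "Other" is never a pattern list: it is
  defined per utterance as the absence of all explicit flags.
* **Person-level union.** A participant reporting several utterances
  (separated by `|` in the cohort CSV) gets the logical OR of the
  per-utterance flags. Because "other" is residual *per utterance*, a
  participant can legitimately carry an explicit flag and "other" at the
  same time. This is deliberate: published exposure tabulations of this
  design show per-category counts whose explicit-category total exceeds
  the number of non-"other" exposed participants, which is only
  arithmetically possible under exactly this semantics.
* **Configurable lexicon.** The reference study's full regex list lives
  in unpublished supplementary material, so the built-in
  `default_lexicon()` carries only the example words its methods section
  prints (idiot, useless, poor memory, quit, resign / bald head, shit,
  ugly / die, kill) plus obvious English conjugations in the lemma map.
  It is illustrative; real analyses should load their own TSV lexicon.
  Literal patterns are substrings, so a pattern like "die" will also hit
  "diet" — acceptable for the bundled demonstration lexicon, and the
  reason production lexicons should prefer regex patterns with
  boundaries.

Word-frequency tables group conjugations through an idempotent lemma map
and drop lemmas occurring fewer than `min_frequency` times (default 2,
the usual word-cloud rule). Ordering is deterministic: count descending,
ties lexicographic.

## Instrument scoring

CES-D: 20 items scored 0–3, reverse-scored items at positions 4, 8, 12,
16 (the instrument-standard set; the positions are configurable because
the survey instrument, not this package, fixes them), total 0–60,
caseness at total ≥ 16. PSQI: 7 component scores 0–3 summed to a global
0–21, poor sleep at global ≥ 6. Both cutoffs are inclusive and
configurable. The exposure item is a 5-level frequency Likert;
anything above "never" counts as exposed. Component derivation from the
18 raw PSQI items is out of scope — input is accepted at component (or
total) level.

## Crude estimation

Each exposure definition (overall exposure, then each category flag,
with *reference = everyone else in the analysis set*, not "unexposed
only") is crossed with each outcome into a 2×2 table. The crude OR is
*ad/bc*; the CI is Woolf's log-normal interval
exp(ln OR ± z·√(1/a+1/b+1/c+1/d)) with z = 1.959964; the p-value is the
two-sided Wald test on ln OR. This estimator family was chosen because
it is the one that reproduces, to printed precision, every fully
consistent published interval of the reference analysis (verified in
`test-acceptance.R`, not assumed). Zero cells raise an explicit error
naming the cell; the Haldane–Anscombe +0.5 correction is available but
off by default because the reference tables contain no zeros and a
silent correction would change the estimand.

## Adjusted estimation

The adjusted OR comes from a from-scratch maximum-likelihood logistic
regression (`fit_logistic()`): Newton–Raphson / IRLS on the Bernoulli
log-likelihood, with step-halving so the likelihood never decreases,
convergence when the largest score component or the relative
log-likelihood change drops below `tol = 1e-10`, covariance as the
inverse observed information. Rank deficiency errors with the names of
the collinear columns; complete separation (coefficient beyond ±15 on
the log-odds scale with an essentially perfect fit) sets a flag and
warns rather than returning silently absurd Wald intervals;
non-convergence is likewise flagged. Tests verify agreement with
`stats::glm` to 1e-6 on fixtures (the reference implementation is used
*only* in tests) and exact reduction to the Woolf machinery on
2×2-structured data.

Model specification follows the reference design: one exposure term per
model (per-type effects are never fitted jointly, matching how such
tables are reported), plus sex, age class (10-year bands), job class,
night shift, marital status, and the baseline score of the outcome's own
instrument. Two open choices were resolved as follows:

* "Baseline results" enter as the **continuous baseline total score**,
  not baseline caseness — the stricter adjustment; caseness adjustment
  remains available by passing a custom `baseline_col`.
* Reference levels are the first-listed levels (male, 20s, regular
  employee, no night shift, unmarried). The exposure OR is invariant to
  this choice, which a test confirms rather than assumes.
* Covariates are encoded at their wave-1 values: the demographic table
  of the reference design is collected at baseline, and ~10% of job
  classifications change between waves.

## The synthetic cohort: a stated world

`cohort_config()` defaults encode the reference study's shape, fixed
once and not tuned against test outcomes:

| quantity | default | origin |
|---|---|---|
| baseline n / follow-up | 800 / 0.63 | study design |
| sex, age, job, night shift, marital margins | published demographic margins | reference table |
| baseline CES-D / PSQI | round(N(12.5, 7.9²)), round(N(5.1, 2.6²)), truncated to range | published means (SD) |
| exposure prevalence | 108/500 | published exposed count |
| P(type flag \| exposed) | 37/108, 21/108, 9/108 | published per-type counts |
| outcome prevalences | ≈ 0.25 / 0.37 | published follow-up caseness |

Wave-2 caseness is drawn from a logistic model whose linear predictor
contains the planted type effects, small covariate effects, and the
baseline score; the intercepts (−2.859 CES-D, −2.514 PSQI) were
calibrated **once** by simulation at n = 200,000 to hit the marginal
prevalences above, then frozen. A consistent wave-2 total score is then
drawn on the matching side of the cutoff (half-normal offsets), because
the analysis consumes only caseness and baseline totals — item-level
response simulation is deliberately out of scope. Utterance texts are
assembled from per-category phrase pools built from the default lexicon,
with a neutral pool that contains no lexicon pattern even as a
substring; this is what makes the classification round-trip exact.
`exposure_baseline_coef` tilts the exposure logit by the centred
baseline score, planting measured confounding for recovery experiments.

What the generator does **not** emulate: covariate dependence (margins
only — the joint distribution is unidentified from published tables),
informative attrition (follow-up is independent Bernoulli), realistic
Japanese text, and — importantly — the heavy multi-label overlap of the
real data. With independent type flags at the configured rates, about
half of exposed participants end up in the residual class, versus about
two-thirds in the reference tabulation; matching both the per-type
counts and the residual count simultaneously is impossible under
independence, and the dependence structure is not published. A green
round-trip or recovery test therefore establishes correctness of the
*pipeline mechanics and estimators*, not realism of the text or of the
flag correlation structure.

## Numerical and degenerate-input choices

* z defaults to 1.959964 (matching common epidemiological software)
  rather than `qnorm(0.975)`; the difference is invisible at two
  decimals but is stated here for exactness.
* Rounding happens only at the report boundary: OR/CI to 2 decimals, p
  to 3, printed as "<0.001" below 0.0005. All stored columns keep full
  precision.
* Empty utterance text is valid (an exposed participant who gave no
  example) and classifies as "other". Empty cohorts, zero cells,
  out-of-range scores, unseen factor levels, duplicate participant ids,
  malformed regexes and non-idempotent lemma maps all raise named
  errors rather than propagating NAs.
* Determinism: one global seed drives the generator; the analysis
  itself is seed-free; identical config + seed yields byte-identical
  report files (hash-checked in tests). The run log records a
  config hash excluding the output directory, which is location, not
  identity.

## Known limitations

* The default lexicon is a demonstration seeded from a handful of
  published example words; per-category findings on real data hinge on
  the user's lexicon and its validation.
* Adjusted estimates from the reference analysis (e.g. its headline
  life-threat/depression OR) are not reproducible without the
  individual-level data, which is not deposited; this package instead
  proves the *structural* properties — exact equivalence of the
  logistic route with the contingency route on collapsed data, and
  recovery of planted effects under confounding at n = 20,000 — that
  such estimates depend on.
* Woolf/Wald inference is asymptotic; with cells as small as the
  life-threat column (a = 7, b = 2) the intervals are wide and the
  normal approximation is strained. Exact or penalized methods (Fisher,
  Firth) are out of scope by design.
* Listwise restriction to wave-2 responders mirrors the reference
  analysis; no attrition weighting or imputation is attempted.
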