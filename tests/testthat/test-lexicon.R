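# lexicon construction, tokenization and utterance flagging

test_that("lexicon constructor enforces its invariants", {
  expect_s3_class(default_lexicon(), "aggr_lexicon")
  expect_error(lexicon(list(job_performance = "x")), "missing")
  expect_error(
    lexicon(list(job_performance = "a", personality_looks = "b",
                 life_threat = "c", other = "d")),
    "residual")
  expect_error(
    lexicon(list(job_performance = c("idiot", ""),
                 personality_looks = "b", life_threat = "c")),
    "empty pattern")
  bad_regex <- list(
    job_performance = data.frame(pattern = "(unclosed", type = "regex"),
    personality_looks = "b", life_threat = "c")
  expect_error(lexicon(bad_regex), "job_performance.*\\(unclosed")
  expect_error(
    lexicon(list(job_performance = "a", personality_looks = "b",
                 life_threat = "c"),
            lemma_map = c(a = "b", b = "c")),
    "idempotent")
})

test_that("tokenize splits on whitespace/punctuation and folds lemmas", {
  expect_identical(tokenize("Useless! Useless!"), c("useless", "useless"))
  expect_identical(tokenize(""), character())
  expect_identical(tokenize(NA_character_), character())
  # direct table lookup after splitting
  expect_identical(tokenize("killed", c(killed = "kill")), "kill")
  expect_identical(tokenize("He killed; he kills.",
                            c(killed = "kill", kills = "kill")),
                   c("he", "kill", "he", "kill"))
})

test_that("normalization is NFKC + lowercase (full-width text matches)", {
  lex <- default_lexicon()
  # full-width Latin letters fold onto ASCII under NFKC
  r <- flag_utterance("Ｕｓｅｌｅｓｓ！", lex)
  expect_true(r$flags[["job_performance"]])
})

test_that("flag_utterance matches the published example words", {
  lex <- default_lexicon()
  r <- flag_utterance("Useless!", lex)
  expect_identical(unname(r$flags),
                   c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(r$matched_patterns$job_performance, "useless")

  expect_true(flag_utterance("Please die.", lex)$flags[["life_threat"]])

  custom <- lexicon(list(job_performance = "useless",
                         personality_looks = c("ugly", "fatty"),
                         life_threat = "die"))
  expect_true(flag_utterance("Lose weight, fatty!", custom)$flags[["personality_looks"]])

  r <- flag_utterance("You're so slow today", lex)
  expect_false(any(r$flags[c("job_performance", "personality_looks",
                             "life_threat")]))
  expect_true(r$flags[["other"]])
  expect_length(r$matched_patterns$other, 0)
})

test_that("multi-word and regex patterns match on the whole utterance", {
  lex <- default_lexicon()
  expect_true(flag_utterance("such a poor memory you have",
                             lex)$flags[["job_performance"]])
  rx <- lexicon(list(
    job_performance = data.frame(pattern = "resign|quit", type = "regex"),
    personality_looks = "ugly", life_threat = "die"))
  expect_true(flag_utterance("Just QUIT.", rx)$flags[["job_performance"]])
})

test_that("residual completeness holds for every classified record", {
  lex <- default_lexicon()
  set.seed(42)
  vocab <- c("useless", "idiot", "die", "ugly", "slow", "today", "work",
             "go", "home", "fool", "deadhead")
  for (i in 1:200) {
    txt <- paste(sample(vocab, sample(0:5, 1), replace = TRUE), collapse = " ")
    fl <- flag_utterance(txt, lex)$flags
    expl <- c("job_performance", "personality_looks", "life_threat")
    expect_identical(fl[["other"]], !any(fl[expl]))
  }
})

test_that("adding a pattern never turns a flag off (monotonicity)", {
  base <- lexicon(list(job_performance = "useless",
                       personality_looks = "ugly", life_threat = "die"))
  grown <- lexicon(list(job_performance = c("useless", "slow"),
                        personality_looks = "ugly", life_threat = "die"))
  set.seed(7)
  vocab <- c("useless", "slow", "die", "ugly", "fine", "work")
  for (i in 1:100) {
    txt <- paste(sample(vocab, sample(1:4, 1), replace = TRUE), collapse = " ")
    f0 <- flag_utterance(txt, base)$flags
    f1 <- flag_utterance(txt, grown)$flags
    expect_true(all(!f0[c("job_performance", "personality_looks",
                          "life_threat")] |
                    f1[c("job_performance", "personality_looks",
                         "life_threat")]))
  }
})

test_that("flags are invariant to the lemma map / tokenizer choice", {
  lex1 <- default_lexicon()
  lex2 <- lexicon(lapply(lex1$patterns, identity), lemma_map = character())
  for (txt in c("You idiot. I'll kill you.", "Please die.", "so slow today"))
    expect_identical(flag_utterance(txt, lex1)$flags,
                     flag_utterance(txt, lex2)$flags)
})

test_that("person-level classification is the union of utterance flags", {
  lex <- default_lexicon()
  utt <- data.frame(
    participant_id = c("p1", "p1", "p2", "p3"),
    text = c("you are useless", "you are so slow today",
             "please die", ""))
  fl <- classify_utterances(utt, lex)
  expect_identical(nrow(fl), 3L)
  p1 <- fl[fl$participant_id == "p1", ]
  # a matched and an unmatched utterance: explicit flag AND residual flag
  expect_true(p1$job_performance && p1$other)
  expect_false(p1$life_threat)
  p3 <- fl[fl$participant_id == "p3", ]
  expect_true(p3$other)  # exposed, gave no example
  expect_error(classify_utterances(data.frame(participant_id = "", text = "x"),
                                   lex),
               "non-empty")
})

test_that("lexicon and lemma map round-trip through TSV", {
  lex <- default_lexicon()
  lp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, lp)
  write_lemma_map(lex$lemma_map, mp)
  back <- read_lexicon(lp, mp)
  expect_identical(back$patterns, lex$patterns)
  expect_identical(sort(names(back$lemma_map)), sort(names(lex$lemma_map)))
})
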