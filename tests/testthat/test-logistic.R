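# design encoding and IRLS logistic regression

test_that("encode_design produces deterministic drop-reference dummies", {
  d <- data.frame(
    participant_id = c("a", "b", "c", "d"),
    sex = c("male", "female", "male", "female"),
    night_shift = c(FALSE, TRUE, TRUE, FALSE),
    overall = c(TRUE, FALSE, TRUE, FALSE),
    y = c(1, 0, 1, 0))
  spec <- model_spec(outcome = "cesd_case", exposure = "overall",
                     covariates = c("sex", "night_shift"))
  d$cesd_case <- d$y
  enc <- encode_design(d, spec)
  # intercept + exposure + 2 binary covariates -> 4 columns
  expect_identical(ncol(enc$X), 4L)
  expect_identical(colnames(enc$X),
                   c("(intercept)", "exposure:overall", "sex:female",
                     "night_shift:TRUE"))
  # round-trip: rows decode back to the records
  expect_identical(enc$X[, "sex:female"] == 1, d$sex == "female")
  expect_identical(enc$X[, "night_shift:TRUE"] == 1, d$night_shift)
  expect_identical(enc$X[, "exposure:overall"] == 1, d$overall)

  # five age classes with reference "20s" -> 4 dummy columns
  d5 <- data.frame(cesd_case = rep(0:1, 5), overall = rep(c(TRUE, FALSE), 5),
                   age_class = rep(c("20s", "30s", "40s", "50s", "60-65"), 2))
  enc5 <- encode_design(d5, model_spec(covariates = "age_class"))
  expect_identical(sum(startsWith(colnames(enc5$X), "age_class:")), 4L)
  for (i in seq_len(nrow(d5))) {
    hit <- which(enc5$X[i, startsWith(colnames(enc5$X), "age_class:")] == 1)
    lvl <- if (length(hit) == 0) "20s" else
      sub("age_class:", "", names(hit))
    expect_identical(lvl, d5$age_class[i])
  }

  d$sex[2] <- "unknown"
  expect_error(encode_design(d, spec), "unseen level.*unknown")
  d$sex[2] <- NA
  expect_error(encode_design(d, spec), "participant b")
  expect_error(encode_design(d[, -2], spec), "lack required column")
})

test_that("intercept-only fit recovers the log-odds in closed form", {
  y <- rep(c(1, 0), c(25, 75))
  fit <- fit_logistic(matrix(1, 100, 1), y)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), log(0.25 / 0.75), tolerance = 1e-10)
})

test_that("single binary predictor reproduces the 2x2 crude estimate", {
  d <- expand_2x2(7, 2, 118, 373)
  fit <- fit_logistic(cbind(1, exposed = as.numeric(d$exposed)),
                      as.numeric(d$case))
  ref <- crude_or(as_2x2(7, 2, 118, 373))
  b <- fit$coefficients[["exposed"]]
  se <- sqrt(fit$covariance["exposed", "exposed"])
  expect_equal(exp(b), ref$odds_ratio, tolerance = 1e-8)
  expect_equal(se, ref$log_or_se, tolerance = 1e-8)  # Wald SE == Woolf SE
  # score equations hold at the optimum
  score <- crossprod(cbind(1, as.numeric(d$exposed)),
                     d$case - fit$fitted)
  expect_lt(max(abs(score)), 10 * 1e-10)
})

test_that("coefficients agree with an independent reference fit", {
  cohort <- generate_cohort(cohort_config(n_baseline = 2000, seed = 5))
  d <- cohort[cohort$followed_up, ]
  d$overall <- dichotomize_exposure(d$exposure_likert)
  d$cesd_case <- d$cesd_total_w2 >= 16
  spec <- model_spec(outcome = "cesd_case", exposure = "overall")
  enc <- encode_design(d, spec)
  fit <- fit_logistic(enc$X, enc$y)
  ref <- stats::glm.fit(enc$X, enc$y, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-12))
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  # covariance: inverse observed information vs reference vcov
  qr_ref <- chol2inv(qr.R(ref$qr))
  expect_equal(unname(diag(fit$covariance)), unname(diag(qr_ref)),
               tolerance = 1e-6)
})

test_that("rank deficiency and separation are reported, not silent", {
  X <- cbind(1, x = c(0, 1, 0, 1), dup = c(0, 1, 0, 1))
  expect_error(fit_logistic(X, c(0, 1, 0, 1)), "collinear.*dup")

  # perfectly separating predictor
  Xs <- cbind(1, x = c(-2, -1, -1.5, 1, 1.5, 2))
  ys <- c(0, 0, 0, 1, 1, 1)
  expect_warning(fit <- fit_logistic(Xs, ys, max_iter = 200), "separation")
  expect_true(fit$separation)
})

test_that("covariate-free adjusted model reduces to the crude estimate", {
  d <- expand_2x2(20, 17, 105, 358)
  d$cesd_case <- d$case
  d$overall <- d$exposed
  spec <- model_spec(outcome = "cesd_case", exposure = "overall",
                     covariates = character())
  adj <- adjusted_or(d, spec)
  cru <- crude_or(build_2x2(d$exposed, d$case))
  expect_equal(adj$odds_ratio, cru$odds_ratio, tolerance = 1e-8)
  expect_equal(adj$ci_low, cru$ci_low, tolerance = 1e-8)
  expect_equal(adj$ci_high, cru$ci_high, tolerance = 1e-8)
  expect_equal(adj$p_value, cru$p_value, tolerance = 1e-8)
  expect_identical(adj$method, "adjusted_wald")
})

test_that("exposure OR is invariant to the reference-level choice", {
  cohort <- generate_cohort(cohort_config(n_baseline = 1200, seed = 8))
  d <- cohort[cohort$followed_up, ]
  d$overall <- dichotomize_exposure(d$exposure_likert)
  d$cesd_case <- d$cesd_total_w2 >= 16
  s1 <- model_spec(outcome = "cesd_case", exposure = "overall")
  refs2 <- default_levels()
  refs2$sex <- rev(refs2$sex)
  refs2$age_class <- c("40s", "20s", "30s", "50s", "60-65")
  s2 <- model_spec(outcome = "cesd_case", exposure = "overall",
                   references = refs2)
  expect_equal(adjusted_or(d, s1)$odds_ratio,
               adjusted_or(d, s2)$odds_ratio, tolerance = 1e-8)
})

test_that("crude and adjusted agree in a collapsible, confounder-free world", {
  co <- default_outcome_coefficients()
  for (oc in c("cesd", "psqi")) {
    co[[oc]][c("female", "night_shift", "marital", "baseline")] <- 0
    co[[oc]][["intercept"]] <- -1.2
  }
  cohort <- generate_cohort(cohort_config(n_baseline = 60000, seed = 14,
                                          follow_up_rate = 1,
                                          outcome_coefficients = co))
  d <- cohort[cohort$followed_up, ]
  d$overall <- dichotomize_exposure(d$exposure_likert)
  d$cesd_case <- d$cesd_total_w2 >= 16
  cru <- crude_or(build_2x2(d$overall, d$cesd_case))
  adj <- adjusted_or(d, model_spec(outcome = "cesd_case",
                                   exposure = "overall"))
  # same estimand once nothing predicts the outcome but exposure
  expect_equal(log(adj$odds_ratio), log(cru$odds_ratio), tolerance = 0.1)
})
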