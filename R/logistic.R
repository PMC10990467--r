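#' Adjusted-model specification
#'
#' Describes one logistic model: a dichotomous outcome, one exposure term,
#' and the adjustment covariates with their reference levels. Defaults
#' mirror the adjusted models of the reference analysis: sex, age class
#' (10-year bands), job class, night-shift work, marital status, plus the
#' baseline total score of the same instrument as the outcome, entered as
#' a continuous covariate.
#'
#' @param outcome `"cesd_case"` or `"psqi_poor"`.
#' @param exposure name of the logical exposure column to estimate
#'   (`"overall"` or a category flag column).
#' @param covariates character subset of `names(references)` plus
#'   `"baseline_score"`, in model order.
#' @param references named list of reference levels / full level sets for
#'   the categorical covariates (first element of each set = reference).
#' @param baseline_col name of the continuous baseline-score column; if
#'   `NULL`, derived from the outcome (`cesd_total_w1` / `psqi_global_w1`).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(outcome = c("cesd_case", "psqi_poor"),
                       exposure = "overall",
                       covariates = c("sex", "age_class", "job_class",
                                      "night_shift", "marital",
                                      "baseline_score"),
                       references = default_levels(),
                       baseline_col = NULL) {
  outcome <- match.arg(outcome)
  if (length(exposure) != 1)
    stop("exactly one exposure term per model")
  if (is.null(baseline_col))
    baseline_col <- if (outcome == "cesd_case") "cesd_total_w1" else "psqi_global_w1"
  structure(list(outcome = outcome, exposure = exposure,
                 covariates = covariates, references = references,
                 baseline_col = baseline_col),
            class = "model_spec")
}

#' Default categorical level sets (reference level first)
#' @export
default_levels <- function() {
  list(sex = c("male", "female"),
       age_class = c("20s", "30s", "40s", "50s", "60-65"),
       job_class = c("regular", "managerial", "board", "non_regular",
                     "self_employed"),
       night_shift = c(FALSE, TRUE),
       marital = c(FALSE, TRUE))
}

#' Build the design matrix and response for a logistic model
#'
#' Dummy (one-hot, drop-reference) coding for categorical covariates, the
#' baseline score as a continuous column, an intercept, and the exposure
#' indicator, in a deterministic column order:
#' intercept, exposure, then covariates in `spec$covariates` order.
#'
#' @param records analysis data.frame; must contain the outcome column,
#'   the exposure column named by `spec$exposure`, every covariate column
#'   and the baseline-score column.
#' @param spec a [model_spec()].
#' @return list with `X` (numeric matrix, named columns), `y` (0/1
#'   vector) and `exposure_col` (column name of the exposure term).
#' @export
encode_design <- function(records, spec) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c(spec$outcome, spec$exposure,
            setdiff(spec$covariates, "baseline_score"))
  if ("baseline_score" %in% spec$covariates) need <- c(need, spec$baseline_col)
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack required column(s): ", paste(miss, collapse = ", "))
  ids <- if ("participant_id" %in% names(records))
    as.character(records$participant_id) else as.character(seq_len(nrow(records)))
  for (col in need) {
    na_at <- which(is.na(records[[col]]))
    if (length(na_at))
      stop("missing value in column \"", col, "\" for participant ",
           ids[na_at[1]])
  }

  n <- nrow(records)
  cols <- list("(intercept)" = rep(1, n))
  ev <- records[[spec$exposure]]
  if (!is.logical(ev)) ev <- as.logical(ev)
  cols[[paste0("exposure:", spec$exposure)]] <- as.numeric(ev)

  for (cov in spec$covariates) {
    if (cov == "baseline_score") {
      cols[[spec$baseline_col]] <- as.numeric(records[[spec$baseline_col]])
      next
    }
    lev <- spec$references[[cov]]
    if (is.null(lev))
      stop("no level set declared for covariate ", cov)
    v <- records[[cov]]
    if (is.logical(lev)) { lev <- as.character(lev); v <- as.character(as.logical(v)) }
    else v <- as.character(v)
    unseen <- setdiff(unique(v), lev)
    if (length(unseen))
      stop("unseen level(s) in covariate \"", cov, "\": ",
           paste(unseen, collapse = ", "))
    for (l in lev[-1])
      cols[[paste0(cov, ":", l)]] <- as.numeric(v == l)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  y <- records[[spec$outcome]]
  if (is.logical(y)) y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  list(X = X, y = y, exposure_col = paste0("exposure:", spec$exposure))
}

#' Maximum-likelihood logistic regression via IRLS
#'
#' Newton-Raphson / iteratively reweighted least squares on the Bernoulli
#' log-likelihood, with step-halving whenever a full Newton step would
#' decrease the likelihood. Convergence is declared when the largest
#' absolute score component falls below `tol` or the relative
#' log-likelihood change does. The coefficient covariance is the inverse
#' of the observed information at the optimum.
#'
#' Complete separation is reported (field `separation`, plus a warning)
#' when a coefficient diverges while every fitted probability approaches
#' its response; non-convergence within `max_iter` is flagged, never
#' silent.
#'
#' @param X numeric design matrix, full column rank (include your own
#'   intercept; see [encode_design()]).
#' @param y 0/1 response vector.
#' @param max_iter maximum IRLS iterations.
#' @param tol convergence tolerance on score and relative log-likelihood.
#' @return object of class `logit_fit`: `coefficients`, `covariance`,
#'   `converged`, `iterations`, `log_likelihood`, `fitted`, `separation`.
#' @export
fit_logistic <- function(X, y, max_iter = 100, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dep, collapse = ", "))
  }

  loglik <- function(eta) sum(y * eta - log1p(exp(eta)))
  beta <- rep(0, ncol(X))
  eta <- drop(X %*% beta)
  ll <- loglik(eta)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    p <- stats::plogis(eta)
    score <- drop(crossprod(X, y - p))
    w <- p * (1 - p)
    info <- crossprod(X, X * w)
    delta <- tryCatch(solve(info, score), error = function(e)
      stop("information matrix singular at iteration ", it,
           " (possible separation)"))
    # step-halving: never accept a likelihood decrease
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      ll_new <- loglik(drop(X %*% beta_new))
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      if (step < 2^-30) { beta_new <- beta; ll_new <- ll; break }
    }
    rel_change <- abs(ll_new - ll) / (abs(ll) + 1e-300)
    beta <- beta_new; eta <- drop(X %*% beta); ll <- ll_new
    if (max(abs(drop(crossprod(X, y - stats::plogis(eta))))) < tol ||
        rel_change < tol) { converged <- TRUE; break }
  }

  p <- stats::plogis(eta)
  # separation heuristic: diverging coefficients with near-perfect fit
  separation <- max(abs(beta)) > 15 && all(abs(y - p) < 1e-6 | p * (1 - p) < 1e-10)
  if (separation)
    warning("possible complete separation: fitted probabilities reach 0/1")
  if (!converged && !separation)
    warning("IRLS did not converge in ", max_iter, " iterations")
  info <- crossprod(X, X * (p * (1 - p)))
  covariance <- solve(info)
  dimnames(covariance) <- list(colnames(X), colnames(X))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 covariance = covariance, converged = converged,
                 iterations = it, log_likelihood = ll, fitted = p,
                 separation = separation),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("<logit_fit> %d coefficients, logLik %.4f, %s in %d iterations\n",
              length(x$coefficients), x$log_likelihood,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  se <- sqrt(diag(x$covariance))
  print(data.frame(estimate = x$coefficients, se = se,
                   z = x$coefficients / se))
  invisible(x)
}

#' Covariate-adjusted odds ratio for one exposure definition
#'
#' Fits the logistic model described by `spec` and returns the exposure
#' effect as an odds ratio with Wald confidence interval and two-sided
#' Wald p-value: OR = exp(beta), CI = exp(beta +/- z se).
#'
#' @inheritParams encode_design
#' @param z normal quantile for the CI.
#' @return an `effect_estimate` with method `"adjusted_wald"`; fields
#'   `converged` and `separation` propagate the fit diagnostics.
#' @export
adjusted_or <- function(records, spec, z = 1.959964) {
  enc <- encode_design(records, spec)
  fit <- fit_logistic(enc$X, enc$y)
  b <- fit$coefficients[[enc$exposure_col]]
  se <- sqrt(fit$covariance[enc$exposure_col, enc$exposure_col])
  effect_estimate(
    odds_ratio = exp(b), ci_low = exp(b - z * se), ci_high = exp(b + z * se),
    log_or_se = se, p_value = 2 * stats::pnorm(-abs(b / se)),
    method = "adjusted_wald", exposure = spec$exposure,
    outcome = spec$outcome, n = nrow(records),
    converged = fit$converged, separation = fit$separation)
}
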