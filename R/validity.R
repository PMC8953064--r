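#' Score the Newest Vital Sign screener
#'
#' Sums six item corrections and bands the total into the published risk
#' categories: 0-1 correct = high likelihood of limited literacy, 2-3 =
#' possibility of limited literacy, 4 or more = adequate literacy. Missing
#' responses are treated as incorrect and flagged with a warning.
#'
#' @param item_corrections Logical (or 0/1) vector of length 6.
#' @return List of class `nvs_result` with `summed_score` (0-6) and
#'   `category`.
#' @export
#' @examples
#' score_nvs(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
score_nvs <- function(item_corrections) {
  if (length(item_corrections) != 6L)
    stop("the screener has exactly 6 items", call. = FALSE)
  x <- as.integer(item_corrections)
  if (anyNA(x)) {
    warning(sum(is.na(x)), " missing response(s) scored as incorrect")
    x[is.na(x)] <- 0L
  }
  if (any(x < 0L | x > 1L)) stop("responses must be 0/1", call. = FALSE)
  s <- sum(x)
  structure(list(summed_score = s, category = nvs_band(s)),
            class = "nvs_result")
}

#' @rdname score_nvs
#' @param score Summed score(s) 0-6.
#' @return `nvs_band()` returns the category label(s) for summed scores.
#' @export
nvs_band <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 6))
    stop("summed score must be in 0..6", call. = FALSE)
  c("high_likelihood_limited", "high_likelihood_limited",
    "possibility_limited", "possibility_limited",
    "adequate", "adequate", "adequate")[score + 1L]
}

#' @export
print.nvs_result <- function(x, ...) {
  cat(sprintf("<nvs_result> score %d/6 (%s)\n", x$summed_score, x$category))
  invisible(x)
}

#' Convergent validity correlation
#'
#' Pearson correlation between two summed-score vectors with pairwise
#' deletion of missing values and a two-sided test.
#'
#' @param scores_a,scores_b Paired numeric score vectors.
#' @return List with `r`, `p_value`, `n` (complete pairs).
#' @export
convergent_correlation <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b))
  ok <- !is.na(scores_a) & !is.na(scores_b)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(scores_a[ok]) == 0 || stats::sd(scores_b[ok]) == 0)
    stop("zero variance in a score vector; correlation undefined", call. = FALSE)
  ct <- stats::cor.test(scores_a[ok], scores_b[ok], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Criterion validity logistic regression
#'
#' Logistic regression of a binary criterion behavior on the health literacy
#' score, optionally controlling for demographic covariates (entered
#' additively). Reports the odds ratio per score point with a Wald 95%
#' confidence interval, plus the ROC area of the raw score against the
#' outcome and its Cohen's d transform. Complete separation and
#' non-convergence are detected and flagged rather than silently reported.
#'
#' @param outcome Binary (0/1 or logical) outcome vector.
#' @param hl_score Numeric score vector.
#' @param covariates Optional data frame of covariates (rows aligned).
#' @param outcome_name Label carried into the result.
#' @param conf_level Confidence level for the Wald interval.
#' @return List of class `criterion_result`: `outcome_name`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `auc`, `cohens_d`, `n`, `converged`, `separation`,
#'   and the fitted `model`.
#' @export
criterion_logistic <- function(outcome, hl_score, covariates = NULL,
                               outcome_name = "outcome", conf_level = 0.95) {
  y <- as.integer(outcome)
  stopifnot(length(y) == length(hl_score))
  dat <- data.frame(.y = y, hl_score = hl_score)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(y))
    dat <- cbind(dat, covariates)
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (length(unique(dat$.y)) < 2L)
    stop("outcome must have both classes", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()))
  beta <- stats::coef(fit)["hl_score"]
  se <- sqrt(stats::vcov(fit)["hl_score", "hl_score"])
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  separation <- !fit$converged || any(abs(stats::coef(fit)) > 15) ||
    any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
  a <- roc_auc(dat$.y, dat$hl_score)
  # a degenerate ROC area (0 or 1, perfect separation) has no finite d
  d <- if (a > 0 && a < 1) auc_to_cohens_d(a) else sign(a - 0.5) * Inf
  structure(list(outcome_name = outcome_name,
                 odds_ratio = unname(exp(beta)),
                 ci_low = unname(exp(beta - zq * se)),
                 ci_high = unname(exp(beta + zq * se)),
                 auc = a, cohens_d = d,
                 n = nrow(dat), converged = fit$converged,
                 separation = separation, model = fit),
            class = "criterion_result")
}

#' @export
print.criterion_result <- function(x, ...) {
  cat(sprintf("<criterion_result> %s: OR = %.2f (95%% CI %.2f, %.2f), AUC = %.2f, d = %.2f (n = %d)\n",
              x$outcome_name, x$odds_ratio, x$ci_low, x$ci_high,
              x$auc, x$cohens_d, x$n))
  if (x$separation) cat("  warning: separation or non-convergence detected\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation with midrank tie correction: the probability
#' that a randomly chosen positive case outscores a randomly chosen
#' negative one, ties counting one half.
#'
#' @param outcome Binary outcome vector (1 = positive class).
#' @param score Numeric score vector.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(outcome, score) {
  y <- as.integer(outcome)
  ok <- !is.na(y) & !is.na(score)
  y <- y[ok]; score <- score[ok]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("need both outcome classes", call. = FALSE)
  r <- rank(score)  # midranks handle ties
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Convert an ROC area to Cohen's d
#'
#' The equal-variance binormal relation underlying the published conversion
#' tables: `d = sqrt(2) * qnorm(auc)`. Antisymmetric about AUC 0.5. With
#' `table_snap = TRUE` the result is rounded to 2 decimals to mimic table
#' lookup.
#'
#' @param auc Area under the ROC curve, in (0, 1).
#' @param table_snap Round to 2 decimal places.
#' @return Cohen's d.
#' @export
#' @examples
#' auc_to_cohens_d(0.5)   # 0
#' auc_to_cohens_d(0.76)  # ~1.0
auc_to_cohens_d <- function(auc, table_snap = FALSE) {
  if (any(auc <= 0 | auc >= 1)) stop("auc must be in (0, 1)", call. = FALSE)
  d <- sqrt(2) * stats::qnorm(auc)
  if (table_snap) round(d, 2) else d
}

#' Crosstab of two categorizations
#'
#' Convenience contingency-table printer for comparing performance-level
#' categorizations across assessments; purely descriptive, no inferential
#' claims attached.
#'
#' @param a,b Category label vectors.
#' @param margin Percentage margin passed to [prop.table()] (2 = within
#'   column).
#' @return List with `counts` and `percent` tables.
#' @export
category_crosstab <- function(a, b, margin = 2L) {
  counts <- table(a, b, useNA = "no")
  list(counts = counts, percent = round(100 * prop.table(counts, margin), 1))
}
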