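#' Uniform differential item functioning between two groups
#'
#' Anchored two-stage uniform DIF: persons are measured once in a pooled
#' calibration; each item's overall difficulty is then re-estimated within
#' each group with person measures (and partial-credit thresholds) anchored.
#' The DIF contrast is the difference of the two group difficulties; a
#' Welch-style t on the two estimates gives the significance. An item is
#' flagged when the contrast is at least `contrast_floor` logits in absolute
#' value *and* p falls below `alpha` (both criteria jointly, the
#' conventional screen for substantively meaningful uniform DIF). Groups of
#' fewer than `min_group_n` persons trigger a warning since about 100
#' persons per group are needed to detect 0.5-logit DIF reliably.
#'
#' @param responses A [response_matrix()].
#' @param grouping Factor (or vector coercible to one) with exactly 2 used
#'   levels, aligned with the persons of `responses`; `NA` persons are
#'   excluded.
#' @param settings An [estimation_settings()] for the pooled calibration.
#' @param contrast_floor Minimum |contrast| in logits to flag (default 0.5).
#' @param alpha Per-test significance threshold (default 0.01, the
#'   multiple-testing allowance).
#' @param min_group_n Group size below which a warning is issued.
#' @param calibration Optional pre-computed pooled calibration to anchor on.
#' @return Data frame of class `dif_result`: one row per item with
#'   `item_id`, `group_a`, `group_b`, `n_a`, `n_b`, `difficulty_a`,
#'   `difficulty_b`, `contrast`, `joint_se`, `t_statistic`, `df`, `p_value`,
#'   `flagged`, `estimable`.
#' @export
uniform_dif <- function(responses, grouping, settings = estimation_settings(),
                        contrast_floor = 0.5, alpha = 0.01,
                        min_group_n = 100L, calibration = NULL) {
  stopifnot(inherits(responses, "response_matrix"))
  g <- factor(grouping)
  if (length(g) != nrow(responses$scores))
    stop("grouping must align with persons", call. = FALSE)
  lev <- levels(droplevels(g))
  if (length(lev) != 2L)
    stop("grouping must have exactly 2 levels (got ", length(lev), ")",
         call. = FALSE)
  if (any(table(g) < min_group_n))
    warning("a group has fewer than ", min_group_n,
            " persons; DIF of 0.5 logits may not be detectable")
  if (is.null(calibration)) calibration <- estimate_jmle(responses, settings)

  al <- align_calibration(calibration, responses)
  g_al <- g[match(al$person_ids, responses$person_ids)]
  res <- lapply(seq_along(al$item_ids), function(j) {
    b0 <- calibration$item_difficulty[j]
    tau <- calibration$thresholds[[j]]
    est <- lapply(lev, function(lv) {
      rows <- which(g_al == lv & !is.na(al$X[, j]))
      anchored_difficulty(al$theta[rows], al$X[rows, j], b0, tau)
    })
    a <- est[[1L]]; b <- est[[2L]]
    if (!a$estimable || !b$estimable)
      return(data.frame(item_id = al$item_ids[j],
                        group_a = lev[1L], group_b = lev[2L],
                        n_a = a$n, n_b = b$n,
                        difficulty_a = a$b, difficulty_b = b$b,
                        contrast = NA_real_, joint_se = NA_real_,
                        t_statistic = NA_real_, df = NA_real_,
                        p_value = NA_real_, flagged = FALSE,
                        estimable = FALSE))
    contrast <- a$b - b$b
    joint_se <- sqrt(a$se^2 + b$se^2)
    tval <- contrast / joint_se
    df <- joint_se^4 / (a$se^4 / (a$n - 1) + b$se^4 / (b$n - 1))
    p <- 2 * stats::pt(-abs(tval), df)
    data.frame(item_id = al$item_ids[j], group_a = lev[1L], group_b = lev[2L],
               n_a = a$n, n_b = b$n,
               difficulty_a = a$b, difficulty_b = b$b,
               contrast = contrast, joint_se = joint_se,
               t_statistic = tval, df = df, p_value = p,
               flagged = abs(contrast) >= contrast_floor & p < alpha,
               estimable = TRUE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("dif_result", "data.frame")
  out
}

# re-estimate an item's overall difficulty for anchored persons, thresholds
# fixed; Newton on the common shift of all steps
anchored_difficulty <- function(theta, x, b0, tau) {
  n <- length(x)
  if (n == 0L)
    return(list(b = NA_real_, se = NA_real_, n = 0L, estimable = FALSE))
  m <- length(item_steps(b0, tau))
  if (length(unique(x)) < 2L && (all(x == 0L) || all(x == m)))
    return(list(b = NA_real_, se = NA_real_, n = n, estimable = FALSE))
  b <- b0
  for (it in 1:100) {
    d <- item_steps(b, tau)
    P <- pcm_prob_matrix(theta, d)
    kk <- 0:length(d)
    E <- drop(P %*% kk); W <- drop(P %*% (kk^2)) - E^2
    move <- clamp((sum(E) - sum(x)) / max(sum(W), 1e-10), 1)
    b <- b + move
    if (abs(move) < 1e-6) break
  }
  d <- item_steps(b, tau)
  P <- pcm_prob_matrix(theta, d)
  kk <- 0:length(d)
  E <- drop(P %*% kk); W <- drop(P %*% (kk^2)) - E^2
  list(b = b, se = 1 / sqrt(max(sum(W), 1e-10)), n = n, estimable = TRUE)
}

#' DIF screen over standard demographic groupings
#'
#' Runs [uniform_dif()] for each requested grouping built from a person
#' covariate table: `gender` (its two modal levels), `age_band` (ages 12-15
#' versus 16-18), and `ethnicity` (two levels). Persons with a missing group
#' label are excluded per grouping; groupings without variation are skipped
#' with a warning.
#'
#' @param responses A [response_matrix()].
#' @param covariates Data frame with a `person_id` column plus the grouping
#'   columns (`gender`, `age` in years, `ethnicity` as available).
#' @param groupings Character vector naming which screens to run.
#' @param ... Passed to [uniform_dif()].
#' @return Named list of `dif_result` data frames.
#' @export
dif_screen <- function(responses, covariates,
                       groupings = c("gender", "age_band", "ethnicity"), ...) {
  stopifnot(is.data.frame(covariates), "person_id" %in% names(covariates))
  cov <- covariates[match(responses$person_ids, covariates$person_id), ]
  shared_cal <- estimate_jmle(responses)
  out <- list()
  for (grp in groupings) {
    g <- switch(grp,
      gender = two_modal_levels(cov$gender),
      age_band = age_band(cov$age),
      ethnicity = two_modal_levels(cov$ethnicity),
      stop("unknown grouping: ", grp, call. = FALSE))
    if (nlevels(droplevels(factor(g))) < 2L) {
      warning("grouping '", grp, "' has no variation; skipped")
      next
    }
    out[[grp]] <- uniform_dif(responses, g, calibration = shared_cal, ...)
  }
  out
}

# keep the two most frequent levels, everything else NA
two_modal_levels <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  keep <- names(tab)[seq_len(min(2L, length(tab)))]
  factor(ifelse(x %in% keep, as.character(x), NA), levels = keep)
}

#' Age bands for invariance testing
#'
#' Partitions integer ages into the two bands used for DIF when single-year
#' samples are too small: 12-15 years versus 16-18 years.
#'
#' @param age Integer ages in years.
#' @return Factor with levels `"12-15"` and `"16-18"`; ages outside 12-18
#'   are `NA`.
#' @export
age_band <- function(age) {
  band <- ifelse(is.na(age) | age < 12 | age > 18, NA,
                 ifelse(age <= 15, "12-15", "16-18"))
  factor(band, levels = c("12-15", "16-18"))
}

#' Mantel-Haenszel DIF cross-check
#'
#' Classical Mantel-Haenszel uniform-DIF test for dichotomous items,
#' stratifying on the raw total score. Provided as an independent
#' cross-check of the anchored-calibration contrast; it is not the primary
#' flag source.
#'
#' @param responses A [response_matrix()] of dichotomous items.
#' @param grouping Two-level factor aligned with persons.
#' @return Data frame with `item_id`, `mh_or` (common odds ratio),
#'   `mh_log_or`, `p_value`.
#' @export
mantel_haenszel_dif <- function(responses, grouping) {
  stopifnot(all(max_scores(responses$specs) == 1L))
  g <- droplevels(factor(grouping))
  stopifnot(nlevels(g) == 2L)
  X <- responses$scores
  tot <- rowSums(X, na.rm = TRUE)
  res <- lapply(seq_len(ncol(X)), function(j) {
    strat <- tot - ifelse(is.na(X[, j]), 0L, X[, j])  # rest score
    ok <- !is.na(X[, j]) & !is.na(g)
    tab <- table(factor(X[ok, j], levels = 0:1), g[ok], strat[ok])
    use <- apply(tab, 3L, function(s) all(colSums(s) > 0))
    tab <- tab[, , use, drop = FALSE]
    if (dim(tab)[3L] < 1L)
      return(data.frame(item_id = colnames(X)[j], mh_or = NA_real_,
                        mh_log_or = NA_real_, p_value = NA_real_))
    mh <- tryCatch(stats::mantelhaen.test(tab, exact = FALSE, correct = FALSE),
                   error = function(e) NULL)
    if (is.null(mh))
      return(data.frame(item_id = colnames(X)[j], mh_or = NA_real_,
                        mh_log_or = NA_real_, p_value = NA_real_))
    data.frame(item_id = colnames(X)[j],
               mh_or = unname(mh$estimate), mh_log_or = log(unname(mh$estimate)),
               p_value = mh$p.value)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
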