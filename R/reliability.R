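#' Item-separation reliability
#'
#' Proportion of the observed item-difficulty variance not attributable to
#' estimation error: `(observed variance - mean squared SE) / observed
#' variance`, floored at 0. Values near 1 indicate the item bank spans a
#' difficulty range wide relative to its calibration error. Population
#' (divide-by-n) variance convention.
#'
#' @param calibration A `rasch_calibration`.
#' @return Reliability in \[0, 1).
#' @export
item_separation_reliability <- function(calibration) {
  b <- calibration$item_difficulty
  se <- calibration$item_se
  if (length(b) < 2L) stop("need at least 2 calibrated items", call. = FALSE)
  v <- mean((b - mean(b))^2)
  if (v == 0) {
    warning("zero variance in item difficulties; reliability is 0")
    return(0)
  }
  max(0, (v - mean(se^2)) / v)
}

#' Person-separation reliability
#'
#' Same variance decomposition as [item_separation_reliability()] applied to
#' person measures. Reported as a secondary statistic: with a skewed sample
#' the strata-based sample-independent reliability is the primary
#' reliability summary.
#'
#' @param calibration A `rasch_calibration`.
#' @return Reliability in \[0, 1).
#' @export
person_separation_reliability <- function(calibration) {
  th <- calibration$person_measure[!is.na(calibration$person_measure)]
  se <- calibration$person_se[!is.na(calibration$person_se)]
  if (length(th) < 2L) stop("need at least 2 measured persons", call. = FALSE)
  v <- mean((th - mean(th))^2)
  if (v == 0) return(0)
  max(0, (v - mean(se^2)) / v)
}

#' KR-20 / coefficient alpha internal consistency
#'
#' Kuder-Richardson formula 20, `(k/(k-1)) (1 - sum(p q) / var(total))`,
#' generalized to the item-variance (coefficient alpha) form so polytomous
#' items are handled identically; on dichotomous data the two coincide
#' exactly. Computed on complete cases with population (divide-by-n)
#' variances.
#'
#' @param responses A [response_matrix()].
#' @return The alpha coefficient (at most 1; can be negative for
#'   pathological data).
#' @export
kr20 <- function(responses) {
  X <- responses$scores
  X <- X[stats::complete.cases(X), , drop = FALSE]
  k <- ncol(X)
  if (k < 2L) stop("need at least 2 items", call. = FALSE)
  if (nrow(X) < 2L) stop("need at least 2 complete cases", call. = FALSE)
  pvar <- function(v) mean((v - mean(v))^2)
  tot_var <- pvar(rowSums(X))
  if (tot_var == 0) stop("zero total-score variance", call. = FALSE)
  item_var <- sum(apply(X, 2L, pvar))
  (k / (k - 1)) * (1 - item_var / tot_var)
}

#' Wright sample-independent reliability
#'
#' Reliability implied by the number of statistically distinct performance
#' levels a test separates: `n^2 / (1 + n^2)` for `n` levels. Unlike
#' sample-dependent person reliability it does not assume a symmetric
#' ability distribution.
#'
#' @param n_levels Positive integer count of performance strata.
#' @return Reliability in \[0.5, 1).
#' @export
#' @examples
#' sample_independent_reliability(2)  # 0.8
#' sample_independent_reliability(4)  # 16/17
sample_independent_reliability <- function(n_levels) {
  if (length(n_levels) != 1L || is.na(n_levels) || n_levels < 1 ||
      n_levels != as.integer(n_levels))
    stop("n_levels must be a positive integer", call. = FALSE)
  n_levels^2 / (1 + n_levels^2)
}

#' Wright strata walk: performance levels and raw-score cutoffs
#'
#' Determines how many statistically distinguishable performance levels the
#' raw-score range supports. Standard errors of the score-to-measure table
#' are first inflated by `inflation` (10% by default); walking up from the
#' lowest attainable raw score, a new level begins at the first score whose
#' measure exceeds the current level's first (anchor) score by at least
#' twice the joint inflated standard error of the two. Cutoffs are reported
#' as inclusive raw-score ranges, and the sample-independent reliability is
#' `n^2/(1+n^2)` for the resulting level count.
#'
#' @param score_table Data frame from [score_to_measure_table()] (columns
#'   `raw_score`, `measure`, `se`), measures non-decreasing and SEs
#'   positive.
#' @param inflation Multiplicative SE inflation factor (default 1.10).
#' @param labels Optional level labels, lowest first; defaults to the
#'   Emerging / Expanding / (Lower/Upper) Bridging naming for 2-4 levels and
#'   `Level k` otherwise.
#' @return List of class `strata_report`: `score_table` (with `se_inflated`
#'   column), `n_levels`, `level_cutoffs` (label, min/max raw score),
#'   `anchors` (raw scores where each level starts),
#'   `sample_independent_reliability`, `se_inflation_factor`.
#' @export
wright_strata <- function(score_table, inflation = 1.10, labels = NULL) {
  st <- score_table
  stopifnot(all(c("raw_score", "measure", "se") %in% names(st)))
  st <- st[order(st$raw_score), ]
  if (any(diff(st$measure) < 0)) stop("measures must be non-decreasing in raw score",
                                      call. = FALSE)
  if (any(st$se <= 0)) stop("standard errors must be positive", call. = FALSE)
  st$se_inflated <- st$se * inflation
  anchor <- 1L
  anchors <- 1L
  level_of <- integer(nrow(st))
  level_of[1L] <- 1L
  for (i in seq_len(nrow(st))[-1L]) {
    gap <- st$measure[i] - st$measure[anchor]
    joint <- sqrt(st$se_inflated[anchor]^2 + st$se_inflated[i]^2)
    if (gap >= 2 * joint) {
      anchor <- i
      anchors <- c(anchors, i)
    }
    level_of[i] <- length(anchors)
  }
  n_levels <- length(anchors)
  if (is.null(labels)) labels <- default_level_labels(n_levels)
  stopifnot(length(labels) == n_levels)
  cut <- data.frame(
    label = labels,
    min_score = st$raw_score[anchors],
    max_score = st$raw_score[c(anchors[-1L] - 1L, nrow(st))])
  structure(list(score_table = st, n_levels = n_levels,
                 level_cutoffs = cut,
                 anchors = st$raw_score[anchors],
                 sample_independent_reliability =
                   sample_independent_reliability(n_levels),
                 se_inflation_factor = inflation),
            class = "strata_report")
}

default_level_labels <- function(n) {
  switch(as.character(n),
         "1" = "Emerging",
         "2" = c("Emerging", "Expanding"),
         "3" = c("Emerging", "Expanding", "Bridging"),
         "4" = c("Emerging", "Expanding", "Lower Bridging", "Upper Bridging"),
         paste("Level", seq_len(n)))
}

#' @export
print.strata_report <- function(x, ...) {
  cat(sprintf("<strata_report> %d level(s), sample-independent reliability %.2f\n",
              x$n_levels, x$sample_independent_reliability))
  for (i in seq_len(nrow(x$level_cutoffs)))
    cat(sprintf("  %s: scores %d-%d\n", x$level_cutoffs$label[i],
                x$level_cutoffs$min_score[i], x$level_cutoffs$max_score[i]))
  invisible(x)
}

#' Published cutoff presets for the adolescent health literacy assessments
#'
#' The published raw-score bands of the functional (FHL), interactive (IHL)
#' and critical (CHL) health literacy assessments and their 23-item
#' composite, plus the younger-group (ages 12-15) composite variant whose
#' Lower/Upper Bridging boundary differs. Shipped as a versioned JSON
#' resource.
#'
#' @return Named list of cutoff data frames (columns `label`, `min_score`,
#'   `max_score`), each carrying a `max_score` attribute with the test's
#'   score ceiling.
#' @export
#' @examples
#' categorize(5, hl_cutoff_presets()$fhl)  # "Expanding"
hl_cutoff_presets <- function() {
  path <- system.file("extdata", "hl_cutoffs.json", package = "raschval")
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  out <- lapply(raw$presets, function(p) {
    df <- data.frame(label = p$levels$label,
                     min_score = p$levels$min_score,
                     max_score = p$levels$max_score)
    attr(df, "max_score") <- p$max_score
    df
  })
  out
}

#' Map raw scores to performance levels
#'
#' @param score Integer raw score(s) within the attainable range.
#' @param cutoffs Cutoff data frame (`label`, `min_score`, `max_score`) from
#'   [wright_strata()] or [hl_cutoff_presets()]; ranges must partition the
#'   score range with inclusive boundaries.
#' @return Character vector of level labels.
#' @export
categorize <- function(score, cutoffs) {
  stopifnot(all(c("label", "min_score", "max_score") %in% names(cutoffs)))
  lo <- min(cutoffs$min_score); hi <- max(cutoffs$max_score)
  if (any(is.na(score)) || any(score < lo | score > hi))
    stop("score outside the attainable range ", lo, "-", hi, call. = FALSE)
  idx <- vapply(score, function(s)
    which(s >= cutoffs$min_score & s <= cutoffs$max_score), integer(1))
  cutoffs$label[idx]
}
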