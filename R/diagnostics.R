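#' Standardized response residuals
#'
#' `z = (x - E) / sqrt(W)` for every observed response, where `E` and `W`
#' are the model-expected score and score variance at the person's measure.
#' Missing responses propagate as `NA`.
#'
#' @param calibration A [estimate_jmle()] calibration (or
#'   [manual_calibration()]).
#' @param responses The matching [response_matrix()].
#' @return Numeric matrix (measured persons x calibrated items) of
#'   standardized residuals.
#' @export
standardized_residuals <- function(calibration, responses) {
  al <- align_calibration(calibration, responses)
  mom <- calibration_moments(calibration, al$theta)
  Z <- (al$X - mom$E) / sqrt(mom$W)
  rownames(Z) <- al$person_ids
  Z
}

# per-cell fourth central moment E[(x-E)^4], needed for mean-square variances
residual_kurtosis <- function(calibration, theta) {
  ids <- names(calibration$item_difficulty)
  C <- matrix(NA_real_, length(theta), length(ids), dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    d <- item_steps(calibration$item_difficulty[j], calibration$thresholds[[j]])
    P <- pcm_prob_matrix(theta, d)
    kk <- 0:length(d)
    E <- drop(P %*% kk)
    C[, j] <- rowSums(P * (outer(rep(1, length(theta)), kk) - E)^4)
  }
  C
}

# shared mean-square machinery over one margin (2 = items, 1 = persons)
mean_square_fit <- function(calibration, responses, margin) {
  al <- align_calibration(calibration, responses)
  mom <- calibration_moments(calibration, al$theta)
  obs <- !is.na(al$X)
  R <- al$X - mom$E                       # score residuals
  W <- mom$W; W[!obs] <- NA
  Z2 <- R^2 / W
  C <- residual_kurtosis(calibration, al$theta); C[!obs] <- NA

  n_used <- apply(obs, margin, sum)
  sumW <- apply(W, margin, sum, na.rm = TRUE)
  outfit <- apply(Z2, margin, mean, na.rm = TRUE)
  infit <- apply(R^2, margin, sum, na.rm = TRUE) / sumW
  # mean-square variances, standard Rasch-software convention
  q2_out <- apply(C / W^2, margin, sum, na.rm = TRUE) / n_used^2 - 1 / n_used
  q2_in <- apply(C - W^2, margin, sum, na.rm = TRUE) / sumW^2
  list(outfit = outfit, infit = infit,
       outfit_zstd = wilson_hilferty(outfit, q2_out),
       infit_zstd = wilson_hilferty(infit, q2_in),
       n_used = n_used)
}

# Wilson-Hilferty cube-root standardization of a mean-square with variance q2
wilson_hilferty <- function(mnsq, q2) {
  q <- sqrt(pmax(q2, 1e-12))
  (mnsq^(1 / 3) - 1) * (3 / q) + q / 3
}

#' Item fit statistics
#'
#' Outfit is the unweighted mean of squared standardized residuals over the
#' persons who took the item; infit is the information-weighted version
#' (`sum(W z^2) / sum(W)`). Both have expectation 1 under the model. The
#' standardized forms (`_zstd`) use the Wilson-Hilferty cube-root
#' transformation with the model variance of the mean-square, so their sign
#' tracks the direction of departure from 1. The point-measure correlation
#' (`pmc`) is the Pearson correlation between item scores and person
#' measures.
#'
#' @inheritParams standardized_residuals
#' @return A data frame of class `fit_report` with one row per item:
#'   `item_id`, `n_used`, `infit_mnsq`, `outfit_mnsq`, `infit_zstd`,
#'   `outfit_zstd`, `pmc`.
#' @export
item_fit <- function(calibration, responses) {
  fs <- mean_square_fit(calibration, responses, margin = 2L)
  if (any(fs$n_used < 2L))
    stop("every item needs at least 2 non-missing responses", call. = FALSE)
  out <- data.frame(item_id = names(calibration$item_difficulty),
                    n_used = fs$n_used,
                    infit_mnsq = fs$infit, outfit_mnsq = fs$outfit,
                    infit_zstd = fs$infit_zstd, outfit_zstd = fs$outfit_zstd,
                    pmc = point_measure_correlation(calibration, responses)$pmc,
                    row.names = NULL)
  class(out) <- c("fit_report", "data.frame")
  attr(out, "unit") <- "item"
  out
}

#' Person fit statistics
#'
#' Mirrors [item_fit()] across rows: outfit/infit mean-squares and their
#' standardized forms per measured person. Persons with fewer than 2
#' responses are excluded with a warning.
#'
#' @inheritParams standardized_residuals
#' @return A `fit_report` data frame with one row per measured person.
#' @export
person_fit <- function(calibration, responses) {
  fs <- mean_square_fit(calibration, responses, margin = 1L)
  al <- align_calibration(calibration, responses)
  keep <- fs$n_used >= 2L
  if (any(!keep))
    warning(sum(!keep), " person(s) with fewer than 2 responses excluded from person fit")
  out <- data.frame(person_id = al$person_ids[keep],
                    n_used = fs$n_used[keep],
                    infit_mnsq = fs$infit[keep], outfit_mnsq = fs$outfit[keep],
                    infit_zstd = fs$infit_zstd[keep],
                    outfit_zstd = fs$outfit_zstd[keep],
                    row.names = NULL)
  class(out) <- c("fit_report", "data.frame")
  attr(out, "unit") <- "person"
  out
}

#' Point-measure correlations
#'
#' Pearson correlation of each item's observed scores with the person
#' measures, the polarity check of the scale: negative values indicate an
#' item keyed against the rest of the test.
#'
#' @inheritParams standardized_residuals
#' @return Data frame with `item_id`, `pmc`, and `defined` (`FALSE` when the
#'   item or measure variance is zero, in which case `pmc` is `NA`).
#' @export
point_measure_correlation <- function(calibration, responses) {
  al <- align_calibration(calibration, responses)
  pmc <- vapply(seq_len(ncol(al$X)), function(j) {
    o <- !is.na(al$X[, j])
    x <- al$X[o, j]; th <- al$theta[o]
    if (stats::sd(x) == 0 || stats::sd(th) == 0) return(NA_real_)
    stats::cor(x, th)
  }, numeric(1))
  data.frame(item_id = al$item_ids, pmc = pmc, defined = !is.na(pmc),
             row.names = NULL)
}

#' First contrast of the residual principal components
#'
#' Principal components analysis of the correlation matrix of item-wise
#' standardized residuals. Under unidimensionality the residuals are noise
#' and the largest eigenvalue stays below 2 items-worth of variance; a first
#' contrast of 2 or more signals a secondary dimension.
#'
#' @param residuals Standardized residual matrix from
#'   [standardized_residuals()] (persons x items).
#' @return List with `first_contrast_eigenvalue`, `unidimensional`
#'   (eigenvalue < 2), `eigenvalues` (all, in item units) and
#'   `rank_deficient`.
#' @export
residual_pca_first_contrast <- function(residuals) {
  if (ncol(residuals) < 3L) stop("need at least 3 items", call. = FALSE)
  R <- stats::cor(residuals, use = "pairwise.complete.obs")
  rank_def <- anyNA(R)
  if (rank_def) {
    warning("rank-deficient residual correlations; undefined entries set to 0")
    R[is.na(R)] <- 0
    diag(R) <- 1
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  list(first_contrast_eigenvalue = ev[1L],
       unidimensional = ev[1L] < 2,
       eigenvalues = ev,
       rank_deficient = rank_def)
}

#' Local independence screen
#'
#' Largest pairwise correlations among item standardized residuals. Item
#' pairs with residual correlations below 0.50 in absolute value are treated
#' as locally independent; both signed extremes are reported.
#'
#' @inheritParams residual_pca_first_contrast
#' @param threshold Dependence threshold on |r| (default 0.50).
#' @return List with `max_abs_correlation`, `max_correlation`,
#'   `min_correlation`, `locally_independent`, `worst_pair` (item ids) and
#'   the full `correlations` matrix.
#' @export
local_independence <- function(residuals, threshold = 0.50) {
  R <- stats::cor(residuals, use = "pairwise.complete.obs")
  D <- R; diag(D) <- NA
  mx <- max(D, na.rm = TRUE); mn <- min(D, na.rm = TRUE)
  mabs <- max(abs(D), na.rm = TRUE)
  w <- which(abs(D) == mabs, arr.ind = TRUE)[1L, ]
  list(max_abs_correlation = mabs,
       max_correlation = mx, min_correlation = mn,
       locally_independent = mabs < threshold,
       worst_pair = colnames(R)[c(w[["row"]], w[["col"]])],
       correlations = R)
}

#' Test characteristic curve monotonicity check
#'
#' Evaluates the test characteristic curve (expected raw total over a theta
#' grid) and verifies it ascends strictly. For a proper Rasch/PCM calibration
#' this holds analytically; the check guards against implementation and
#' serialization faults.
#'
#' @param calibration A `rasch_calibration`.
#' @param grid Theta grid (default 201 points over \[-6, 6\]).
#' @return List with `monotone` (logical), `theta` and `tcc` (the sampled
#'   curve).
#' @export
check_tcc_monotonicity <- function(calibration, grid = seq(-6, 6, length.out = 201L)) {
  tcc <- tcc_value(calibration, grid)
  list(monotone = all(diff(tcc) > 0), theta = grid, tcc = tcc)
}

#' Run all three Rasch assumption checks
#'
#' Convenience wrapper combining [residual_pca_first_contrast()],
#' [local_independence()] and [check_tcc_monotonicity()] into a single
#' dimensionality report.
#'
#' @inheritParams standardized_residuals
#' @return List of class `dimensionality_report` with fields
#'   `first_contrast_eigenvalue`, `unidimensional`,
#'   `max_abs_residual_correlation`, `max_residual_correlation`,
#'   `min_residual_correlation`, `locally_independent`, `tcc_monotone`.
#' @export
assumption_checks <- function(calibration, responses) {
  Z <- standardized_residuals(calibration, responses)
  pca <- residual_pca_first_contrast(Z)
  li <- local_independence(Z)
  tcc <- check_tcc_monotonicity(calibration)
  structure(list(
    first_contrast_eigenvalue = pca$first_contrast_eigenvalue,
    unidimensional = pca$unidimensional,
    max_abs_residual_correlation = li$max_abs_correlation,
    max_residual_correlation = li$max_correlation,
    min_residual_correlation = li$min_correlation,
    locally_independent = li$locally_independent,
    tcc_monotone = tcc$monotone
  ), class = "dimensionality_report")
}

#' @export
print.dimensionality_report <- function(x, ...) {
  cat("<dimensionality_report>\n")
  cat(sprintf("  first contrast eigenvalue: %.2f (%s)\n",
              x$first_contrast_eigenvalue,
              if (x$unidimensional) "unidimensional" else "secondary dimension"))
  cat(sprintf("  max |residual correlation|: %.2f (%s)\n",
              x$max_abs_residual_correlation,
              if (x$locally_independent) "independent" else "dependent pair"))
  cat(sprintf("  TCC monotone: %s\n", x$tcc_monotone))
  invisible(x)
}
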