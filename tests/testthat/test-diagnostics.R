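test_that("standardized residuals match hand computations", {
  specs <- test_spec(lapply(c("A", "B"), item_spec))
  cal <- manual_calibration(specs, c(0, 0), person_measure = c(0, log(3)),
                            person_ids = c("p1", "p2"))
  X <- rbind(p1 = c(1L, 0L), p2 = c(0L, 1L))
  rmx <- response_matrix(X, specs, person_ids = rownames(X))
  Z <- standardized_residuals(cal, rmx)
  expect_equal(Z["p1", "A"], 1)                       # (1 - 0.5)/0.5
  expect_equal(Z["p1", "B"], -1)
  expect_equal(Z["p2", "A"], -sqrt(3), tolerance = 1e-12) # (0 - .75)/sqrt(.1875)
  # missing propagates
  X[1, 2] <- NA
  Z2 <- standardized_residuals(cal, response_matrix(X, specs, rownames(X)))
  expect_true(is.na(Z2["p1", "B"]))
})

test_that("outfit is exactly 1 when every residual is +/-1", {
  specs <- test_spec(lapply(sprintf("Q%d", 1:4), item_spec))
  cal <- manual_calibration(specs, rep(0, 4), person_measure = rep(0, 6))
  set.seed(41)
  X <- matrix(rbinom(24, 1, 0.5), 6, 4)   # any data: all z are +/-1 at theta=b
  rmx <- response_matrix(X, specs)
  fit <- item_fit(cal, rmx)
  expect_equal(fit$outfit_mnsq, rep(1, 4))
  expect_equal(fit$infit_mnsq, rep(1, 4))
})

test_that("item fit is centered near 1 under the model and flags injected noise", {
  set.seed(42)
  theta <- rnorm(500)
  b <- runif(20, -2, 2)
  rmx <- dich_responses(theta, b)
  cal <- estimate_jmle(rmx)
  fit <- item_fit(cal, rmx)
  expect_gt(mean(fit$outfit_mnsq), 0.9)
  expect_lt(mean(fit$outfit_mnsq), 1.1)
  expect_true(all(fit$outfit_mnsq >= 0))
  expect_true(all(abs(fit$pmc) <= 1))

  # replace one item with fair coin flips independent of ability
  X <- rmx$scores
  X[, 7] <- rbinom(500, 1, 0.5)
  rmx2 <- response_matrix(X, rmx$specs)
  cal2 <- estimate_jmle(rmx2)
  fit2 <- item_fit(cal2, rmx2)
  expect_equal(which.max(fit2$outfit_mnsq), 7L)
  expect_gt(fit2$outfit_zstd[7], 2)
})

test_that("injected random units rank first by outfit in nearly all replicates", {
  set.seed(43)
  hits_item <- hits_person <- logical(100)
  for (r in 1:100) {
    # item injection: many persons per item keep the null outfits tight
    X <- draw_dich(rnorm(400), runif(15, -2, 2))
    X[, 3] <- rbinom(400, 1, 0.5)          # random item
    rmx <- response_matrix(X, test_spec(lapply(colnames(X), item_spec)))
    cal <- estimate_jmle(rmx)
    hits_item[r] <- which.max(item_fit(cal, rmx)$outfit_mnsq) == 3L
    # person injection: a long test with a targeted cohort, so one random
    # responder stands above the null persons' outfit sampling noise
    Xp <- draw_dich(rnorm(25, 0, 0.5), seq(-2.2, 2.2, length.out = 120))
    Xp[9, ] <- rbinom(120, 1, 0.5)         # random responder
    rmxp <- response_matrix(Xp, test_spec(lapply(colnames(Xp), item_spec)))
    calp <- estimate_jmle(rmxp)
    pf <- person_fit(calp, rmxp)
    hits_person[r] <- pf$person_id[which.max(pf$outfit_mnsq)] == "P9"
  }
  expect_gte(mean(hits_item), 0.95)
  expect_gte(mean(hits_person), 0.95)
})

test_that("fit statistics are invariant to person ordering", {
  set.seed(44)
  rmx <- dich_responses(rnorm(150), c(-1, 0, 1, 0.5, -0.5))
  cal <- estimate_jmle(rmx)
  fit <- item_fit(cal, rmx)
  pp <- sample(150)
  rmx2 <- subset_responses(rmx, persons = pp)
  fit2 <- item_fit(cal, rmx2)
  expect_equal(fit2$outfit_mnsq, fit$outfit_mnsq, tolerance = 1e-12)
  expect_equal(fit2$infit_zstd, fit$infit_zstd, tolerance = 1e-12)
})

test_that("a Guttman-consistent person overfits; degenerate persons are excluded", {
  specs <- test_spec(lapply(sprintf("Q%d", 1:6), item_spec))
  cal <- manual_calibration(specs, seq(-2.5, 2.5, length.out = 6),
                            person_measure = c(0, 0.2),
                            person_ids = c("g", "few"))
  X <- rbind(g = c(1L, 1L, 1L, 0L, 0L, 0L),
             few = c(1L, rep(NA, 5L)))
  rmx <- response_matrix(X, specs, rownames(X))
  expect_warning(pf <- person_fit(cal, rmx), "fewer than 2")
  expect_equal(pf$person_id, "g")
  expect_lt(pf$outfit_mnsq, 1)
})

test_that("point-measure correlation equals the direct Pearson correlation", {
  set.seed(45)
  rmx <- dich_responses(rnorm(100), c(-0.8, 0.2, 1))
  cal <- estimate_jmle(rmx)
  pmc <- point_measure_correlation(cal, rmx)
  th <- cal$person_measure[!is.na(cal$person_measure)]
  X <- rmx$scores[names(th), ]
  for (j in 1:3)
    expect_equal(pmc$pmc[j], cor(X[, j], th), tolerance = 1e-12)
  # affine function of the measure correlates 1; reverse key flips the sign
  specs <- test_spec(list(item_spec("up", "partial_credit", 3),
                          item_spec("down", "partial_credit", 3)))
  th2 <- c(-1.5, -0.5, 0.5, 1.5)
  cal2 <- manual_calibration(specs, c(0, 0), person_measure = th2)
  X2 <- cbind(up = 0:3, down = 3:0)
  pmc2 <- point_measure_correlation(cal2, response_matrix(X2, specs))
  expect_equal(pmc2$pmc, c(1, -1))
})

test_that("zero-variance items are flagged as undefined pmc", {
  specs <- test_spec(lapply(c("a", "b", "c"), item_spec))
  cal <- manual_calibration(specs, rep(0, 3), person_measure = c(-1, 0, 1))
  X <- cbind(a = c(0L, 1L, 1L), b = c(1L, 1L, 1L), c = c(0L, 1L, 0L))
  pmc <- point_measure_correlation(cal, response_matrix(X, specs))
  expect_false(pmc$defined[2])
  expect_true(is.na(pmc$pmc[2]))
})

test_that("residual PCA separates unidimensional noise from a planted dimension", {
  set.seed(46)
  theta <- rnorm(500)
  b <- runif(20, -1.5, 1.5)
  rmx <- dich_responses(theta, b)
  cal <- estimate_jmle(rmx)
  pca <- residual_pca_first_contrast(standardized_residuals(cal, rmx))
  expect_lt(pca$first_contrast_eigenvalue, 2)
  expect_true(pca$unidimensional)

  # second dimension injected into 8 of the 20 items
  theta2 <- rnorm(500)
  X <- draw_dich(theta, b)
  X[, 1:8] <- draw_dich(theta + 1.4 * theta2, b[1:8])
  rmx2 <- response_matrix(X, rmx$specs)
  cal2 <- estimate_jmle(rmx2)
  pca2 <- residual_pca_first_contrast(standardized_residuals(cal2, rmx2))
  expect_gte(pca2$first_contrast_eigenvalue, 2)
  expect_false(pca2$unidimensional)
})

test_that("residual PCA agrees with a direct eigendecomposition oracle", {
  set.seed(47)
  Z <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, letters[1:5]))
  pca <- residual_pca_first_contrast(Z)
  expect_equal(pca$first_contrast_eigenvalue,
               max(eigen(cor(Z), symmetric = TRUE)$values), tolerance = 1e-8)
  # orthogonalized (decorrelated) residuals: identity correlation, eigenvalues 1
  Q <- prcomp(matrix(rnorm(30), 10, 3))$x
  expect_equal(residual_pca_first_contrast(Q)$first_contrast_eigenvalue, 1,
               tolerance = 1e-8)
})

test_that("local independence flags duplicated items and matches direct correlations", {
  set.seed(48)
  theta <- rnorm(400)
  X <- draw_dich(theta, c(-1, 0, 1, 0.5))
  X <- cbind(X, I05 = X[, 2L])
  rmx <- response_matrix(X, test_spec(lapply(colnames(X), item_spec)))
  cal <- estimate_jmle(rmx)
  Z <- standardized_residuals(cal, rmx)
  li <- local_independence(Z)
  expect_false(li$locally_independent)
  expect_equal(li$max_abs_correlation, 1, tolerance = 1e-9)
  expect_setequal(li$worst_pair, c("I02", "I05"))
  expect_equal(li$max_correlation, max(cor(Z)[upper.tri(cor(Z))]),
               tolerance = 1e-12)

  # null cohort: residual correlations stay far below the 0.50 threshold
  rmx0 <- dich_responses(theta, runif(20, -1.5, 1.5))
  cal0 <- estimate_jmle(rmx0)
  li0 <- local_independence(standardized_residuals(cal0, rmx0))
  expect_true(li0$locally_independent)
  expect_lt(li0$max_abs_correlation, 0.5)
})

test_that("test characteristic curves ascend with correct limits", {
  set.seed(49)
  co <- generate_cohort(cohort_config(seed = 901))
  cal <- estimate_jmle(co$responses)
  chk <- check_tcc_monotonicity(cal)
  expect_true(chk$monotone)
  expect_length(chk$tcc, 201L)
  r_max <- sum(vapply(cal$specs, `[[`, integer(1), "max_score"))
  grid <- seq(-30, 30, length.out = 301)
  wide <- check_tcc_monotonicity(cal, grid = grid)
  expect_lt(wide$tcc[1], 0.01)
  expect_gt(wide$tcc[301], r_max - 0.01)
  # single dichotomous item: TCC equals its ICC
  cal1 <- manual_calibration(test_spec(list(item_spec("a"), item_spec("b"))),
                             c(0.7, -0.7), person_measure = 0)
  th <- seq(-3, 3, length.out = 201)
  expect_equal(check_tcc_monotonicity(cal1, grid = th)$tcc,
               dichotomous_prob(th, 0.7) + dichotomous_prob(th, -0.7),
               tolerance = 1e-12)
})

test_that("assumption checks bundle the three screens", {
  set.seed(50)
  rmx <- dich_responses(rnorm(300), runif(10, -1, 1))
  cal <- estimate_jmle(rmx)
  ch <- assumption_checks(cal, rmx)
  expect_true(ch$unidimensional && ch$locally_independent && ch$tcc_monotone)
  expect_lt(ch$min_residual_correlation, ch$max_residual_correlation)
})
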