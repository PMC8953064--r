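test_that("item-separation reliability matches hand computations", {
  specs <- test_spec(lapply(c("a", "b", "c"), item_spec))
  cal <- manual_calibration(specs, c(-1, 0, 1), person_measure = numeric(0),
                            person_ids = character(0))
  # population variance 2/3, mean squared SE 0.25 -> 0.625
  cal$item_se[] <- 0.5
  expect_equal(item_separation_reliability(cal), 0.625)
  cal$item_se[] <- 1e-6                      # no error variance
  expect_gt(item_separation_reliability(cal), 0.999)
  cal$item_difficulty[] <- 0                 # degenerate spread
  expect_warning(r0 <- item_separation_reliability(cal), "zero variance")
  expect_equal(r0, 0)
})

test_that("separation reliabilities are high for a well-spread calibrated bank", {
  co <- generate_cohort(cohort_config(seed = 801))
  cal <- estimate_jmle(co$responses)
  expect_gt(item_separation_reliability(cal), 0.9)
  p <- person_separation_reliability(cal)
  expect_true(p > 0 && p < 1)
})

test_that("KR-20 equals its classical p*q hand computation and coefficient alpha", {
  # worked 4-person fixture: p = (3/4, 2/4, 1/4), sum pq = 0.625,
  # population total variance 1.25 -> (3/2)(1 - 0.5) = 0.75
  X <- rbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, 1), c(0, 0, 0))
  rmx <- response_matrix(X, test_spec(lapply(c("a", "b", "c"), item_spec)))
  expect_equal(kr20(rmx), 0.75, tolerance = 1e-12)
  # generic dichotomous data: agreement with an independently coded KR-20
  set.seed(802)
  rmx2 <- dich_responses(rnorm(150), runif(8, -1, 1))
  p <- colMeans(rmx2$scores)
  tot <- rowSums(rmx2$scores)
  kr20_pq <- (8 / 7) * (1 - sum(p * (1 - p)) / mean((tot - mean(tot))^2))
  expect_equal(kr20(rmx2), kr20_pq, tolerance = 1e-12)
})

test_that("KR-20 hits its structural benchmarks", {
  set.seed(803)
  x <- rbinom(50, 1, 0.6)
  dup <- response_matrix(cbind(a = x, b = x, c = x, d = x),
                         test_spec(lapply(letters[1:4], item_spec)))
  expect_equal(kr20(dup), 1, tolerance = 1e-12)   # k identical columns
  coin <- response_matrix(matrix(rbinom(4000 * 10, 1, 0.5), 4000, 10,
                                 dimnames = list(NULL, sprintf("c%d", 1:10))),
                          test_spec(lapply(sprintf("c%d", 1:10), item_spec)))
  expect_lt(abs(kr20(coin)), 0.1)                 # independent items -> ~0
  solo <- response_matrix(cbind(a = x, b = 1L - x),
                          test_spec(lapply(c("a", "b"), item_spec)))
  expect_error(kr20(solo), "variance")            # zero total variance
})

test_that("sample-independent reliability follows n^2/(1+n^2)", {
  expect_equal(sample_independent_reliability(1), 0.5)
  expect_equal(sample_independent_reliability(2), 0.8)
  expect_equal(sample_independent_reliability(4), 16 / 17)
  vals <- vapply(1:8, sample_independent_reliability, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0.5 & vals < 1))
  expect_error(sample_independent_reliability(0), "positive")
  expect_error(sample_independent_reliability(2.5), "integer")
})

test_that("the strata walk reproduces a hand-executed example", {
  # 7 scores, measures -3..3, SE 0.3 -> inflated 0.33; the gap criterion is
  # 2*sqrt(2*0.33^2) = 0.933, so every 1-logit step starts a new level
  st <- data.frame(raw_score = 0:6, measure = -3:3, se = 0.3)
  rep7 <- wright_strata(st)
  expect_equal(rep7$n_levels, 7L)
  expect_equal(rep7$sample_independent_reliability, 49 / 50)
  expect_equal(rep7$level_cutoffs$min_score, 0:6)
  expect_equal(rep7$score_table$se_inflated, rep(0.33, 7))

  # same table with SE 0.6: joint gap 2*sqrt(2*0.66^2) = 1.87 -> every
  # second score opens a level
  rep3 <- wright_strata(data.frame(raw_score = 0:6, measure = -3:3, se = 0.6))
  expect_equal(rep3$n_levels, 4L)
  expect_equal(rep3$anchors, c(0, 2, 4, 6))
})

test_that("degenerate and invalid score tables are handled", {
  flat <- data.frame(raw_score = 0:5, measure = rep(0, 6), se = 0.4)
  expect_equal(wright_strata(flat)$n_levels, 1L)
  expect_equal(wright_strata(flat)$sample_independent_reliability, 0.5)
  bad <- data.frame(raw_score = 0:2, measure = c(0, 1, 0.5), se = 0.4)
  expect_error(wright_strata(bad), "non-decreasing")
  negse <- data.frame(raw_score = 0:2, measure = 0:2, se = c(0.4, 0, 0.4))
  expect_error(wright_strata(negse), "positive")
})

test_that("levels never decrease as standard errors shrink", {
  st <- data.frame(raw_score = 0:10, measure = seq(-4, 4, length.out = 11),
                   se = 0.9)
  prev <- 0L
  for (f in c(1, 0.7, 0.5, 0.3, 0.15)) {
    st2 <- st; st2$se <- st$se * f
    rep_f <- wright_strata(st2)
    expect_gte(rep_f$n_levels, prev)
    # the level count always equals the number of anchor advances
    expect_equal(rep_f$n_levels, length(rep_f$anchors))
    prev <- rep_f$n_levels
  }
})

test_that("a short well-targeted test separates two levels at study scale", {
  co <- generate_cohort(cohort_config(
    bank = dich_bank(c(0.98, 0.73, 0.62, -0.12, -0.94, -1.28),
                     ids = sprintf("F%d", 1:6)),
    seed = 804))
  cal <- estimate_jmle(co$responses)
  rep2 <- wright_strata(score_to_measure_table(cal))
  expect_equal(rep2$n_levels, 2L)
  expect_equal(rep2$sample_independent_reliability, 0.8)
  expect_equal(rep2$level_cutoffs$label, c("Emerging", "Expanding"))
})

test_that("published cutoff presets categorize exactly as printed", {
  pre <- hl_cutoff_presets()
  expect_setequal(names(pre),
                  c("fhl", "ihl", "chl", "composite", "composite_younger"))
  expect_equal(categorize(5, pre$fhl), "Expanding")
  expect_equal(categorize(5, pre$ihl), "Emerging")
  expect_equal(categorize(28, pre$composite), "Upper Bridging")
  expect_equal(categorize(27, pre$composite), "Lower Bridging")
  expect_equal(categorize(27, pre$composite_younger), "Upper Bridging")
  # partition: every attainable score maps to exactly one level
  for (p in pre) {
    sc <- min(p$min_score):max(p$max_score)
    expect_length(categorize(sc, p), length(sc))
  }
  expect_error(categorize(7, pre$fhl), "range")
  expect_error(categorize(-1, pre$fhl), "range")
})
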