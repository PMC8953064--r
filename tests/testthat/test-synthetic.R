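test_that("the default bank emulates the published battery structure", {
  bank <- default_item_bank()
  expect_length(bank$specs, 23L)
  expect_equal(unname(table(bank$scale)[c("fhl", "ihl", "chl")]),
               c(6L, 10L, 7L), ignore_attr = TRUE)
  expect_equal(range(bank$difficulty), c(-2.05, 2.91))
  mm <- vapply(bank$specs, `[[`, integer(1), "max_score")
  expect_equal(sum(mm[bank$scale == "chl"]), 14L)  # critical scale spans 0-14
  expect_equal(sum(mm), 30L)                       # composite spans 0-30
  for (t in bank$thresholds)
    if (!is.null(t)) expect_equal(mean(t), 0)
})

test_that("generation is deterministic in the seed", {
  c1 <- generate_cohort(cohort_config(seed = 55))
  c2 <- generate_cohort(cohort_config(seed = 55))
  c3 <- generate_cohort(cohort_config(seed = 56))
  expect_identical(c1$responses$scores, c2$responses$scores)
  expect_identical(c1$covariates, c2$covariates)
  expect_identical(c1$truth$theta, c2$truth$theta)
  expect_false(identical(c1$responses$scores, c3$responses$scores))
  expect_error(cohort_config(), "seed")
})

test_that("cell frequencies at fixed abilities match the model probabilities", {
  set.seed(57)
  bank <- item_bank(test_spec(list(item_spec("d1"), item_spec("p1", "partial_credit", 3))),
                    c(0.5, -0.3), list(NULL, c(-0.8, 0, 0.8)))
  for (th in c(-1.5, 0, 1.5)) {
    X <- draw_responses(rep(th, 10000), bank)
    # dichotomous cell
    p <- dichotomous_prob(th, 0.5)
    mc_se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(mean(X[, "d1"]) - p), 3 * mc_se + 1e-9)
    # every partial-credit category
    probs <- pcm_category_probs(th, -0.3, c(-0.8, 0, 0.8))
    for (k in 0:3) {
      mc_se <- sqrt(probs[k + 1] * (1 - probs[k + 1]) / 10000)
      expect_lt(abs(mean(X[, "p1"] == k) - probs[k + 1]), 3.5 * mc_se + 1e-9)
    }
  }
})

test_that("the truth record closes over the generating probabilities", {
  de <- data.frame(item_id = "FHLD7", grouping = "gender", shift = 0.9)
  co <- generate_cohort(cohort_config(dif_effects = de, seed = 58))
  tr <- co$truth
  # effective difficulties reproduce bank + DIF shift exactly
  fem <- tr$groupings$gender == "female"
  expect_equal(unname(tr$effective_difficulty[fem, "FHLD7"]),
               rep(unname(tr$difficulty["FHLD7"]) + 0.9, sum(fem)))
  expect_equal(unname(tr$effective_difficulty[!fem, "FHLD7"]),
               rep(unname(tr$difficulty["FHLD7"]), sum(!fem)))
  # every generating probability is recomputable from the record
  for (i in c(1L, 50L)) for (j in c("FHLD7", "CRHLP4")) {
    p <- pcm_category_probs(tr$theta[i], tr$effective_difficulty[i, j],
                            if (is.null(tr$thresholds[[j]])) 0 else tr$thresholds[[j]])
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  # observed totals track the model-expected totals
  mm <- vapply(co$responses$specs, `[[`, integer(1), "max_score")
  E <- vapply(seq_len(23), function(j) {
    mean(vapply(seq_len(355), function(i) {
      tau <- co$truth$thresholds[[j]]
      sum((0:mm[j]) * pcm_category_probs(tr$theta[i],
                                         tr$effective_difficulty[i, j],
                                         if (is.null(tau)) 0 else tau))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(mean(abs(colMeans(co$responses$scores) - E)), 0.03)
})

test_that("misfit person mechanisms overwrite the intended cells", {
  co <- generate_cohort(cohort_config(
    misfit_persons = list(n = 12L, mechanism = "random_responder"),
    seed = 59))
  expect_length(co$truth$misfit_persons, 12L)
  ct <- generate_cohort(cohort_config(
    misfit_persons = list(n = 5L, mechanism = "careless_tail"), seed = 60))
  expect_length(ct$truth$misfit_persons, 5L)
  # careless tail: early items still follow the model (scores bounded by spec)
  expect_true(all(ct$responses$scores >= 0, na.rm = TRUE))
})

test_that("missingness masks cells at the configured rate", {
  co <- generate_cohort(cohort_config(missing_rate = 0.1, seed = 61))
  rate <- mean(is.na(co$responses$scores))
  expect_lt(abs(rate - 0.1), 0.01)
  # calibration still runs on the masked matrix
  cal <- estimate_jmle(co$responses)
  expect_true(cal$converged)
})

test_that("a clean cohort survives the full purification pipeline untouched", {
  set.seed(62)
  clean <- replicate(10, {
    co <- generate_cohort(cohort_config(seed = sample.int(1e6, 1)))
    nrow(purify_items(co$responses)$removed) == 0L
  })
  expect_gte(mean(clean), 0.9)
})

test_that("criterion behaviors follow the configured logistic link", {
  set.seed(63)
  score <- rowSums(draw_dich(rnorm(2000), seq(-2, 2, length.out = 10)))
  # null slope: behavior unrelated to the score
  b0 <- generate_criterion_behaviors(score, 0, c(x = 0.2))
  expect_lt(abs(roc_auc(b0$beh_x, score) - 0.5), 0.03)
  # slope matching a known odds ratio per point is recovered
  b1 <- generate_criterion_behaviors(score, log(1.43), c(x = -2))
  cr <- criterion_logistic(b1$beh_x, score)
  expect_true(cr$ci_low <= 1.43 && 1.43 <= cr$ci_high)
  # extreme negative intercept: the behavior vanishes
  b2 <- generate_criterion_behaviors(score, 0, c(x = -30))
  expect_equal(sum(b2$beh_x), 0L)
})

test_that("the convergent screener shows its designed difficulty and limits", {
  set.seed(64)
  theta <- rnorm(500)
  noiseless <- generate_convergent_measure(theta, 0)
  noisy <- generate_convergent_measure(theta, 1.5)
  s_true <- rowSums(draw_dich(theta, c(0.98, 0.73, 0.62, -0.12, -0.94, -1.28)))
  expect_gt(cor(noiseless, s_true), cor(noisy, s_true))  # noise attenuates
  expect_warning(generate_convergent_measure(theta, 0, difficulties = rep(10, 6)),
                 "floor")
})
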