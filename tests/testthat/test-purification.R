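fake_fit <- function(df) {
  df$infit_mnsq <- 1
  df$infit_zstd <- 0
  df$n_used <- 100L
  class(df) <- c("fit_report", "data.frame")
  attr(df, "unit") <- "item"
  df
}

test_that("removal candidates follow the outfit gate and negative-polarity rule", {
  fit <- fake_fit(data.frame(
    item_id = c("A", "B", "C", "D", "E"),
    outfit_mnsq = c(1.8, 1.6, 1.1, 0.4, 1.0),
    outfit_zstd = c(2.5, 1.0, 0.5, -2.5, 0.1),
    pmc = c(0.4, 0.5, 0.55, 0.3, -0.10)))
  cand <- flag_removal_candidates(fit)
  # A passes both gates; B fails the zstd gate; D is low-mnsq (never removed);
  # E has perfect fit but negative polarity, appended last
  expect_equal(cand$item_id, c("A", "E"))
  expect_equal(cand$trigger, c("outfit", "negative_pmc"))

  ok <- fake_fit(data.frame(item_id = c("A", "B"),
                            outfit_mnsq = c(1.4, 0.6),
                            outfit_zstd = c(1.9, -1.2), pmc = c(0.5, 0.4)))
  expect_equal(nrow(flag_removal_candidates(ok)), 0L)
})

test_that("candidates are ordered worst-first with deterministic tie-breaks", {
  fit <- fake_fit(data.frame(
    item_id = c("b_tie", "a_tie", "worst", "neg2", "neg1"),
    outfit_mnsq = c(1.7, 1.7, 2.4, 1.0, 1.0),
    outfit_zstd = c(2.2, 2.2, 3.0, 0, 0),
    pmc = c(0.3, 0.3, 0.2, -0.2, -0.05)))
  cand <- flag_removal_candidates(fit)
  expect_equal(cand$item_id[1], "worst")
  expect_equal(cand$item_id[2:3], c("a_tie", "b_tie"))  # lexical tie-break
  expect_setequal(cand$item_id[4:5], c("neg1", "neg2"))
  # an item breaching both rules is classified by its negative polarity
  both <- fake_fit(data.frame(item_id = "X", outfit_mnsq = 2.5,
                              outfit_zstd = 4, pmc = -0.3))
  expect_equal(flag_removal_candidates(both)$trigger, "negative_pmc")
  # keep-list overrides
  keep <- purification_rules(keep_items = "worst")
  expect_false("worst" %in% flag_removal_candidates(fit, keep)$item_id)
})

test_that("model-consistent data are not purified", {
  co <- generate_cohort(cohort_config(seed = 301))
  tr <- purify_items(co$responses)
  expect_equal(nrow(tr$removed), 0L)
  expect_length(tr$rounds, 1L)
  expect_null(tr$rounds[[1]]$removed_item)
})

test_that("injected noise items are removed one per round, worst first", {
  co <- generate_cohort(purification_design("six_noise", seed = 302))
  tr <- purify_items(co$responses)
  expect_setequal(tr$removed$item_id, co$truth$noise_items$item_id)
  expect_true(all(tr$removed$trigger == "outfit"))
  expect_length(tr$rounds, 7L)           # 6 removals + clean final round
  expect_equal(ncol(tr$final_responses$scores), 6L)
  # audit: every recorded removal breached its floors at removal time
  for (r in tr$rounds) {
    if (is.null(r$removed_item)) next
    row <- r$fit[r$fit$item_id == r$removed_item, ]
    if (r$trigger == "outfit") {
      expect_gt(row$outfit_mnsq, 1.5)
      expect_gt(row$outfit_zstd, 2)
    } else {
      expect_lt(row$pmc, 0)
    }
    # single removal per round, and it is the worst candidate
    expect_equal(r$candidates$item_id[1], r$removed_item)
  }
})

test_that("a reverse-keyed item exits through the negative-polarity rule", {
  co <- generate_cohort(purification_design("reverse_keyed", seed = 303))
  tr <- purify_items(co$responses)
  expect_setequal(tr$removed$item_id,
                  c(co$truth$noise_items$item_id, co$truth$reversed_items))
  expect_equal(sum(tr$removed$trigger == "outfit"), 4L)
  expect_equal(tr$removed$trigger[tr$removed$item_id == "R01"], "negative_pmc")
})

test_that("purification traces are deterministic and respect the item floor", {
  co <- generate_cohort(purification_design("six_noise", seed = 304))
  t1 <- purify_items(co$responses)
  t2 <- purify_items(co$responses)
  expect_identical(t1$removed, t2$removed)
  expect_equal(t1$final_calibration$item_difficulty,
               t2$final_calibration$item_difficulty)
  # a floor above the retainable count aborts instead of gutting the scale
  expect_error(purify_items(co$responses, min_items = 12L), "fewer than 12")
})

test_that("person misfit round keeps the original data when no one misfits", {
  set.seed(305)
  rmx <- dich_responses(rnorm(250), seq(-1, 1, length.out = 8))
  pr <- person_misfit_round(rmx, purification_rules(person_outfit_floor = 6))
  expect_equal(pr$verdict, "no_candidates")
  expect_identical(pr$responses, rmx)
  expect_null(pr$fit_after)
})

test_that("person misfit round adopts the reduced data when fit improves", {
  # random responders in a wide-ability cohort push items past the outfit
  # band; removing them restores the band
  set.seed(306)
  theta <- rnorm(355, 0, 2)
  X <- draw_dich(theta, seq(-1.2, 1.2, length.out = 12))
  X[1:40, ] <- matrix(rbinom(40 * 12, 1, 0.5), 40)
  rmx <- response_matrix(X, test_spec(lapply(colnames(X), item_spec)))
  pr <- person_misfit_round(rmx)
  expect_equal(pr$verdict, "improved")
  expect_gt(length(pr$removed_persons), 0L)
  expect_lt(nrow(pr$responses$scores), 355L)
  band <- function(f) sum(f$outfit_mnsq < 0.5 | f$outfit_mnsq > 1.5)
  expect_true(band(pr$fit_after) < band(pr$fit_before) ||
                (band(pr$fit_after) == band(pr$fit_before) &&
                   mean(abs(pr$fit_after$outfit_zstd)) <
                     mean(abs(pr$fit_before$outfit_zstd))))
})

test_that("person misfit round retains the original data when fit does not improve", {
  # model-consistent cohort: the few persons past the floor are chance
  # events and their removal only overfits the items
  found <- FALSE
  for (s in 307:312) {
    set.seed(s)
    rmx <- dich_responses(rnorm(300), seq(-1.5, 1.5, length.out = 10))
    pr <- person_misfit_round(rmx)
    if (pr$verdict == "not_improved") {
      found <- TRUE
      expect_identical(pr$responses, rmx)
      expect_equal(pr$removed_persons, character(0))
      break
    }
  }
  expect_true(found)
})

test_that("person misfit round refuses to shrink below the sample floor", {
  set.seed(313)
  rmx <- dich_responses(rnorm(40), seq(-1.5, 1.5, length.out = 12))
  # an aggressive person floor marks many persons, so removal would cut the
  # sample below the floor and the original data must be retained
  expect_warning(pr <- person_misfit_round(
    rmx, purification_rules(person_outfit_floor = 1.05), min_persons = 38L),
    "fewer than 38")
  expect_equal(pr$verdict, "too_few_persons")
  expect_identical(pr$responses, rmx)
})

test_that("model-consistent replicates essentially never lose items", {
  set.seed(314)
  removed <- replicate(10, {
    rmx <- dich_responses(rnorm(400), runif(15, -1.5, 1.5))
    nrow(purify_items(rmx)$removed)
  })
  expect_lte(mean(removed), 1)
  expect_gte(mean(removed == 0), 0.8)
})
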