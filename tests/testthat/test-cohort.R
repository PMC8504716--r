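test_that("cohort config validates probabilities, seed and allocation", {
  expect_error(cohort_config(N = 10, p_responder = 0.6, p_nonresponder = 0.5,
                             seed = 1), "exceeds 1")
  expect_error(cohort_config(N = 10, p_responder = 0.1, p_nonresponder = 0.1),
               "seed is required")
  expect_error(cohort_config(N = 10, p_responder = 0.1, p_nonresponder = 0.1,
                             seed = 2^31 - 10, n_reps = 100), "below 2\\^31")
  cfg <- cohort_config(N = 10, p_responder = 0.1, p_nonresponder = 0.1,
                       seed = 1)
  expect_equal(cfg$alloc_T_share, 2 / 3)
  expect_identical(cfg$allocation, "bernoulli")
})

test_that("potential outcomes are deterministic within each category", {
  cfg <- cohort_config(N = 5000, p_responder = 0.1, p_nonresponder = 0.1,
                       seed = 3)
  p <- generate_cohort(cfg)$participants
  resp <- p[p$category == "responder", ]
  expect_true(all(resp$outcome_under_C) && !any(resp$outcome_under_T))
  nonr <- p[p$category == "nonresponder", ]
  expect_true(all(nonr$outcome_under_C) && all(nonr$outcome_under_T))
  ninf <- p[p$category == "noninformative", ]
  expect_true(!any(ninf$outcome_under_C) && !any(ninf$outcome_under_T))
  # realized outcome is the potential outcome of the assigned arm
  expect_identical(p$realized_outcome,
                   ifelse(p$arm == "T", p$outcome_under_T, p$outcome_under_C))
})

test_that("identical config and seed reproduce the cohort byte for byte", {
  cfg <- cohort_config(N = 500, p_responder = 0.05, p_nonresponder = 0.05,
                       seed = 11)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(generate_cohort(cfg), p1)
  write_cohort_csv(generate_cohort(cfg), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(
    readLines(p1)[1],
    "id,category,arm,outcome_under_C,outcome_under_T,realized_outcome")
  # a different seed gives a different cohort
  expect_false(identical(
    generate_cohort(cfg)$participants,
    generate_cohort(cfg, seed = 12)$participants))
})

test_that("tabulation tallies realized outcomes into the 2x2 table", {
  hand <- data.frame(
    id = 1:4,
    category = c("responder", "nonresponder", "noninformative",
                 "noninformative"),
    arm = c("T", "C", "C", "T"),
    outcome_under_C = c(TRUE, TRUE, FALSE, FALSE),
    outcome_under_T = c(FALSE, TRUE, FALSE, FALSE),
    realized_outcome = c(FALSE, TRUE, FALSE, FALSE)
  )
  tab <- tabulate_cohort(hand)
  expect_identical(c(tab$a, tab$b, tab$c, tab$d), c(1L, 0L, 1L, 2L))
  expect_identical(tab$Nc + tab$NT, 4L)

  one_arm <- hand[hand$arm == "C", ]
  expect_error(tabulate_cohort(one_arm), "arm is empty")
})

test_that("degenerate category mixes produce the expected tables", {
  # all non-informative: no events anywhere
  cfg0 <- cohort_config(N = 400, p_responder = 0, p_nonresponder = 0,
                        seed = 5)
  tab0 <- tabulate_cohort(generate_cohort(cfg0))
  expect_identical(tab0$a + tab0$b, 0L)

  # all non-responders: everyone dies, empirical RR = 1
  cfg1 <- cohort_config(N = 400, p_responder = 0, p_nonresponder = 1,
                        seed = 5)
  tab1 <- tabulate_cohort(generate_cohort(cfg1))
  expect_identical(tab1$c + tab1$d, 0L)
  expect_equal(event_rates(tab1)$RR, 1)
})

test_that("true breakdown counts latent labels and matches the table margins", {
  cfg <- cohort_config(N = 3000, p_responder = 0.05, p_nonresponder = 0.06,
                       seed = 21)
  coh <- generate_cohort(cfg)
  tb <- true_breakdown(coh)
  p <- coh$participants
  expect_identical(tb$responders_total, sum(p$category == "responder"))
  expect_identical(tb$nonresponders_total, sum(p$category == "nonresponder"))
  expect_identical(tb$noninformative, sum(p$category == "noninformative"))
  expect_identical(tb$N, nrow(p))
  expect_identical(tb$responders_total + tb$unnecessary, tb$N)
  expect_identical(tb$ethical_losses, tb$N - tb$responders_T)

  # the observed table's events are exactly the latent event-presenters
  tab <- tabulate_cohort(coh)
  expect_identical(tab$a, tb$potential_responders_C + tb$nonresponders_C)
  expect_identical(tab$b, tb$nonresponders_T)
})

test_that("exact-split allocation fixes the experimental arm size", {
  cfg <- cohort_config(N = 900, p_responder = 0.05, p_nonresponder = 0.05,
                       seed = 2, allocation = "exact")
  p <- generate_cohort(cfg)$participants
  expect_identical(sum(p$arm == "T"), 600L)
})

test_that("decomposition recovers the latent breakdown on a large cohort", {
  cfg <- cohort_config(N = 1e6, p_responder = 0.0258, p_nonresponder = 0.0574,
                       seed = 31)
  coh <- generate_cohort(cfg)
  est <- decompose_trial(tabulate_cohort(coh), warn = FALSE)
  truth <- true_breakdown(coh)
  expect_lt(abs(est$responders_total - truth$responders_total) /
              truth$responders_total, 0.05)
  expect_lt(abs(est$noninformative - truth$noninformative) /
              truth$noninformative, 0.05)
})

test_that("the absolute benefit estimator is unbiased for the responder share", {
  cfg <- cohort_config(N = 2000, p_responder = 0.05, p_nonresponder = 0.05,
                       seed = 100, n_reps = 200)
  rec <- recovery_experiment(cfg)
  expect_lte(abs(rec$ab$bias), 3 * rec$ab$se)
  expect_true(rec$ab$unbiased)
  expect_lte(abs(rec$responders_T$mean - rec$responders_T$latent_mean),
             3 * rec$responders_T$se_mean)
})

test_that("with no responders the estimate is clamped at zero from below", {
  cfg <- cohort_config(N = 1000, p_responder = 0, p_nonresponder = 0.05,
                       seed = 9, n_reps = 100)
  rec <- recovery_experiment(cfg)
  expect_gt(rec$n_clamped, 0)
  # clamping can only push the mean estimate up, never below the truth
  expect_gte(rec$responders_T$mean, 0)
  expect_gte(rec$responders_T$bias, 0)
})

test_that("doubling the cohort size shrinks the estimator spread as sqrt(N)", {
  base <- cohort_config(N = 4000, p_responder = 0.05, p_nonresponder = 0.05,
                        seed = 500, n_reps = 200)
  dbl <- cohort_config(N = 8000, p_responder = 0.05, p_nonresponder = 0.05,
                       seed = 900, n_reps = 200)
  se_base <- recovery_experiment(base)$ab$se
  se_dbl <- recovery_experiment(dbl)$ab$se
  expect_gt(se_dbl / se_base, 0.6)
  expect_lt(se_dbl / se_base, 0.85)
})

test_that("recovery report survives a JSON round trip", {
  cfg <- cohort_config(N = 500, p_responder = 0.05, p_nonresponder = 0.05,
                       seed = 44, n_reps = 10)
  rec <- recovery_experiment(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_recovery_json(rec, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$n_reps, 10)
  expect_equal(back$ab$bias, rec$ab$bias)
})
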