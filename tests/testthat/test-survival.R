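make_records <- function(time, event) {
  data.frame(sample_id = sprintf("s%02d", seq_along(time)), time = time,
             event = event)
}

test_that("log-rank statistic matches the from-definition tally and nulls out", {
  # 8-record two-group toy with hand-computable at-risk tables
  time <- c(2, 4, 6, 9, 3, 5, 8, 12)
  event <- c(1, 1, 0, 1, 1, 1, 1, 0)
  grp <- rep(c("A", "B"), each = 4)
  rec <- make_records(time, event)
  expect_equal(logrank_neglog10p(rec, grp),
               oracle_logrank_2group(time, event, grp), tolerance = 1e-8)

  # identical time/event multisets in both groups: statistic 0, p = 1
  rec2 <- make_records(c(1, 3, 5, 7, 1, 3, 5, 7), c(1, 0, 1, 1, 1, 0, 1, 1))
  expect_equal(logrank_neglog10p(rec2, rep(c("A", "B"), each = 4)), 0)

  # -log10 p > -log10(0.05) exactly when p < 0.05
  set.seed(8)
  rec3 <- make_records(c(rexp(20, 1), rexp(20, 4)), rep(1, 40))
  out <- logrank_neglog10p(rec3, rep(1:2, each = 20))
  sd3 <- survival::survdiff(survival::Surv(rec3$time, rec3$event) ~ rep(1:2, each = 20))
  p3 <- stats::pchisq(sd3$chisq, 1, lower.tail = FALSE)
  expect_identical(out > -log10(0.05), p3 < 0.05)

  # guards
  expect_error(logrank_neglog10p(rec, rep("A", 8)), "2 groups")
  expect_error(logrank_neglog10p(make_records(c(-1, 2), c(1, 1)), c("A", "B")),
               "time")
})

test_that("the Cox score-test variant agrees with survival::coxph", {
  set.seed(3)
  rec <- make_records(c(rexp(15, 1), rexp(15, 3)), rbinom(30, 1, 0.8))
  grp <- rep(c("A", "B"), each = 15)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(rec$time, rec$event) ~ factor(grp),
                    ties = "breslow"))
  sc <- summary(fit)$sctest
  expect_equal(logrank_neglog10p(rec, grp, method = "cox-score"),
               -log10(stats::pchisq(sc["test"], sc["df"], lower.tail = FALSE)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("concordance index matches brute-force pair enumeration", {
  # perfectly concordant, uncensored: singleton risk groups ordered by time
  # give distinct risks for every sample, so every pair is concordant
  time <- c(1, 2, 3, 10, 11, 12)
  event <- rep(1, 6)
  expect_equal(concordance_index(make_records(time, event), paste0("g", 1:6)), 1.0)

  # two groups of three: the nine cross-group pairs are concordant, the six
  # within-group pairs are risk ties (0.5 each) -> C = (9 + 3)/15
  grp <- rep(c("high", "low"), each = 3)
  expect_equal(concordance_index(make_records(time, event), grp), 0.8)

  # single subtype: uninformative, C = 0.5
  expect_equal(concordance_index(make_records(time, event), rep("A", 6)), 0.5)

  # censored toy vs exhaustive enumeration at the fitted risk scores
  time2 <- c(2, 5, 7, 3, 8, 11)
  event2 <- c(1, 1, 0, 1, 1, 1)
  grp2 <- rep(c("A", "B"), each = 3)
  rec2 <- make_records(time2, event2)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time2, event2) ~ factor(grp2),
                    ties = "breslow"))
  risk <- unname(fit$linear.predictors)
  expect_equal(concordance_index(rec2, grp2),
               oracle_cindex(time2, event2, risk), tolerance = 1e-10)

  # larger random instance with censoring
  set.seed(12)
  t3 <- round(rexp(30, rep(c(1, 3, 6), each = 10)), 3)
  e3 <- rbinom(30, 1, 0.7)
  g3 <- rep(c("x", "y", "z"), each = 10)
  fit3 <- suppressWarnings(
    survival::coxph(survival::Surv(t3, e3) ~ factor(g3), ties = "breslow"))
  expect_equal(concordance_index(make_records(t3, e3), g3),
               oracle_cindex(t3, e3, unname(fit3$linear.predictors)),
               tolerance = 1e-10)
})

test_that("C-index is invariant to monotone relabelling of risk groups", {
  set.seed(21)
  time <- rexp(24, rep(c(1, 2, 4), each = 8))
  event <- rbinom(24, 1, 0.8)
  grp <- rep(c("a", "b", "c"), each = 8)
  rec <- make_records(time, event)
  # relabel groups with different strings preserving the partition
  expect_equal(concordance_index(rec, grp),
               concordance_index(rec, c(a = "g1", b = "g2", c = "g3")[grp]))
})

test_that("Kaplan-Meier tables match product-limit hand computation", {
  # 5-record toy with one censored observation
  time <- c(1, 2, 3, 4, 5)
  event <- c(1, 1, 0, 1, 1)
  rec <- make_records(time, event)
  km <- km_curves(rec, rep("A", 5))
  oh <- oracle_km(time, event)
  expect_equal(km$time[km$n_event > 0], oh$time)
  expect_equal(km$survival[km$n_event > 0], oh$surv, tolerance = 1e-12)
  # hand values: 4/5, 3/4 * 4/5 = 3/5, then censor, 3/5 * 1/2, * 0
  expect_equal(oh$surv, c(4/5, 3/5, 3/10, 0), tolerance = 1e-12)

  # no events: flat curve at 1
  km2 <- km_curves(make_records(c(3, 6, 9), c(0, 0, 0)), rep("A", 3))
  expect_true(all(km2$survival == 1))

  # all events at distinct times, no censoring: drops of 1/n
  km3 <- km_curves(make_records(c(1, 2, 3, 4), rep(1, 4)), rep("A", 4))
  expect_equal(km3$survival, c(3, 2, 1, 0) / 4, tolerance = 1e-12)
})

test_that("log-rank p-values are calibrated under label permutation and powered under real separation", {
  set.seed(31)
  coh <- generate_cohort(synthetic_spec(n_samples = 100, seed = 31))
  rec <- coh$clinical
  # null: shuffled labels rarely significant (quick 60-shuffle check; the
  # full 200-shuffle calibration runs in the acceptance suite)
  hits <- 0
  for (i in 1:60) {
    lab <- sample(coh$true_labels)
    p <- 10^(-logrank_neglog10p(rec, lab))
    if (p < 0.05) hits <- hits + 1
  }
  expect_lt(hits / 60, 0.15)
  # true labels with >= 3-fold hazard ratios separate strongly
  expect_gt(logrank_neglog10p(rec, coh$true_labels), 2)
})
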