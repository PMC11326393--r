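# RECIST, ORR, Simon design OCs, Kaplan-Meier, adverse events.

test_that("percent change is plain arithmetic with a guarded baseline", {
  expect_equal(percent_change(10, 6.5), -35)
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(9.62, 9.62 * 0.74), -26)
  expect_error(percent_change(0, 5), "baseline")
})

test_that("RECIST boundary suite", {
  pr <- classify_recist(c(baseline = 10, week6 = 9, week12 = 7))
  expect_equal(unname(pr$category), c("SD", "PR"))
  expect_equal(pr$best_response, "PR")

  expect_equal(classify_recist(c(baseline = 10, week6 = 9.2,
                                 week12 = 7.4))$best_response, "SD")
  # exactly -30% -> PR
  expect_equal(unname(classify_recist(c(baseline = 10, week12 = 7))$category),
               "PR")
  # exactly +20% with >= 0.5 cm absolute -> PD
  expect_equal(unname(classify_recist(c(baseline = 10, week12 = 12))$category),
               "PD")
  # +20% but < 0.5 cm absolute -> SD
  expect_equal(unname(classify_recist(c(baseline = 2, week12 = 2.4))$category),
               "SD")
  # progression is judged from the nadir, not baseline
  rec <- classify_recist(c(baseline = 10, week6 = 6, week12 = 7.3))
  expect_equal(unname(rec$category), c("PR", "PD"))
  expect_equal(rec$best_response, "PR")
  # disappearance -> CR
  expect_equal(classify_recist(c(baseline = 3, week12 = 0))$best_response, "CR")

  expect_error(classify_recist(c(week6 = 5)), "baseline")
})

test_that("the trial's 17 best responses give ORR 35% with 6 PR, 11 SD", {
  resp <- trial_tables()$best_response$best_response
  expect_equal(table(factor(resp, c("CR", "PR", "SD", "PD")))[["PR"]], 6)
  expect_equal(sum(resp == "SD"), 11)
  orr <- orr_with_ci(resp)
  expect_equal(orr$rate, 6 / 17)
  expect_equal(round(100 * orr$rate), 35)
  cbr <- clinical_benefit_rate(resp)
  expect_equal(cbr$rate, 1)
})

test_that("Clopper-Pearson endpoints equal beta quantiles (binom.test oracle)", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    k <- sample(0:n, 1)
    resp <- c(rep("PR", k), rep("SD", n - k))
    ci <- orr_with_ci(resp)$ci
    ref <- stats::binom.test(k, n)$conf.int
    expect_equal(ci, as.numeric(ref), tolerance = 1e-12)
  }
  expect_equal(orr_with_ci(rep("SD", 17))$ci[1], 0)
  w <- orr_with_ci(c(rep("PR", 6), rep("SD", 11)), method = "wilson")
  expect_true(w$ci[1] > 0 && w$ci[2] < 1)
})

test_that("simon_oc matches full outcome-path enumeration to < 1e-12", {
  d <- two_stage_design()
  for (p in c(0.01, 0.05, 0.1, 0.24, 0.5, 0.9)) {
    expect_lt(abs(simon_oc(d, p)$reject_prob -
                    oracle_simon_reject(11, 0, 17, 3, p)), 1e-12)
  }
  d2 <- two_stage_design(n1 = 9, futility_stop_at = 1, n_total = 24,
                         reject_threshold = 5, p0 = 0.1, p1 = 0.3)
  for (p in c(0.05, 0.1, 0.3, 0.6)) {
    expect_lt(abs(simon_oc(d2, p)$reject_prob -
                    oracle_simon_reject(9, 1, 24, 5, p)), 1e-12)
  }
})

test_that("the trial design attains its printed type I error and power", {
  d <- two_stage_design()
  expect_equal(round(simon_oc(d, 0.05)$reject_prob, 2), 0.05)
  expect_equal(round(100 * simon_oc(d, 0.24)$reject_prob), 80)
  oc0 <- simon_oc(d, 0)
  expect_equal(oc0$reject_prob, 0)
  expect_equal(oc0$early_stop_prob, 1)
  expect_equal(oc0$expected_n, 11)
})

test_that("rejection probability is non-decreasing in p", {
  d <- two_stage_design()
  rp <- vapply(seq(0, 1, length.out = 101),
               function(p) simon_oc(d, p)$reject_prob, numeric(1))
  expect_true(all(diff(rp) >= -1e-12))
  expect_error(simon_oc(d, 1.2), "\\[0, 1\\]")
})

test_that("KM equals empirical survival without censoring", {
  time <- c(3, 6, 9, rep(25, 14))
  event <- c(1, 1, 1, rep(0, 14))
  km <- km_estimate(time, event, 12)
  expect_equal(km$survival, 14 / 17)
  expect_equal(round(100 * km$survival, 1), 82.4)

  # all-event data: S(t) = 1 - ECDF(t) at every event time
  set.seed(3)
  t2 <- sort(sample(1:50, 20, replace = TRUE))
  km2 <- km_estimate(t2, rep(1, 20), max(t2))
  for (i in seq_len(nrow(km2$curve))) {
    expect_equal(km2$curve$survival[i], 1 - mean(t2 <= km2$curve$time[i]))
  }
  # no events at all
  km3 <- km_estimate(c(5, 10), c(0, 0), 12)
  expect_equal(km3$survival, 1)
  expect_equal(km3$ci, c(1, 1))
  expect_error(km_estimate(-1, 1, 5), "negative")
})

test_that("KM matches the hand product oracle under heavy censoring", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    time <- sample(1:15, n, replace = TRUE)
    event <- rbinom(n, 1, 0.5)
    at <- sample(1:15, 1)
    if (all(event == 0)) event[1] <- 1
    expect_equal(km_estimate(time, event, at)$survival,
                 oracle_km(time, event, at), tolerance = 1e-12)
  }
})

test_that("KM agrees with survival::survfit", {
  skip_if_not_installed("survival")
  set.seed(13)
  time <- rexp(40, 0.1)
  event <- rbinom(40, 1, 0.6)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "log")
  km <- km_estimate(time, event, max(time))
  sf <- summary(fit, times = fit$time[fit$n.event > 0])
  expect_equal(km$curve$survival, as.numeric(sf$surv), tolerance = 1e-10)
  pos <- km$curve$survival > 0  # survfit reports NA bounds once S hits 0
  expect_equal(km$curve$lower[pos], as.numeric(sf$lower)[pos],
               tolerance = 1e-10)
})

test_that("adverse events count patients per grade band", {
  tab <- tabulate_adverse_events(
    ae_records_from_counts(trial_tables()$adverse_events), n_treated = 17)
  ht <- tab[tab$term == "Hypertension", ]
  expect_equal(ht$n_grade3plus, 4)
  expect_equal(ht$pct_grade3plus, 23.5)
  expect_equal(ht$pct_any, 58.8)
  expect_true(all(tab$n_grade3plus <= tab$n_any))

  empty <- tabulate_adverse_events(
    data.frame(patient_id = character(0), term = character(0),
               grade = integer(0)), 17)
  expect_equal(nrow(empty), 0)
  # duplicate events for one patient count once
  dup <- data.frame(patient_id = c("a", "a", "b"), term = "Nausea",
                    grade = c(2, 3, 1))
  expect_equal(tabulate_adverse_events(dup, 17)$n_any, 2)
  expect_error(tabulate_adverse_events(
    data.frame(patient_id = "a", term = "x", grade = NA), 17), "grade")
})
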