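# Fold changes, rank tests, Spearman correlation, ctDNA summaries.

test_that("fold changes anchor to baseline and report exclusions", {
  panel <- data.frame(
    patient_id = rep(c("a", "b", "c"), each = 2),
    timepoint = rep(c("baseline", "W6D1"), 3),
    analyte = "VEGF",
    value = c(10, 16, 5, 5, 0, 7)  # c has zero baseline
  )
  expect_warning(fc <- fold_changes(panel), "excluded")
  expect_equal(fc$fold[fc$patient_id == "a" & fc$timepoint == "W6D1"], 1.6)
  expect_equal(fc$fold[fc$patient_id == "b" & fc$timepoint == "W6D1"], 1)
  expect_true(all(fc$fold[fc$timepoint == "baseline"] == 1))
  expect_false("c" %in% fc$patient_id)
  expect_equal(attr(fc, "excluded")$patient_id, "c")
})

test_that("fold changes are invariant to per-patient rescaling", {
  coh <- generate_cohort(10, seed = 4)
  p1 <- coh$panel
  scale <- stats::setNames(runif(10, 0.5, 5), unique(p1$patient_id))
  p2 <- p1
  p2$value <- p1$value * scale[p1$patient_id]
  f1 <- fold_changes(p1)
  f2 <- fold_changes(p2)
  expect_equal(f2$fold, f1$fold, tolerance = 1e-12)
})

test_that("planted median fold change is recovered through fold_changes", {
  meds <- vapply(1:200, function(s) {
    fc <- fold_changes(generate_cohort(17, seed = 5000 + s)$panel)
    median(fc$fold[fc$analyte == "cfDNA" & fc$timepoint == "W6D1"])
  }, numeric(1))
  expect_lt(abs(mean(meds) - 1.6) / 1.6, 0.10)
})

test_that("signed-rank test: extreme case, oracle agreement, invariance", {
  r <- paired_signed_rank(rep(0, 6), 1:6)
  expect_equal(r$p_value, 2 / 2^6)
  expect_equal(r$statistic, 21)

  set.seed(21)
  for (i in 1:50) {
    n <- sample(3:10, 1)
    d <- round(rnorm(n), sample(0:1, 1))  # occasional ties / zeros
    if (all(d == 0)) d[1] <- 1
    got <- paired_signed_rank(rep(0, n), d)
    expect_equal(got$p_value, oracle_signed_rank_p(d), tolerance = 1e-12)
  }
  # invariance under positive affine transforms (which preserve the order
  # of the paired differences; general monotone maps do not)
  set.seed(22)
  x <- rlnorm(12); y <- rlnorm(12) * 1.4
  expect_equal(paired_signed_rank(2 * x + 3, 2 * y + 3)$p_value,
               paired_signed_rank(x, y)$p_value)
  expect_error(paired_signed_rank(1:5, 1:5), "degenerate")
})

test_that("rank-sum test: exact p, degenerate equality, oracle agreement", {
  expect_equal(rank_sum_twogroup(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(rank_sum_twogroup(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  expect_equal(rank_sum_twogroup(c(5, 7, 9), c(5, 7, 9))$p_value, 1)

  set.seed(23)
  for (i in 1:40) {
    m <- sample(3:7, 1); n <- sample(3:7, 1)
    a <- rnorm(m); b <- rnorm(n)  # continuous: no ties
    expect_equal(rank_sum_twogroup(a, b)$p_value, oracle_ranksum_p(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(rank_sum_twogroup(exp(c(1, 5, 2)), exp(c(4, 3, 6)))$p_value,
               rank_sum_twogroup(c(1, 5, 2), c(4, 3, 6))$p_value)
  expect_error(rank_sum_twogroup(numeric(0), 1:3), "non-empty")
})

test_that("rank tests hold their nominal size under the null", {
  # 10,000-rep null simulations at n = 15; attained size in [0.04, 0.06]
  set.seed(99)
  n_rep <- 10000L
  rej_sr <- 0L; rej_rs <- 0L
  for (i in seq_len(n_rep)) {
    d <- rnorm(15)
    if (paired_signed_rank(rep(0, 15), d)$p_value <= 0.05) rej_sr <- rej_sr + 1L
    if (rank_sum_twogroup(rnorm(15), rnorm(15))$p_value <= 0.05) rej_rs <- rej_rs + 1L
  }
  expect_gte(rej_sr / n_rep, 0.04)
  expect_lte(rej_sr / n_rep, 0.06)
  expect_gte(rej_rs / n_rep, 0.04)
  expect_lte(rej_rs / n_rep, 0.06)
})

test_that("spearman: monotone data, antisymmetry, permutation oracle", {
  up <- c(a = 1, b = 4, c = 9, d = 16)
  chg <- c(a = -40, b = -20, c = -10, d = 5)
  s <- spearman_vs_tumor_change(up, chg)
  expect_equal(s$rho, 1)
  s2 <- spearman_vs_tumor_change(up, -chg)
  expect_equal(s2$rho, -1)

  set.seed(31)
  x <- c(1, 1, 2, 3, 3, 4, 5, 5)  # tie-laden
  y <- c(2, 1, 1, 3, 5, 4, 4, 6)
  got <- spearman_vs_tumor_change(x, y, p_method = "permutation")
  ref <- oracle_spearman(x, y)
  expect_equal(got$rho, ref$rho, tolerance = 1e-12)
  expect_equal(got$p_value, ref$p, tolerance = 1e-12)

  expect_error(spearman_vs_tumor_change(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_vs_tumor_change(c(1, 2), c(1, 2)), "3 complete")
})

test_that("detection rates reproduce k/n to one decimal exhaustively", {
  for (n in c(1:25, 50, 54, 100)) {
    flags <- do.call(rbind, lapply(0:n, function(k) {
      data.frame(patient_id = seq_len(n), timepoint = sprintf("k%03d", k),
                 detected = seq_len(n) <= k)
    }))
    dr <- detection_rates(flags)
    dr <- dr[dr$timepoint != "overall", ]
    k <- as.integer(sub("k", "", dr$timepoint))
    expect_equal(dr$percent, floor(1000 * k / n + 0.5) / 10)
  }
})

test_that("the printed detection counts give the printed rates", {
  flags <- detection_flags_from_counts(trial_tables()$detection_counts)
  dr <- detection_rates(flags)
  expect_equal(dr$percent[dr$timepoint == "baseline"], 30.8)
  expect_equal(dr$percent[dr$timepoint == "W6D1"], 42.9)
  expect_equal(dr$percent[dr$timepoint == "overall"], 29.6)
  expect_equal(dr$k[dr$timepoint == "overall"], 16)
  expect_equal(dr$n[dr$timepoint == "overall"], 54)
})

test_that("variant summary parses the printed table", {
  vs <- variant_summary(trial_tables()$variants)
  expect_setequal(names(vs$per_gene), c("SETD2", "TP53", "NRAS", "VHL", "TERT"))
  expect_equal(vs$max_vaf, 2.35)
  expect_equal(vs$n_variants, 9)
  expect_true(vs$oncomap["3", "TP53"])
  expect_false(vs$oncomap["1", "TP53"])

  empty <- variant_summary(trial_tables()$variants[0, ])
  expect_equal(empty$n_variants, 0)
  bad <- trial_tables()$variants
  bad$vaf_percent[3] <- "12x"
  expect_error(variant_summary(bad), "row.*3")
})

test_that("panel_tests reports unadjusted and Holm-adjusted p-values", {
  coh <- generate_cohort(17, seed = 6)
  pt <- panel_tests(coh$panel, "W6D1")
  expect_true(all(pt$p_holm >= pt$p_value - 1e-12))
  expect_true("VEGF" %in% pt$analyte)
  # a planted 1.6-fold analyte should be clearly significant at n = 17
  expect_lt(pt$p_value[pt$analyte == "VEGF"], 0.05)
})

test_that("a planted niche-coverage shift in PR patients is detectable", {
  # end-to-end power property: per-patient coverage log-normal, PR shifted
  # by 2 sd on the log scale; 6 vs 11 rank-sum at alpha 0.05
  set.seed(71)
  n_rep <- 500L
  hits <- 0L
  for (i in seq_len(n_rep)) {
    cov_sd <- rlnorm(11, meanlog = log(0.05), sdlog = 0.5)
    cov_pr <- rlnorm(6, meanlog = log(0.05) + 2 * 0.5, sdlog = 0.5)
    if (rank_sum_twogroup(cov_pr, cov_sd)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.80)
})
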