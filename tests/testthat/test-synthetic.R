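# Synthetic tissue and cohort generators: planted truth must be recoverable
# and every stochastic claim reproducible under a fixed seed.

test_that("all-zero densities give an empty tissue with zero coverage", {
  ts <- tissue_spec(seed = 1, background_density = c(
    CD4 = 0, CD8 = 0, MHCII = 0, TCF1_CD8 = 0, other = 0))
  tt <- generate_tissue(ts)
  expect_equal(nrow(tt$cells), 0)
  expect_equal(tt$truth$planted_coverage, 0)
})

test_that("planted disc coverage matches the analytic disc/tumor ratio", {
  # 1 mm^2 disc wholly inside a 16 mm^2 square tumor
  r <- sqrt(1e6 / pi)
  ts <- tissue_spec(seed = 2, niche_specs = list(
    list(cx_um = 2000, cy_um = 2000, radius_um = r,
         mhc2_per_mm2 = 20, tcf1cd8_per_mm2 = 5)))
  tt <- generate_tissue(ts)
  expect_equal(tt$truth$planted_coverage, (pi * r^2 / 1e6) / 16,
               tolerance = 0.02)

  # disc below either threshold is not a true niche
  ts2 <- tissue_spec(seed = 2, niche_specs = list(
    list(cx_um = 2000, cy_um = 2000, radius_um = r,
         mhc2_per_mm2 = 20, tcf1cd8_per_mm2 = 3)))
  expect_equal(generate_tissue(ts2)$truth$planted_coverage, 0)
})

test_that("background counts follow Poisson moments across seeds", {
  # 100 cells/mm^2 over a 4 mm^2 tumor -> N ~ Poisson(400)
  totals <- vapply(1:50, function(s) {
    ts <- tissue_spec(width_um = 2000, height_um = 2000, seed = s,
                      background_density = c(other = 100))
    nrow(generate_tissue(ts)$cells)
  }, numeric(1))
  expect_lt(abs(mean(totals) - 400), 3 * sqrt(400) / sqrt(50))
  expect_lt(abs(var(totals) - 400), 400 * 0.6)
})

test_that("generation is deterministic and confined to the tumor polygon", {
  ts <- tissue_spec(seed = 42, tumor_polygon = disc_polygon(2000, 2000, 1800),
                    niche_specs = list(list(cx_um = 2000, cy_um = 1200,
                                            radius_um = 500, mhc2_per_mm2 = 32,
                                            tcf1cd8_per_mm2 = 12)))
  t1 <- generate_tissue(ts)
  t2 <- generate_tissue(ts)
  expect_identical(t1$cells, t2$cells)
  expect_true(all(points_in_mask(t1$mask, t1$cells$x_um, t1$cells$y_um)))

  d1 <- tempfile(); d2 <- tempfile()
  write_tissue(t1, d1); write_tissue(t2, d2)
  for (f in c("cells.csv", "mask.geojson", "truth_niche.geojson")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("invalid tissue specs are rejected", {
  expect_error(tissue_spec(background_density = c(CD8 = -1)), ">= 0")
  expect_error(tissue_spec(background_density = c(bogus = 5)), "phenotypes")
  expect_error(tissue_spec(niche_specs = list(list(cx_um = 0, cy_um = 0,
                                                   radius_um = 0,
                                                   mhc2_per_mm2 = 1,
                                                   tcf1cd8_per_mm2 = 1))))
})

test_that("planted PR labels are recovered exactly by RECIST downstream", {
  coh <- generate_cohort(17, seed = 9)
  resp <- classify_cohort(coh$lesions)
  expect_equal(sum(resp$best_response == "PR"), 6)
  expect_equal(sum(resp$best_response == "SD"), 11)
  expect_equal(stats::setNames(resp$best_response, resp$patient_id),
               coh$truth$planted_response)
})

test_that("planted analyte fold changes are recovered across replicates", {
  meds <- vapply(1:200, function(s) {
    coh <- generate_cohort(17, seed = 1000 + s)
    p <- coh$panel
    b <- p[p$analyte == "VEGF" & p$timepoint == "baseline", ]
    w <- p[p$analyte == "VEGF" & p$timepoint == "W6D1", ]
    median(w$value[match(b$patient_id, w$patient_id)] / b$value)
  }, numeric(1))
  expect_lt(abs(mean(meds) - 1.6) / 1.6, 0.10)
})

test_that("planted detection rates fall within binomial 99% bands", {
  rates <- c(baseline = 4 / 13, W6D1 = 6 / 14, PostTx = 5 / 16, PostSx = 1 / 11)
  n_rep <- 1000L
  hits <- matrix(0, n_rep, 4, dimnames = list(NULL, names(rates)))
  for (s in seq_len(n_rep)) {
    coh <- generate_cohort(17, seed = 20000 + s)
    agg <- tapply(coh$flags$detected, coh$flags$timepoint, mean)
    hits[s, ] <- agg[colnames(hits)]
  }
  emp <- colMeans(hits)
  n_tot <- n_rep * 17
  for (tp in names(rates)) {
    band <- 2.576 * sqrt(rates[[tp]] * (1 - rates[[tp]]) / n_tot)
    expect_lt(abs(emp[[tp]] - rates[[tp]]), band + 1e-12)
  }
})

test_that("impossible cohort effects are rejected", {
  expect_error(cohort_effects(detection_rates = c(baseline = 1.2)), "\\[0, 1\\]")
  expect_error(cohort_effects(pr_change_range = c(-20, -10)), "-30")
  expect_error(generate_cohort(5, cohort_effects(n_pr = 6)), "exceeds")
})

test_that("cohort bundle writes reproducibly", {
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(generate_cohort(17, seed = 3), d1)
  write_cohort(generate_cohort(17, seed = 3), d2)
  for (f in c("lesions.csv", "panel.csv", "flags.csv", "survival.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})
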