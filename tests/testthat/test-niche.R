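# Density grids, niche detection and coverage: checked against brute-force
# window recounts and the generator's planted truth.

square_mask <- function(mm) {
  tumor_mask(cbind(c(0, mm, mm, 0) * 1000, c(0, 0, mm, mm) * 1000))
}

test_that("a single cell at a window center counts once with density 1", {
  mask <- square_mask(3)
  ph <- make_pheno(1500, 1500, "MHCII")
  g <- density_grid(ph, mask, niche_params())
  w <- g[g$cx_um == 1500 & g$cy_um == 1500, ]
  expect_equal(w$n_mhc2, 1L)
  expect_equal(w$dens_mhc2, 1 / 1.0)
  expect_equal(sum(g$n_tcf1cd8), 0L)
})

test_that("disjoint tiles reproduce total in-mask counts exactly", {
  set.seed(5)
  n <- 2000
  ph <- make_pheno(runif(n, 0, 4000), runif(n, 0, 4000),
                   sample(c("MHCII", "TCF1_CD8"), n, replace = TRUE))
  mask <- square_mask(4)
  g <- density_grid(ph, mask, niche_params(mode = "tiles"))
  expect_equal(sum(g$n_mhc2), sum(ph$pheno_MHCII))
  expect_equal(sum(g$n_tcf1cd8), sum(ph$pheno_TCF1_CD8))
})

test_that("window counts equal the brute-force recount on random tissues", {
  for (s in 1:3) {
    set.seed(s)
    n <- c(500, 3000, 10000)[s]
    ph <- make_pheno(runif(n, 0, 4000), runif(n, 0, 4000),
                     sample(c("MHCII", "TCF1_CD8", "other"), n, replace = TRUE))
    mask <- square_mask(4)
    p <- niche_params(stride_um = c(250, 500, 1000)[s])
    g <- density_grid(ph, mask, p)
    cx <- sort(unique(g$cx_um)); cy <- sort(unique(g$cy_um))
    keep <- ph$pheno_MHCII
    oc <- oracle_window_counts(ph$x_um[keep], ph$y_um[keep], cx, cy, p$side_um)
    got <- matrix(g$n_mhc2, nrow = length(cx))  # grid rows: cx fastest
    expect_identical(got, oc + 0L)
  }
})

test_that("homogeneous Poisson tissue gives window counts near the mean", {
  ts <- tissue_spec(width_um = 5000, height_um = 5000, seed = 8,
                    background_density = c(MHCII = 16))
  tt <- generate_tissue(ts)
  ph <- call_phenotypes(tt$cells, c(DAPI = 1, CD4 = 50, CD8 = 50,
                                    MHCII = 50, TCF1 = 50))
  g <- density_grid(ph, tt$mask, niche_params())
  full <- g[g$area_mm2 > 0.999, ]
  expect_lt(abs(mean(full$n_mhc2) - 16), 3 * sqrt(16) / sqrt(nrow(full)) + 1)
})

test_that("niche conjunction fails when either phenotype is absent", {
  set.seed(9)
  ph <- make_pheno(runif(3000, 0, 4000), runif(3000, 0, 4000), "MHCII")
  nm <- detect_niches(ph, square_mask(4))  # 187/mm^2 MHC-II, 0 TCF1+CD8+
  expect_equal(nm$coverage, 0)
  expect_equal(nm$niche_area_mm2, 0)
})

test_that("coverage is monotonically non-increasing in both thresholds", {
  ts <- tissue_spec(seed = 13, niche_specs = list(
    list(cx_um = 2000, cy_um = 2000, radius_um = 700,
         mhc2_per_mm2 = 32, tcf1cd8_per_mm2 = 12)))
  tt <- generate_tissue(ts)
  ph <- call_phenotypes(tt$cells)
  cov <- function(m, t) detect_niches(ph, tt$mask,
                                      niche_params(mhc2_min_per_mm2 = m,
                                                   tcf1cd8_min_per_mm2 = t))$coverage
  base <- cov(16, 4)
  expect_lte(cov(32, 4), base)
  expect_lte(cov(16, 8), base)
  expect_lte(cov(32, 8), min(cov(32, 4), cov(16, 8)))
  expect_true(base >= 0 && base <= 1)
})

test_that("planted 1-mm^2 discs are recovered within the stated tolerance", {
  # single-tissue coverage is Poisson-noisy at the niche boundary, so the
  # check averages relative error across replicate tissues
  errs <- vapply(1:8, function(s) {
    ts <- tissue_spec(seed = 300 + s, niche_specs = list(
      list(cx_um = 2000, cy_um = 2000, radius_um = sqrt(1e6 / pi),
           mhc2_per_mm2 = 32, tcf1cd8_per_mm2 = 12)))
    tt <- generate_tissue(ts)
    nm <- detect_niches(call_phenotypes(tt$cells), tt$mask)
    nm$coverage / tt$truth$planted_coverage - 1
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.25)
})

test_that("translation leaves counts and coverage unchanged", {
  ts <- tissue_spec(seed = 19, niche_specs = list(
    list(cx_um = 2000, cy_um = 2000, radius_um = 600,
         mhc2_per_mm2 = 32, tcf1cd8_per_mm2 = 12)))
  tt <- generate_tissue(ts)
  ph <- call_phenotypes(tt$cells)
  nm1 <- detect_niches(ph, tt$mask)

  shift <- c(1234.5, -987.25)
  ph2 <- ph
  ph2$x_um <- ph2$x_um + shift[1]
  ph2$y_um <- ph2$y_um + shift[2]
  rings <- lapply(tt$mask$polygons[[1]], function(r) {
    cbind(r[, 1] + shift[1], r[, 2] + shift[2])
  })
  nm2 <- detect_niches(ph2, tumor_mask(list(rings)))
  expect_equal(nm2$grid$n_mhc2, nm1$grid$n_mhc2)
  expect_equal(nm2$grid$n_tcf1cd8, nm1$grid$n_tcf1cd8)
  expect_equal(nm2$coverage, nm1$coverage, tolerance = 1e-12)
})

test_that("halving the stride changes coverage only within the edge bound", {
  # deterministic lattice tissue (no Poisson noise) isolates the pure
  # window-discretization effect the bound is about
  lattice_in_disc <- function(spacing, cx, cy, r) {
    g <- expand.grid(x = seq(spacing / 2, 4000, by = spacing),
                     y = seq(spacing / 2, 4000, by = spacing))
    g[(g$x - cx)^2 + (g$y - cy)^2 <= r^2, ]
  }
  r <- sqrt(2e6 / pi)  # 2 mm^2: perimeter/area low enough for the bound
  mh <- lattice_in_disc(sqrt(1e6 / 32), 2000, 2000, r)   # 32 / mm^2
  tc <- lattice_in_disc(sqrt(1e6 / 12), 2000, 2000, r)   # 12 / mm^2
  ph <- make_pheno(c(mh$x, tc$x), c(mh$y, tc$y),
                   rep(c("MHCII", "TCF1_CD8"), c(nrow(mh), nrow(tc))))
  mask <- square_mask(4)
  c250 <- detect_niches(ph, mask, niche_params(stride_um = 250))$coverage
  c125 <- detect_niches(ph, mask, niche_params(stride_um = 125))$coverage
  expect_lt(abs(c125 - c250) / c250, 0.10)
})

test_that("a mask that misses every window raises a geometry error", {
  ph <- make_pheno(numeric(0), numeric(0), character(0))
  expect_error(density_grid(ph, square_mask(2),
                            niche_params(min_window_overlap = 1)),
               NA)  # full-overlap windows exist for an aligned square
  expect_error(niche_params(stride_um = 2000), "stride")
  expect_error(niche_params(mhc2_min_per_mm2 = 0), "> 0")
})
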