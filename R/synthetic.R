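# Synthetic tissues and clinical/assay cohorts with known ground truth.
#
# The tissue generator plants an inhomogeneous Poisson point pattern: a
# background intensity per phenotype over the tumor polygon, plus hard
# circular niche discs inside which the MHC-II+ and TCF1+CD8+ intensities
# are raised to stated per-mm^2 values. Hard discs keep the true niche
# coverage analytic (union of disc areas clipped to the tumor), which is
# what downstream acceptance tests compare against. Where discs overlap,
# the max (not the sum) of their densities applies, so the planted region
# is exactly the union of the discs.

# Canonical marker and phenotype vocabularies.
MARKERS <- c("DAPI", "CD4", "CD8", "MHCII", "TCF1")
PHENOTYPES <- c("CD4", "CD8", "MHCII", "TCF1_CD8", "other")

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Specify a synthetic tissue
#'
#' @param width_um,height_um Frame extent in micrometres.
#' @param tumor_polygon Tumor outline; anything accepted by [tumor_mask()].
#'   Default: the full frame rectangle.
#' @param background_density Named numeric vector, cells per mm^2 per
#'   phenotype (names among `CD4`, `CD8`, `MHCII`, `TCF1_CD8`, `other`).
#' @param niche_specs List of niche discs, each a list with `cx_um`, `cy_um`,
#'   `radius_um`, `mhc2_per_mm2`, `tcf1cd8_per_mm2`.
#' @param intensity_model Named list per marker with `positive_mean`,
#'   `negative_mean`, `sd` (arbitrary fluorescence units). The default puts
#'   positive and negative populations > 10 sd apart so threshold
#'   phenotyping recovers planted labels.
#' @param seed Integer RNG seed.
#' @return An object of class `tissue_spec`.
#' @export
tissue_spec <- function(width_um = 4000, height_um = 4000,
                        tumor_polygon = NULL,
                        background_density = c(CD4 = 50, CD8 = 50, MHCII = 8,
                                               TCF1_CD8 = 1, other = 400),
                        niche_specs = list(),
                        intensity_model = default_intensity_model(),
                        seed = 1L) {
  if (is.null(tumor_polygon)) {
    tumor_polygon <- cbind(c(0, width_um, width_um, 0),
                           c(0, 0, height_um, height_um))
  }
  mask <- tumor_mask(tumor_polygon)
  bd <- background_density
  if (is.null(names(bd)) || !all(names(bd) %in% PHENOTYPES)) {
    stop("background_density must be named with phenotypes among: ",
         paste(PHENOTYPES, collapse = ", "), call. = FALSE)
  }
  if (any(bd < 0)) stop("densities must be >= 0", call. = FALSE)
  for (ns in niche_specs) {
    need <- c("cx_um", "cy_um", "radius_um", "mhc2_per_mm2", "tcf1cd8_per_mm2")
    if (!all(need %in% names(ns))) {
      stop("each niche spec needs fields: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (ns$radius_um <= 0 || ns$mhc2_per_mm2 < 0 || ns$tcf1cd8_per_mm2 < 0) {
      stop("niche radius must be > 0 and densities >= 0", call. = FALSE)
    }
  }
  structure(
    list(width_um = width_um, height_um = height_um, mask = mask,
         background_density = bd, niche_specs = niche_specs,
         intensity_model = intensity_model, seed = as.integer(seed)),
    class = "tissue_spec"
  )
}

#' Default per-marker fluorescence intensity model
#'
#' Gaussian positive/negative populations floored at zero; only the order
#' statistics matter for thresholding, so the shapes are deliberately simple.
#'
#' @return Named list per marker.
#' @export
default_intensity_model <- function() {
  one <- list(positive_mean = 100, negative_mean = 10, sd = 8)
  stats::setNames(rep(list(one), length(MARKERS)), MARKERS)
}

# Disc density of phenotype `pheno` ("MHCII" or "TCF1_CD8") at points,
# 0 where no disc covers the point.
disc_density_at <- function(spec, pheno, px, py) {
  key <- if (pheno == "MHCII") "mhc2_per_mm2" else "tcf1cd8_per_mm2"
  dens <- numeric(length(px))
  covered <- logical(length(px))
  for (ns in spec$niche_specs) {
    inside <- (px - ns$cx_um)^2 + (py - ns$cy_um)^2 <= ns$radius_um^2
    dens[inside] <- pmax(dens[inside], ns[[key]])
    covered <- covered | inside
  }
  list(density = dens, covered = covered)
}

# Sample one phenotype's point pattern by thinning a homogeneous Poisson
# process at the maximal intensity over the frame bounding box.
sample_phenotype_points <- function(spec, pheno) {
  bg <- if (pheno %in% names(spec$background_density)) {
    unname(spec$background_density[[pheno]])
  } else 0
  disc_max <- 0
  if (pheno %in% c("MHCII", "TCF1_CD8") && length(spec$niche_specs) > 0) {
    key <- if (pheno == "MHCII") "mhc2_per_mm2" else "tcf1cd8_per_mm2"
    disc_max <- max(vapply(spec$niche_specs, function(ns) ns[[key]], numeric(1)))
  }
  lam_max <- max(bg, disc_max)  # cells per mm^2
  if (lam_max <= 0) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0)))
  }
  bbox <- mask_bbox(spec$mask)
  area_mm2 <- (bbox[3] - bbox[1]) * (bbox[4] - bbox[2]) / 1e6
  n <- stats::rpois(1, lam_max * area_mm2)
  if (n == 0) return(data.frame(x_um = numeric(0), y_um = numeric(0)))
  px <- stats::runif(n, bbox[1], bbox[3])
  py <- stats::runif(n, bbox[2], bbox[4])
  keep <- points_in_mask(spec$mask, px, py)
  # local intensity: disc density where covered, else background
  if (pheno %in% c("MHCII", "TCF1_CD8")) {
    dd <- disc_density_at(spec, pheno, px, py)
    lam <- ifelse(dd$covered, dd$density, bg)
  } else {
    lam <- rep(bg, n)
  }
  keep <- keep & (stats::runif(n) < lam / lam_max)
  data.frame(x_um = px[keep], y_um = py[keep])
}

# Draw a marker intensity vector: Gaussian by positivity, floored at 0.
draw_intensity <- function(model, positive) {
  mu <- ifelse(positive, model$positive_mean, model$negative_mean)
  pmax(0, stats::rnorm(length(positive), mean = mu, sd = model$sd))
}

#' Generate a synthetic tissue section
#'
#' Produces a per-cell coordinate + marker-intensity table, the tumor mask,
#' and a ground-truth record (planted niche raster, coverage and counts)
#' against which phenotype calling and niche detection can be validated.
#'
#' @param spec A [tissue_spec()].
#' @param niche_thresholds Densities a planted disc must reach to count as a
#'   true niche in the ground truth (defaults: 16 MHC-II+ and 4 TCF1+CD8+
#'   cells per mm^2, the canonical niche definition).
#' @param truth_raster_um Resolution of the ground-truth niche raster.
#' @return A list of class `synthetic_tissue`: `cells` (data.frame
#'   `cell_id, x_um, y_um, <marker>_intensity`), `mask` ([tumor_mask()]),
#'   `truth` (list with `planted_coverage`, `planted_counts`, `niche_raster`,
#'   `phenotype` per cell).
#' @examples
#' ts <- tissue_spec(seed = 7, niche_specs = list(
#'   list(cx_um = 2000, cy_um = 2000, radius_um = 564.2,
#'        mhc2_per_mm2 = 40, tcf1cd8_per_mm2 = 10)))
#' tissue <- generate_tissue(ts)
#' tissue$truth$planted_coverage
#' @export
generate_tissue <- function(spec,
                            niche_thresholds = c(mhc2 = 16, tcf1cd8 = 4),
                            truth_raster_um = 25) {
  stopifnot(inherits(spec, "tissue_spec"))
  with_seed(spec$seed, {
    pts <- lapply(PHENOTYPES, function(p) {
      d <- sample_phenotype_points(spec, p)
      if (nrow(d) > 0) d$phenotype <- p
      d
    })
    pts <- do.call(rbind, pts[vapply(pts, nrow, integer(1)) > 0])
    if (is.null(pts) || nrow(pts) == 0) {
      pts <- data.frame(x_um = numeric(0), y_um = numeric(0),
                        phenotype = character(0))
    }
    n <- nrow(pts)
    cells <- data.frame(cell_id = if (n > 0) sprintf("c%05d", seq_len(n)) else character(0),
                        x_um = pts$x_um, y_um = pts$y_um)
    ph <- pts$phenotype
    positive <- list(
      DAPI  = rep(TRUE, n),
      CD4   = ph == "CD4",
      CD8   = ph %in% c("CD8", "TCF1_CD8"),
      MHCII = ph == "MHCII",
      TCF1  = ph == "TCF1_CD8"
    )
    for (m in MARKERS) {
      cells[[paste0(m, "_intensity")]] <-
        draw_intensity(spec$intensity_model[[m]], positive[[m]])
    }
    truth <- tissue_truth(spec, ph, niche_thresholds, truth_raster_um)
    structure(list(cells = cells, mask = spec$mask, truth = truth, spec = spec),
              class = "synthetic_tissue")
  })
}

# Ground truth: raster of the union of qualifying discs clipped to the tumor.
tissue_truth <- function(spec, phenotype_labels, niche_thresholds, raster_um) {
  qualifying <- Filter(function(ns) {
    ns$mhc2_per_mm2 >= niche_thresholds[["mhc2"]] &&
      ns$tcf1cd8_per_mm2 >= niche_thresholds[["tcf1cd8"]]
  }, spec$niche_specs)
  bbox <- mask_bbox(spec$mask)
  gx <- seq(bbox[1] + raster_um / 2, bbox[3], by = raster_um)
  gy <- seq(bbox[2] + raster_um / 2, bbox[4], by = raster_um)
  g <- expand.grid(x = gx, y = gy)
  in_tumor <- points_in_mask(spec$mask, g$x, g$y)
  in_niche <- logical(nrow(g))
  for (ns in qualifying) {
    in_niche <- in_niche |
      ((g$x - ns$cx_um)^2 + (g$y - ns$cy_um)^2 <= ns$radius_um^2)
  }
  in_niche <- in_niche & in_tumor
  coverage <- if (any(in_tumor)) sum(in_niche) / sum(in_tumor) else 0
  list(
    planted_coverage = coverage,
    planted_niche_area_mm2 = sum(in_niche) * raster_um^2 / 1e6,
    planted_counts = table(factor(phenotype_labels, levels = PHENOTYPES)),
    phenotype = phenotype_labels,
    niche_raster = list(x = gx, y = gy,
                        niche = matrix(in_niche, nrow = length(gx)),
                        tumor = matrix(in_tumor, nrow = length(gx)),
                        raster_um = raster_um)
  )
}

# ---------------------------------------------------------------------------
# Clinical / assay cohort generation

ASSAY_TIMEPOINTS <- c("baseline", "W6D1", "PostTx", "PostSx")
LESION_TIMEPOINTS <- c("baseline", "week6", "week12")

#' Cohort-level effect parameters for the synthetic generator
#'
#' Defaults restate the trial's stated world: 17 patients, 6 partial
#' responses, baseline primary-tumor sizes 3.31-24.41 cm, week-12 reductions
#' of 8-42 percent (every patient shrank), a planted 1.6-fold median analyte
#' rise at W6D1 for treatment-responsive markers, ctDNA detection rates of
#' 4/13, 6/14, 5/16 and 1/11 across the four sampling timepoints, and
#' one-year disease-free survival near 82 percent.
#'
#' @param n_pr Number of patients planted as partial responders.
#' @param baseline_size_range_cm Range of baseline target-lesion sums.
#' @param pr_change_range,sd_change_range Week-12 percent-change ranges for
#'   PR and SD patients (PR range must lie at or below -30).
#' @param week6_fraction_range Week-6 change as a fraction of week-12 change.
#' @param analyte_fold Named list: per analyte, named vector of planted
#'   median fold changes versus baseline at `W6D1`, `PostTx`, `PostSx`.
#' @param analyte_sdlog Log-normal sd of per-patient fold changes.
#' @param detection_rates Named per-timepoint ctDNA detection probabilities.
#' @param dfs_1yr,os_1yr Planted one-year survival fractions.
#' @param followup_months Administrative censoring time.
#' @return A list of class `cohort_effects`.
#' @export
cohort_effects <- function(
    n_pr = 6,
    baseline_size_range_cm = c(3.31, 24.41),
    pr_change_range = c(-42, -30),
    sd_change_range = c(-29, -8),
    week6_fraction_range = c(0.3, 0.8),
    analyte_fold = list(
      VEGF   = c(W6D1 = 1.6, PostTx = 1.6, PostSx = 1.1),
      cMET   = c(W6D1 = 1.4, PostTx = 1.2, PostSx = 1.2),
      Gas6   = c(W6D1 = 1.3, PostTx = 1.2, PostSx = 1.3),
      AXL    = c(W6D1 = 1.3, PostTx = 1.3, PostSx = 1.1),
      HGF    = c(W6D1 = 1.0, PostTx = 1.0, PostSx = 1.0),
      VEGFR2 = c(W6D1 = 0.7, PostTx = 0.6, PostSx = 0.9),
      cfDNA  = c(W6D1 = 1.6, PostTx = 1.5, PostSx = 1.0)
    ),
    analyte_sdlog = 0.25,
    detection_rates = c(baseline = 4 / 13, W6D1 = 6 / 14,
                        PostTx = 5 / 16, PostSx = 1 / 11),
    dfs_1yr = 0.824, os_1yr = 0.941,
    followup_months = 25) {
  if (any(detection_rates < 0 | detection_rates > 1)) {
    stop("detection rates must lie in [0, 1]", call. = FALSE)
  }
  if (dfs_1yr <= 0 || dfs_1yr > 1 || os_1yr <= 0 || os_1yr > 1) {
    stop("survival fractions must lie in (0, 1]", call. = FALSE)
  }
  if (max(pr_change_range) > -30) {
    stop("PR change range must lie at or below -30 percent", call. = FALSE)
  }
  for (a in analyte_fold) {
    if (any(a <= 0)) stop("planted fold changes must be > 0", call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_effects")
}

#' Generate a synthetic trial cohort
#'
#' Draws per-patient lesion series (with a planted number of RECIST partial
#' responses), baseline-anchored analyte trajectories with planted median
#' fold changes, per-timepoint ctDNA detection flags, and survival times.
#'
#' @param n_patients Number of patients (>= 1).
#' @param effects A [cohort_effects()] object.
#' @param seed Integer RNG seed.
#' @return A list of class `synthetic_cohort` with data.frames `lesions`
#'   (`patient_id, timepoint, sum_diameters_cm`), `panel`
#'   (`patient_id, timepoint, analyte, value`), `flags`
#'   (`patient_id, timepoint, detected`), `survival`
#'   (`patient_id, time_months, event, endpoint`), and a `truth` list.
#' @examples
#' coh <- generate_cohort(17, seed = 1)
#' table(coh$truth$planted_response)
#' @export
generate_cohort <- function(n_patients = 17, effects = cohort_effects(),
                            seed = 1L) {
  stopifnot(inherits(effects, "cohort_effects"))
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (effects$n_pr > n_patients) {
    stop("planted PR count exceeds cohort size", call. = FALSE)
  }
  with_seed(seed, {
    ids <- sprintf("P%02d", seq_len(n_patients))
    is_pr <- seq_len(n_patients) <= effects$n_pr

    baseline <- stats::runif(n_patients, effects$baseline_size_range_cm[1],
                             effects$baseline_size_range_cm[2])
    chg12 <- ifelse(
      is_pr,
      stats::runif(n_patients, effects$pr_change_range[1], effects$pr_change_range[2]),
      stats::runif(n_patients, effects$sd_change_range[1], effects$sd_change_range[2])
    )
    frac6 <- stats::runif(n_patients, effects$week6_fraction_range[1],
                          effects$week6_fraction_range[2])
    chg6 <- chg12 * frac6
    lesions <- data.frame(
      patient_id = rep(ids, each = 3),
      timepoint = rep(LESION_TIMEPOINTS, n_patients),
      sum_diameters_cm = as.vector(rbind(baseline,
                                         baseline * (1 + chg6 / 100),
                                         baseline * (1 + chg12 / 100)))
    )

    analytes <- names(effects$analyte_fold)
    panel <- do.call(rbind, lapply(analytes, function(a) {
      base_val <- stats::rlnorm(n_patients, meanlog = log(100), sdlog = 0.5)
      med <- effects$analyte_fold[[a]]
      vals <- cbind(
        baseline = base_val,
        W6D1   = base_val * stats::rlnorm(n_patients, log(med[["W6D1"]]), effects$analyte_sdlog),
        PostTx = base_val * stats::rlnorm(n_patients, log(med[["PostTx"]]), effects$analyte_sdlog),
        PostSx = base_val * stats::rlnorm(n_patients, log(med[["PostSx"]]), effects$analyte_sdlog)
      )
      data.frame(
        patient_id = rep(ids, times = 4),
        timepoint = rep(ASSAY_TIMEPOINTS, each = n_patients),
        analyte = a,
        value = as.vector(vals)
      )
    }))

    flags <- do.call(rbind, lapply(ASSAY_TIMEPOINTS, function(tp) {
      data.frame(patient_id = ids, timepoint = tp,
                 detected = stats::runif(n_patients) < effects$detection_rates[[tp]])
    }))

    surv <- do.call(rbind, lapply(c(DFS = "DFS", OS = "OS"), function(ep) {
      s1 <- if (ep == "DFS") effects$dfs_1yr else effects$os_1yr
      rate <- -log(s1) / 12  # per month
      t_event <- stats::rexp(n_patients, rate)
      time <- pmin(t_event, effects$followup_months)
      data.frame(patient_id = ids, time_months = time,
                 event = as.integer(t_event <= effects$followup_months),
                 endpoint = ep)
    }))
    rownames(surv) <- NULL

    truth <- list(
      planted_response = stats::setNames(ifelse(is_pr, "PR", "SD"), ids),
      planted_changes = data.frame(patient_id = ids, week6 = chg6, week12 = chg12),
      cohort_effects = effects,
      planted_detection_rates = effects$detection_rates
    )
    structure(list(lesions = lesions, panel = panel, flags = flags,
                   survival = surv, truth = truth, seed = as.integer(seed)),
              class = "synthetic_cohort")
  })
}
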