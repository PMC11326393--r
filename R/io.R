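# CSV dialects, schema validation and bundled trial summary tables.
#
# Column contracts:
#   cell table:  cell_id, x_um, y_um, <marker>_intensity...
#   lesions:     patient_id, timepoint, sum_diameters_cm
#   panel:       patient_id, timepoint, analyte, value
#   flags:       patient_id, timepoint, detected
#   variants:    patient_id, timepoint, gene, nt_change, aa_change, vaf_percent
#   survival:    patient_id, time_months, event, endpoint
#   AE records:  patient_id, term, grade

#' Read / write a per-cell coordinate + intensity table
#'
#' @param path CSV path.
#' @return Data.frame with `cell_id`, `x_um`, `y_um` and one
#'   `<marker>_intensity` column per marker.
#' @export
read_cell_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("cell_id", "x_um", "y_um")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    stop("cell table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!any(grepl("_intensity$", names(d)))) {
    stop("cell table ", path, " has no <marker>_intensity columns",
         call. = FALSE)
  }
  d
}

#' @rdname read_cell_table
#' @param cells Cell table data.frame.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_checked_csv <- function(path, need, what) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    stop(what, " table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d
}

#' Readers for the clinical/assay CSV dialects
#'
#' @param path CSV path.
#' @return A validated data.frame.
#' @export
read_lesions <- function(path) {
  read_checked_csv(path, c("patient_id", "timepoint", "sum_diameters_cm"),
                   "lesion")
}

#' @rdname read_lesions
#' @export
read_panel <- function(path) {
  read_checked_csv(path, c("patient_id", "timepoint", "analyte", "value"),
                   "assay panel")
}

#' @rdname read_lesions
#' @export
read_flags <- function(path) {
  d <- read_checked_csv(path, c("patient_id", "timepoint", "detected"),
                        "detection-flag")
  d$detected <- as.logical(d$detected)
  d
}

#' @rdname read_lesions
#' @export
read_variants <- function(path) {
  read_checked_csv(path, c("patient_id", "timepoint", "gene", "nt_change",
                           "aa_change", "vaf_percent"), "variant")
}

#' @rdname read_lesions
#' @export
read_survival <- function(path) {
  read_checked_csv(path, c("patient_id", "time_months", "event", "endpoint"),
                   "survival")
}

#' Write a synthetic tissue bundle to disk
#'
#' Writes `cells.csv`, `mask.geojson`, `truth_niche.geojson` (the planted
#' niche region) and `params.json` (the generation parameters, seed
#' included) into `dir`.
#'
#' @param tissue A `synthetic_tissue` from [generate_tissue()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tissue <- function(tissue, dir) {
  stopifnot(inherits(tissue, "synthetic_tissue"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cell_table(tissue$cells, file.path(dir, "cells.csv"))
  write_mask_geojson(tissue$mask, file.path(dir, "mask.geojson"))
  rr <- raster_row_runs(list(
    x = tissue$truth$niche_raster$x, y = tissue$truth$niche_raster$y,
    covered = tissue$truth$niche_raster$niche,
    stride_um = tissue$truth$niche_raster$raster_um))
  feats <- if (length(rr) > 0) {
    list(geojson_feature(multipolygon_geometry(lapply(rr, list)),
                         list(layer = "planted_niche", units = "um")))
  } else list()
  write_feature_collection(feats, file.path(dir, "truth_niche.geojson"))
  spec <- tissue$spec
  params <- list(
    width_um = spec$width_um, height_um = spec$height_um,
    background_density = as.list(spec$background_density),
    niche_specs = spec$niche_specs, seed = spec$seed,
    planted_coverage = tissue$truth$planted_coverage
  )
  jsonlite::write_json(params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a synthetic cohort bundle to disk
#'
#' Writes `lesions.csv`, `panel.csv`, `flags.csv`, `survival.csv` and
#' `params.json` into `dir`.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$lesions, file.path(dir, "lesions.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$panel, file.path(dir, "panel.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$flags, file.path(dir, "flags.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$survival, file.path(dir, "survival.csv"),
                   row.names = FALSE, quote = FALSE)
  eff <- cohort$truth$cohort_effects
  params <- list(
    n_patients = length(unique(cohort$lesions$patient_id)),
    n_pr = eff$n_pr, detection_rates = as.list(eff$detection_rates),
    seed = cohort$seed
  )
  jsonlite::write_json(params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# ---------------------------------------------------------------------------
# Bundled trial summary tables (transcribed published marginals)

#' Published summary tables of the NCT04022343 trial
#'
#' Plain-text transcriptions of the published per-patient best responses,
#' the somatic ctDNA variant table, the per-timepoint ctDNA detection
#' counts, and the treatment-related adverse-event marginals of the phase 2
#' neoadjuvant cabozantinib ccRCC trial. These printed tables are the
#' desk-reproducible inputs for the clinical and correlative worked
#' examples; patient-level image data are not public.
#'
#' @return A list of data.frames: `best_response` (17 patients), `variants`
#'   (9 rows), `detection_counts` (`timepoint, k, n`), `adverse_events`
#'   (per-term any-grade and grade >= 3 patient counts; denominator 17).
#' @export
trial_tables <- function() {
  p <- function(f) system.file("extdata", f, package = "immuniche",
                               mustWork = TRUE)
  list(
    best_response = utils::read.csv(p("trial_best_response.csv"),
                                    stringsAsFactors = FALSE),
    variants = read_variants(p("trial_ctdna_variants.csv")),
    detection_counts = utils::read.csv(p("trial_ctdna_detection_counts.csv"),
                                       stringsAsFactors = FALSE),
    adverse_events = utils::read.csv(p("trial_adverse_events.csv"),
                                     stringsAsFactors = FALSE)
  )
}

#' Expand per-timepoint detection counts into per-sample flags
#'
#' The published detection summary reports k detected of n assayed per
#' timepoint; per-sample identities are synthetic (s1, s2, ...) since the
#' published table is a marginal. Rates computed from the expansion equal
#' the printed rates exactly.
#'
#' @param counts Data.frame `timepoint, k, n`.
#' @return Data.frame `patient_id, timepoint, detected`.
#' @export
detection_flags_from_counts <- function(counts) {
  do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    n <- counts$n[i]; k <- counts$k[i]
    data.frame(patient_id = sprintf("s%02d", seq_len(n)),
               timepoint = counts$timepoint[i],
               detected = seq_len(n) <= k)
  }))
}

#' Expand per-term adverse-event marginals into patient-level records
#'
#' Synthetic reconstruction: for each term, the first `n_grade3plus`
#' patients receive grade 3 and the remainder grade 1. Per-term counts and
#' percentages are preserved exactly; cross-term patient overlap is
#' arbitrary (the published table is a marginal).
#'
#' @param ae_counts Data.frame `term, n_any, n_grade3plus`.
#' @return Data.frame `patient_id, term, grade`.
#' @export
ae_records_from_counts <- function(ae_counts) {
  do.call(rbind, lapply(seq_len(nrow(ae_counts)), function(i) {
    n <- ae_counts$n_any[i]
    if (n == 0) return(NULL)
    g3 <- ae_counts$n_grade3plus[i]
    data.frame(patient_id = sprintf("P%02d", seq_len(n)),
               term = ae_counts$term[i],
               grade = ifelse(seq_len(n) <= g3, 3L, 1L))
  }))
}
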