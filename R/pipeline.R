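# Configuration, input validation and the pipeline driver:
# simulate -> phenotype -> niches -> clinical -> correlate -> report.
#
# A run is fully described by one JSON-serializable config; every artifact
# carries a provenance block (config hash, seed, package version), and a
# rerun with the same config is byte-identical.

#' Assemble a pipeline configuration
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Master RNG seed for the simulate stage.
#' @param n_patients Cohort size for the simulate stage.
#' @param inputs Optional named list of input paths (`cells`, `mask`,
#'   `lesions`, `panel`, `flags`, `variants`, `survival`). Any that are NULL
#'   are produced by the simulate stage instead.
#' @param niche A [niche_params()] object.
#' @param thresholds Phenotype thresholds: `"auto"` or a named vector.
#' @param design A [two_stage_design()] object.
#' @param tissue A [tissue_spec()] or NULL for the default synthetic tissue
#'   (one planted 1-mm^2 niche disc above both thresholds).
#' @param effects A [cohort_effects()] object.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("immuniche_run_"),
                            seed = 1L, n_patients = 17L, inputs = list(),
                            niche = niche_params(), thresholds = "auto",
                            design = two_stage_design(),
                            tissue = NULL, effects = cohort_effects()) {
  if (is.null(tissue)) {
    tissue <- tissue_spec(
      seed = seed,
      niche_specs = list(list(cx_um = 2000, cy_um = 2000, radius_um = 564.19,
                              mhc2_per_mm2 = 32, tcf1cd8_per_mm2 = 12))
    )
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         n_patients = as.integer(n_patients), inputs = inputs,
         niche = niche, thresholds = thresholds, design = design,
         tissue = tissue, effects = effects),
    class = "pipeline_config"
  )
}

# Stable hash of the config for provenance: md5 of its serialized JSON.
# The output directory is excluded so that identical analyses written to
# different locations hash identically.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  ser <- jsonlite::serializeJSON(cfg, digits = 12)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(ser, tf)
  unname(tools::md5sum(tf))
}

log_stage <- function(stage, msg, quiet) {
  if (!quiet) message(sprintf("[%s] %s | %s", format(Sys.time(), "%H:%M:%S"),
                              stage, msg))
}

#' Validate pipeline input files
#'
#' Schema-checks every configured input CSV/GeoJSON and applies unit sanity
#' rules: cell coordinates (um) should span more than 100 um, and lesion
#' diameter sums (cm) should be below 50. Violations carry a severity:
#' `fatal` violations make the config unrunnable, `warning` ones do not.
#'
#' @param config A [pipeline_config()].
#' @return Data.frame of class `validation_report` with columns `file`,
#'   `row`, `severity`, `message` (zero rows when everything passes).
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  v <- list()
  add <- function(file, row, severity, message) {
    v[[length(v) + 1L]] <<- data.frame(file = file, row = row,
                                       severity = severity, message = message)
  }
  ip <- config$inputs
  for (nm in names(ip)) {
    if (!is.null(ip[[nm]]) && !file.exists(ip[[nm]])) {
      add(ip[[nm]], NA_integer_, "fatal", paste0("missing input file (", nm, ")"))
    }
  }
  check <- function(nm, reader) {
    if (is.null(ip[[nm]]) || !file.exists(ip[[nm]])) return(NULL)
    tryCatch(reader(ip[[nm]]),
             error = function(e) {
               add(ip[[nm]], NA_integer_, "fatal", conditionMessage(e))
               NULL
             })
  }
  cells <- check("cells", read_cell_table)
  if (!is.null(cells) && nrow(cells) > 1) {
    span <- max(diff(range(cells$x_um)), diff(range(cells$y_um)))
    if (span <= 100) {
      add(ip$cells, NA_integer_, "warning",
          sprintf("coordinate span %.1f um <= 100 um: are units really um?",
                  span))
    }
  }
  lesions <- check("lesions", read_lesions)
  if (!is.null(lesions)) {
    bad <- which(lesions$sum_diameters_cm >= 50)
    for (r in bad) {
      add(ip$lesions, r, "warning",
          sprintf("diameter sum %.1f cm >= 50: cm/mm confusion?",
                  lesions$sum_diameters_cm[r]))
    }
  }
  check("panel", read_panel)
  check("flags", read_flags)
  check("variants", read_variants)
  check("survival", read_survival)
  if (!is.null(ip$mask) && file.exists(ip$mask)) {
    tryCatch(read_mask_geojson(ip$mask),
             error = function(e) add(ip$mask, NA_integer_, "fatal",
                                     conditionMessage(e)))
  }
  out <- if (length(v) > 0) do.call(rbind, v) else
    data.frame(file = character(0), row = integer(0),
               severity = character(0), message = character(0))
  class(out) <- c("validation_report", "data.frame")
  out
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> phenotype -> niches -> clinical -> correlate and
#' writes a report bundle (JSON summary plus per-stage CSV/GeoJSON
#' artifacts) under `config$out_dir`. Inputs listed in `config$inputs`
#' replace the corresponding simulated artifacts.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log lines.
#' @return The report (a list), invisibly; written to
#'   `<out_dir>/report.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  vr <- validate_inputs(config)
  if (any(vr$severity == "fatal")) {
    stop("validation failure:\n",
         paste(sprintf("  %s: %s", vr$file[vr$severity == "fatal"],
                       vr$message[vr$severity == "fatal"]), collapse = "\n"),
         call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  provenance <- list(config_hash = hash, seed = config$seed,
                     package = "immuniche",
                     version = as.character(utils::packageVersion("immuniche")))
  run_stage <- function(stage, fn) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fn(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log_stage(stage, sprintf("done in %.2f s", proc.time()[["elapsed"]] - t0),
              quiet)
    out
  }

  # --- simulate ------------------------------------------------------------
  sim <- run_stage("simulate", function() {
    tissue <- if (is.null(config$inputs$cells)) {
      generate_tissue(config$tissue)
    } else NULL
    cohort <- generate_cohort(config$n_patients, config$effects,
                              seed = config$seed)
    cells <- if (is.null(tissue)) read_cell_table(config$inputs$cells) else
      tissue$cells
    mask <- if (!is.null(config$inputs$mask)) {
      read_mask_geojson(config$inputs$mask)
    } else if (!is.null(tissue)) tissue$mask else
      stop("a tumor mask is required when cells are supplied")
    lesions <- if (is.null(config$inputs$lesions)) cohort$lesions else
      read_lesions(config$inputs$lesions)
    panel <- if (is.null(config$inputs$panel)) cohort$panel else
      read_panel(config$inputs$panel)
    flags <- if (is.null(config$inputs$flags)) cohort$flags else
      read_flags(config$inputs$flags)
    survival <- if (is.null(config$inputs$survival)) cohort$survival else
      read_survival(config$inputs$survival)
    variants <- if (is.null(config$inputs$variants)) NULL else
      read_variants(config$inputs$variants)
    list(cells = cells, mask = mask, tissue = tissue, lesions = lesions,
         panel = panel, flags = flags, survival = survival,
         variants = variants)
  })

  # --- phenotype -----------------------------------------------------------
  pheno <- run_stage("phenotype", function() {
    ph <- call_phenotypes(sim$cells, thresholds = config$thresholds)
    utils::write.csv(ph, file.path(config$out_dir, "phenotypes.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      c(provenance, list(thresholds = as.list(attr(ph, "thresholds_used")))),
      file.path(config$out_dir, "thresholds.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ph
  })

  # --- niches --------------------------------------------------------------
  nm <- run_stage("niches", function() {
    nm <- detect_niches(pheno, sim$mask, config$niche)
    utils::write.csv(
      data.frame(cx_um = nm$grid$cx_um, cy_um = nm$grid$cy_um,
                 n_mhc2 = nm$grid$n_mhc2, n_tcf1cd8 = nm$grid$n_tcf1cd8,
                 area_mm2 = nm$grid$area_mm2, is_niche = nm$grid$is_niche),
      file.path(config$out_dir, "niche_grid.csv"),
      row.names = FALSE, quote = FALSE)
    export_immunomap(pheno, nm, sim$mask,
                     file.path(config$out_dir, "immunomap.geojson"))
    nm
  })

  # --- clinical ------------------------------------------------------------
  clinical <- run_stage("clinical", function() {
    resp <- classify_cohort(sim$lesions)
    orr <- orr_with_ci(resp$best_response)
    cbr <- clinical_benefit_rate(resp$best_response)
    oc0 <- simon_oc(config$design, config$design$p0)
    oc1 <- simon_oc(config$design, config$design$p1)
    dfs <- sim$survival[sim$survival$endpoint == "DFS", ]
    km <- km_estimate(dfs$time_months, dfs$event, at_time = 12)
    utils::write.csv(resp, file.path(config$out_dir, "recist.csv"),
                     row.names = FALSE, quote = FALSE)
    list(responses = resp, orr = orr, clinical_benefit = cbr,
         design_oc = list(null = oc0, alternative = oc1),
         dfs_12mo = list(survival = km$survival, ci = km$ci))
  })

  # --- correlate -----------------------------------------------------------
  correlate <- run_stage("correlate", function() {
    fc <- fold_changes(sim$panel)
    tests <- panel_tests(sim$panel, "W6D1")
    rates <- detection_rates(sim$flags)
    pct12 <- stats::setNames(clinical$responses$pct_week12,
                             clinical$responses$patient_id)
    sp <- lapply(split(sim$panel[sim$panel$timepoint == "W6D1", ],
                       sim$panel$analyte[sim$panel$timepoint == "W6D1"]),
                 function(sub) {
                   vals <- stats::setNames(sub$value, sub$patient_id)
                   tryCatch(spearman_vs_tumor_change(vals, pct12),
                            error = function(e) NULL)
                 })
    vs <- if (!is.null(sim$variants)) variant_summary(sim$variants) else NULL
    utils::write.csv(tests, file.path(config$out_dir, "panel_tests.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(rates, file.path(config$out_dir, "detection_rates.csv"),
                     row.names = FALSE, quote = FALSE)
    list(fold_changes = fc, panel_tests = tests, detection_rates = rates,
         spearman_w6 = sp, variants = vs)
  })

  # --- report --------------------------------------------------------------
  report <- list(
    provenance = provenance,
    niche = list(coverage = nm$coverage, niche_area_mm2 = nm$niche_area_mm2,
                 n_windows = nrow(nm$grid), n_niche_windows = sum(nm$grid$is_niche),
                 planted_coverage = if (!is.null(sim$tissue))
                   sim$tissue$truth$planted_coverage else NULL),
    composition = as.list(composition_fractions(pheno)),
    clinical = list(
      best_response = table_to_list(clinical$responses$best_response),
      orr = clinical$orr[c("n", "responders", "rate", "ci")],
      clinical_benefit_rate = clinical$clinical_benefit$rate,
      design_oc = clinical$design_oc,
      dfs_12mo = clinical$dfs_12mo),
    correlative = list(
      panel_tests = correlate$panel_tests,
      detection_rates = correlate$detection_rates,
      max_vaf = if (!is.null(correlate$variants)) correlate$variants$max_vaf
                else NULL)
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  log_stage("report", paste("bundle written to", config$out_dir), quiet)
  invisible(report)
}

table_to_list <- function(x) as.list(table(x))

# ---------------------------------------------------------------------------
# Command-line entry point

#' Command-line interface
#'
#' Subcommands: `simulate`, `phenotype`, `niches`, `immunomap`, `clinical`,
#' `correlate`, `report`, `all` (the stages share one driver; single-stage
#' subcommands run the pipeline up to and including that stage's outputs).
#' Flags: `--out DIR`, `--seed N`, `--patients N`, and for `clinical` a
#' `--design n1=11,stop=0,n=17,reject=3` override. Exit codes: 0 success,
#' 2 validation failure, 3 stage failure.
#'
#' @param args Character vector of CLI arguments (default: the process
#'   command line).
#' @return Integer exit status, invisibly. Call via
#'   `Rscript -e 'immuniche::immuniche_cli()' all --out run1 --seed 7`.
#' @export
immuniche_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  subcommands <- c("simulate", "phenotype", "niches", "immunomap",
                   "clinical", "correlate", "report", "all")
  if (length(args) == 0 || !args[1] %in% subcommands) {
    message("usage: immuniche <", paste(subcommands, collapse = "|"),
            "> [--out DIR] [--seed N] [--patients N] [--design k=v,...]")
    return(invisible(2L))
  }
  get_flag <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  out_dir <- get_flag("--out", file.path(getwd(), "immuniche_out"))
  seed <- as.integer(get_flag("--seed", "1"))
  n_pat <- as.integer(get_flag("--patients", "17"))
  design <- two_stage_design()
  dflag <- get_flag("--design", NULL)
  if (!is.null(dflag)) {
    kv <- strsplit(strsplit(dflag, ",")[[1]], "=")
    vals <- stats::setNames(as.integer(vapply(kv, `[`, "", 2)),
                            vapply(kv, `[`, "", 1))
    design <- two_stage_design(
      n1 = vals[["n1"]], futility_stop_at = vals[["stop"]],
      n_total = vals[["n"]], reject_threshold = vals[["reject"]])
  }
  config <- pipeline_config(out_dir = out_dir, seed = seed,
                            n_patients = n_pat, design = design)
  status <- tryCatch({
    run_pipeline(config)
    0L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("validation failure", conditionMessage(e))) 2L else 3L
  })
  invisible(status)
}
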