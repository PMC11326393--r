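# Marker-intensity thresholding into phenotype calls and whole-tissue
# composition fractions.
#
# Pipeline position: immediately downstream of the per-cell coordinate +
# intensity export. Cells are gated on DAPI first; lineage markers are then
# thresholded within DAPI+ cells; TCF1 is evaluated only inside CD8+ cells
# (stem-like T cells are a CD8 subset by definition).

REQUIRED_MARKERS <- c("DAPI", "CD4", "CD8", "MHCII", "TCF1")
PHENO_FLAGS <- c("DAPI", "CD4", "CD8", "MHCII", "TCF1_CD8")

#' Automatic two-class intensity threshold for one marker
#'
#' Derives a per-tissue positivity threshold from the intensity
#' distribution alone (published thresholds for the assay do not exist;
#' the derived value is always recorded in the output).
#'
#' The default `"gap"` method places the threshold at the midpoint of the
#' largest gap between consecutive sorted log1p intensities above the
#' marker median. When positive and negative populations are separated
#' (means >= 5 sd apart) the inter-population gap dominates every
#' within-population spacing and the split is essentially exact, even when
#' positives are a small minority — the regime where the classic Otsu
#' criterion fails by splitting inside the negative bulk. `"otsu"`
#' (histogram-based between-class variance maximisation on log1p
#' intensities) is retained for comparison.
#'
#' @param x Non-negative intensity vector.
#' @param method `"gap"` (default) or `"otsu"`.
#' @param bins Histogram resolution for the Otsu method.
#' @return A single threshold on the raw intensity scale.
#' @export
auto_threshold <- function(x, method = c("gap", "otsu"), bins = 256L) {
  method <- match.arg(method)
  if (method == "gap") gap_threshold(x) else otsu_threshold(x, bins)
}

# Largest-gap split above the median, in log1p space.
gap_threshold <- function(x) {
  lx <- sort(log1p(x[is.finite(x)]))
  if (length(lx) < 2 || diff(range(lx)) == 0) {
    stop("cannot derive a threshold from a constant intensity vector",
         call. = FALSE)
  }
  upper <- lx[lx >= stats::median(lx)]
  if (length(upper) < 2 || diff(range(upper)) == 0) {
    return(expm1(max(lx)) + 1)  # no spread above the median: nothing positive
  }
  gaps <- diff(upper)
  i <- which.max(gaps)
  expm1((upper[i] + upper[i + 1]) / 2)
}

otsu_threshold <- function(x, bins = 256L) {
  lx <- log1p(x[is.finite(x)])
  if (length(lx) == 0 || diff(range(lx)) == 0) {
    stop("cannot derive a threshold from a constant intensity vector",
         call. = FALSE)
  }
  edges <- seq(min(lx), max(lx), length.out = bins + 1L)
  h <- tabulate(findInterval(lx, edges, rightmost.closed = TRUE), nbins = bins)
  mids <- (edges[-1] + edges[-(bins + 1L)]) / 2
  w <- h / sum(h)
  w0 <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  expm1(mids[which.max(between)])
}

#' Call per-cell phenotypes from marker intensities
#'
#' @param cells Cell table with columns `cell_id`, `x_um`, `y_um` and
#'   `<marker>_intensity` for at least DAPI, CD4, CD8, MHCII, TCF1.
#' @param thresholds Either the string `"auto"` (per-marker two-class split
#'   on this tissue via [auto_threshold()]; DAPI gated as any positive
#'   intensity) or a named numeric vector of positive thresholds per marker.
#' @return A `phenotype_table`: data.frame with `cell_id`, `x_um`, `y_um`
#'   and logical columns `pheno_DAPI`, `pheno_CD4`, `pheno_CD8`,
#'   `pheno_MHCII`, `pheno_TCF1_CD8`. Thresholds used are stored in
#'   `attr(, "thresholds_used")`.
#' @details A cell is flagged positive for a marker when its intensity is at
#'   or above the marker threshold, after DAPI gating (cells below the DAPI
#'   threshold carry no other flags). Cells above threshold for both CD4 and
#'   CD8 are assigned to the lineage with the larger intensity z-score, so
#'   the lineages are disjoint. TCF1 is thresholded only within CD8+ cells.
#' @examples
#' ts <- generate_tissue(tissue_spec(seed = 2))
#' ph <- call_phenotypes(ts$cells)
#' colSums(ph[startsWith(names(ph), "pheno_")])
#' @export
call_phenotypes <- function(cells, thresholds = "auto") {
  cols <- paste0(REQUIRED_MARKERS, "_intensity")
  missing_cols <- setdiff(cols, names(cells))
  if (length(missing_cols) > 0) {
    stop("cell table is missing required marker column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dapi <- cells$DAPI_intensity
  if (nrow(cells) == 0 || all(dapi == 0)) {
    stop("empty tissue: no DAPI signal in the cell table", call. = FALSE)
  }
  if (identical(thresholds, "auto")) {
    # DAPI drives segmentation, so every exported object carries DAPI
    # signal: the DAPI gate is "any positive intensity" unless the caller
    # supplies an explicit threshold. Lineage/functional markers get the
    # per-tissue two-class split.
    thr <- vapply(setdiff(REQUIRED_MARKERS, "DAPI"), function(m) {
      auto_threshold(cells[[paste0(m, "_intensity")]])
    }, numeric(1))
    thr <- c(DAPI = min(dapi[dapi > 0]), thr)[REQUIRED_MARKERS]
  } else {
    if (is.null(names(thresholds)) ||
        !all(REQUIRED_MARKERS %in% names(thresholds))) {
      stop("thresholds must be named for all of: ",
           paste(REQUIRED_MARKERS, collapse = ", "), call. = FALSE)
    }
    if (any(thresholds[REQUIRED_MARKERS] <= 0)) {
      stop("thresholds must be positive", call. = FALSE)
    }
    thr <- thresholds[REQUIRED_MARKERS]
  }

  pos <- function(m) cells[[paste0(m, "_intensity")]] >= thr[[m]]
  dapi_pos <- pos("DAPI")
  cd4 <- pos("CD4") & dapi_pos
  cd8 <- pos("CD8") & dapi_pos
  both <- cd4 & cd8
  if (any(both)) {
    zscore <- function(m) {
      v <- cells[[paste0(m, "_intensity")]]
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) s <- 1
      (v - mean(v)) / s
    }
    prefer_cd8 <- zscore("CD8")[both] >= zscore("CD4")[both]
    cd4[both] <- !prefer_cd8
    cd8[both] <- prefer_cd8
  }
  mhc2 <- pos("MHCII") & dapi_pos
  tcf1_cd8 <- cd8 & pos("TCF1")

  out <- data.frame(
    cell_id = cells$cell_id, x_um = cells$x_um, y_um = cells$y_um,
    pheno_DAPI = dapi_pos, pheno_CD4 = cd4, pheno_CD8 = cd8,
    pheno_MHCII = mhc2, pheno_TCF1_CD8 = tcf1_cd8
  )
  attr(out, "thresholds_used") <- thr
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Whole-tissue composition as percent of DAPI+ cells
#'
#' @param pheno A `phenotype_table` from [call_phenotypes()].
#' @return Named numeric vector of percentages of DAPI+ cells for `CD4`,
#'   `CD8`, `TCF1_CD8`, `MHCII` and `other`. `MHCII` here counts cells not
#'   already assigned to a T-cell lineage, so
#'   `CD4 + CD8 + MHCII + other = 100` exactly (`TCF1_CD8` is a subset of
#'   `CD8` and is reported alongside, not added).
#' @examples
#' ph <- call_phenotypes(generate_tissue(tissue_spec(seed = 3))$cells)
#' composition_fractions(ph)
#' @export
composition_fractions <- function(pheno) {
  stopifnot(inherits(pheno, "phenotype_table"))
  n_dapi <- sum(pheno$pheno_DAPI)
  if (n_dapi == 0) stop("empty tissue: no DAPI+ cells", call. = FALSE)
  d <- pheno[pheno$pheno_DAPI, ]
  mhc_only <- d$pheno_MHCII & !d$pheno_CD4 & !d$pheno_CD8
  other <- !d$pheno_CD4 & !d$pheno_CD8 & !mhc_only
  100 * c(
    CD4 = sum(d$pheno_CD4),
    CD8 = sum(d$pheno_CD8),
    TCF1_CD8 = sum(d$pheno_TCF1_CD8),
    MHCII = sum(mhc_only),
    other = sum(other)
  ) / n_dapi
}
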