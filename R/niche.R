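# Immune-niche detection and spatial statistics.
#
# The niche definition: tumor regions containing >= 16 MHC-II+ cells and
# >= 4 TCF1+CD8+ T cells per mm^2 within the same area. "Within the same
# area" is realized as a sliding square window of area `window_area_mm2`
# (default 1 mm^2) whose centers sit on a `stride_um` lattice (default
# 250 um); the niche region is the union of qualifying windows clipped to
# the tumor mask, and coverage is that union's area divided by tumor area.
# Disjoint tiling is available via `mode = "tiles"`.

#' Parameters of the niche definition
#'
#' @param mhc2_min_per_mm2 Minimum MHC-II+ cell density (default 16/mm^2).
#' @param tcf1cd8_min_per_mm2 Minimum TCF1+CD8+ density (default 4/mm^2).
#' @param window_area_mm2 Evaluation window area (default 1 mm^2).
#' @param stride_um Window-center spacing (default 250 um). Must not exceed
#'   the window side length.
#' @param min_window_overlap Windows whose in-mask fraction falls below this
#'   value are classified "outside" and never contribute (default 0.25);
#'   this avoids spuriously unstable densities at the tumor boundary.
#' @param mode `"sliding"` (default) or `"tiles"` (stride = window side,
#'   disjoint windows).
#' @return An object of class `niche_params`.
#' @export
niche_params <- function(mhc2_min_per_mm2 = 16, tcf1cd8_min_per_mm2 = 4,
                         window_area_mm2 = 1.0, stride_um = 250,
                         min_window_overlap = 0.25,
                         mode = c("sliding", "tiles")) {
  mode <- match.arg(mode)
  side_um <- sqrt(window_area_mm2) * 1000
  if (mode == "tiles") stride_um <- side_um
  if (mhc2_min_per_mm2 <= 0 || tcf1cd8_min_per_mm2 <= 0) {
    stop("density thresholds must be > 0", call. = FALSE)
  }
  if (min_window_overlap <= 0 || min_window_overlap > 1) {
    stop("min_window_overlap must lie in (0, 1]", call. = FALSE)
  }
  if (stride_um > side_um) {
    stop("stride_um must not exceed the window side length (",
         round(side_um), " um)", call. = FALSE)
  }
  structure(
    list(mhc2_min_per_mm2 = mhc2_min_per_mm2,
         tcf1cd8_min_per_mm2 = tcf1cd8_min_per_mm2,
         window_area_mm2 = window_area_mm2, side_um = side_um,
         stride_um = stride_um, min_window_overlap = min_window_overlap,
         mode = mode),
    class = "niche_params"
  )
}

# Window-center lattice covering [lo, hi] with windows of width `side`.
window_centers <- function(lo, hi, side, stride) {
  n <- max(1L, as.integer(ceiling(((hi - lo) - side) / stride)) + 1L)
  lo + side / 2 + stride * (seq_len(n) - 1L)
}

# Interval-accelerated in-window counting: cells sorted by x, candidate
# ranges found by binary search, y filtered within candidates. Windows are
# half-open [lo, hi) in both axes so that disjoint tiles partition cells.
count_in_windows <- function(x, y, cx, cy, side) {
  h <- side / 2
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  counts <- matrix(0L, nrow = length(cx), ncol = length(cy))
  for (i in seq_along(cx)) {
    lo <- cx[i] - h; hi <- cx[i] + h
    i0 <- findInterval(lo, xs, left.open = TRUE) + 1L  # first xs >= lo
    i1 <- findInterval(hi, xs, left.open = TRUE)       # last xs < hi
    if (i1 < i0) next
    ycand <- ys[i0:i1]
    for (j in seq_along(cy)) {
      counts[i, j] <- sum(ycand >= cy[j] - h & ycand < cy[j] + h)
    }
  }
  counts
}

#' Per-window phenotype counts and densities over a tumor mask
#'
#' Lays square windows of area `window_area_mm2` on a `stride_um` lattice
#' covering the mask bounding box, counts in-mask MHC-II+ and TCF1+CD8+
#' cells per window, and normalizes densities by the window-in-mask area.
#'
#' @param pheno A `phenotype_table` from [call_phenotypes()].
#' @param mask A [tumor_mask()].
#' @param params A [niche_params()].
#' @return A data.frame of class `density_grid` with one row per window:
#'   `cx_um, cy_um, n_mhc2, n_tcf1cd8, area_mm2, dens_mhc2, dens_tcf1cd8,
#'   inside` (`inside` is FALSE for windows below the overlap minimum, whose
#'   densities are NA).
#' @export
density_grid <- function(pheno, mask, params = niche_params()) {
  stopifnot(inherits(pheno, "phenotype_table"), inherits(mask, "tumor_mask"),
            inherits(params, "niche_params"))
  bbox <- mask_bbox(mask)
  side <- params$side_um
  cx <- window_centers(bbox[1], bbox[3], side, params$stride_um)
  cy <- window_centers(bbox[2], bbox[4], side, params$stride_um)

  in_mask <- points_in_mask(mask, pheno$x_um, pheno$y_um)
  mh <- pheno[in_mask & pheno$pheno_MHCII, c("x_um", "y_um")]
  tc <- pheno[in_mask & pheno$pheno_TCF1_CD8, c("x_um", "y_um")]
  n_mhc2 <- count_in_windows(mh$x_um, mh$y_um, cx, cy, side)
  n_tcf1 <- count_in_windows(tc$x_um, tc$y_um, cx, cy, side)

  # in-mask fraction of every window from one pooled sample-lattice query
  k <- 10L
  u <- (seq_len(k) - 0.5) / k * side - side / 2
  grid <- expand.grid(cx = cx, cy = cy)
  sx <- rep(grid$cx, each = k * k) + rep(rep(u, times = k), nrow(grid))
  sy <- rep(grid$cy, each = k * k) + rep(rep(u, each = k), nrow(grid))
  frac <- colMeans(matrix(points_in_mask(mask, sx, sy), nrow = k * k))
  if (all(frac == 0)) {
    stop("geometry error: tumor mask does not overlap any window",
         call. = FALSE)
  }

  inside <- frac >= params$min_window_overlap
  area_mm2 <- frac * params$window_area_mm2
  out <- data.frame(
    cx_um = grid$cx, cy_um = grid$cy,
    n_mhc2 = as.vector(n_mhc2), n_tcf1cd8 = as.vector(n_tcf1),
    area_mm2 = area_mm2,
    dens_mhc2 = ifelse(inside, as.vector(n_mhc2) / area_mm2, NA_real_),
    dens_tcf1cd8 = ifelse(inside, as.vector(n_tcf1) / area_mm2, NA_real_),
    inside = inside
  )
  attr(out, "params") <- params
  attr(out, "bbox") <- bbox
  class(out) <- c("density_grid", "data.frame")
  out
}

#' Detect immune niches and compute tumor coverage
#'
#' A window is niche-positive when its MHC-II+ density and its TCF1+CD8+
#' density both meet their thresholds in the same window. Each window
#' center classifies its stride-resolution raster cell, so the niche
#' region is the set of stride cells whose surrounding window qualifies,
#' clipped to the mask; coverage is its area divided by the tumor area.
#' (Rasterizing the full 1-mm^2 window instead would dilate a niche by up
#' to a window radius in every direction.)
#'
#' @inheritParams density_grid
#' @return An object of class `niche_map`: list with `grid` (the
#'   [density_grid()] plus an `is_niche` column), `niche_area_mm2`,
#'   `coverage`, `raster` (stride-resolution union raster) and `params`.
#' @examples
#' ts <- tissue_spec(seed = 11, niche_specs = list(
#'   list(cx_um = 2000, cy_um = 2000, radius_um = 564.2,
#'        mhc2_per_mm2 = 40, tcf1cd8_per_mm2 = 10)))
#' tissue <- generate_tissue(ts)
#' nm <- detect_niches(call_phenotypes(tissue$cells), tissue$mask)
#' nm$coverage
#' @export
detect_niches <- function(pheno, mask, params = niche_params()) {
  grid <- density_grid(pheno, mask, params)
  grid$is_niche <- grid$inside &
    !is.na(grid$dens_mhc2) & grid$dens_mhc2 >= params$mhc2_min_per_mm2 &
    !is.na(grid$dens_tcf1cd8) & grid$dens_tcf1cd8 >= params$tcf1cd8_min_per_mm2

  bbox <- attr(grid, "bbox")
  stride <- params$stride_um
  # raster cells are the stride-sized cells around each window center
  rx <- sort(unique(grid$cx_um))
  ry <- sort(unique(grid$cy_um))
  covered <- matrix(FALSE, nrow = length(rx), ncol = length(ry))
  pos <- grid[grid$is_niche, c("cx_um", "cy_um")]
  if (nrow(pos) > 0) {
    covered[cbind(match(pos$cx_um, rx), match(pos$cy_um, ry))] <- TRUE
  }

  niche_area_mm2 <- 0
  if (any(covered)) {
    idx <- which(covered, arr.ind = TRUE)
    fr <- vapply(seq_len(nrow(idx)), function(i) {
      x0 <- rx[idx[i, 1]] - stride / 2
      y0 <- ry[idx[i, 2]] - stride / 2
      rect_mask_fraction(mask, x0, x0 + stride, y0, y0 + stride, k = 5L)
    }, numeric(1))
    niche_area_mm2 <- sum(fr) * stride^2 / 1e6
  }
  coverage <- min(1, niche_area_mm2 / mask$area_mm2)
  structure(
    list(grid = grid, params = params, niche_area_mm2 = niche_area_mm2,
         coverage = coverage,
         raster = list(x = rx, y = ry, covered = covered, stride_um = stride),
         mask = mask),
    class = "niche_map"
  )
}

#' @export
print.niche_map <- function(x, ...) {
  cat(sprintf(
    "<niche_map> %d/%d windows niche-positive; niche area %.3f mm^2; coverage %.1f%%\n",
    sum(x$grid$is_niche), sum(x$grid$inside), x$niche_area_mm2,
    100 * x$coverage
  ))
  invisible(x)
}

#' Nearest-neighbor distances between phenotype point sets
#'
#' For every cell of `from_phenotype`, the Euclidean distance (um) to the
#' nearest cell of `to_phenotype`. When the two phenotypes are the same,
#' each cell's distance excludes itself.
#'
#' @param pheno A `phenotype_table`.
#' @param from_phenotype,to_phenotype Phenotype names among `"DAPI"`,
#'   `"CD4"`, `"CD8"`, `"MHCII"`, `"TCF1_CD8"`.
#' @return Numeric vector of distances, one per `from_phenotype` cell, named
#'   by `cell_id`.
#' @examples
#' ph <- call_phenotypes(generate_tissue(tissue_spec(seed = 5))$cells)
#' d <- nn_distances(ph, "CD8", "MHCII")
#' summary(d)
#' @export
nn_distances <- function(pheno, from_phenotype, to_phenotype) {
  stopifnot(inherits(pheno, "phenotype_table"))
  col <- function(p) {
    cn <- paste0("pheno_", p)
    if (!cn %in% names(pheno)) {
      stop("unknown phenotype: ", p, call. = FALSE)
    }
    which(pheno[[cn]])
  }
  fi <- col(from_phenotype)
  ti <- col(to_phenotype)
  self <- identical(from_phenotype, to_phenotype)
  if (length(ti) == 0 || (self && length(ti) < 2)) {
    stop("undefined distance: no eligible cells of phenotype ",
         to_phenotype, call. = FALSE)
  }
  d <- nn_dist_grid(pheno$x_um[fi], pheno$y_um[fi],
                    pheno$x_um[ti], pheno$y_um[ti],
                    exclude = if (self) match(fi, ti) else NULL)
  stats::setNames(d, pheno$cell_id[fi])
}

# Bucket-grid nearest-neighbor search. `exclude[i]` (optional) is the index
# into the to-set that from-point i must ignore (self-matching).
nn_dist_grid <- function(fx, fy, tx, ty, exclude = NULL) {
  n <- length(fx); m <- length(tx)
  if (n == 0) return(numeric(0))
  xmin <- min(tx, fx); xmax <- max(tx, fx)
  ymin <- min(ty, fy); ymax <- max(ty, fy)
  span <- max(xmax - xmin, ymax - ymin, 1)
  h <- max(span / max(1, ceiling(sqrt(m))), 1e-9)
  nbx <- as.integer(floor((xmax - xmin) / h)) + 1L
  nby <- as.integer(floor((ymax - ymin) / h)) + 1L
  bx <- pmin(as.integer(floor((tx - xmin) / h)), nbx - 1L)
  by <- pmin(as.integer(floor((ty - ymin) / h)), nby - 1L)
  bucket_of <- bx + nbx * by + 1L
  buckets <- split(seq_len(m), bucket_of)

  out <- numeric(n)
  for (i in seq_len(n)) {
    pbx <- min(as.integer(floor((fx[i] - xmin) / h)), nbx - 1L)
    pby <- min(as.integer(floor((fy[i] - ymin) / h)), nby - 1L)
    best <- Inf
    r <- 0L
    max_r <- max(nbx, nby)
    repeat {
      # buckets at Chebyshev ring r around (pbx, pby)
      xs <- max(0L, pbx - r):min(nbx - 1L, pbx + r)
      ys <- max(0L, pby - r):min(nby - 1L, pby + r)
      cand <- integer(0)
      for (byy in ys) {
        for (bxx in xs) {
          if (max(abs(bxx - pbx), abs(byy - pby)) != r) next
          b <- buckets[[as.character(bxx + nbx * byy + 1L)]]
          if (!is.null(b)) cand <- c(cand, b)
        }
      }
      if (!is.null(exclude) && !is.na(exclude[i])) {
        cand <- cand[cand != exclude[i]]
      }
      if (length(cand) > 0) {
        dd <- sqrt((tx[cand] - fx[i])^2 + (ty[cand] - fy[i])^2)
        best <- min(best, min(dd))
      }
      # points in unscanned buckets are at distance >= r * h
      if ((is.finite(best) && best <= r * h) || r > max_r) break
      r <- r + 1L
    }
    out[i] <- best
  }
  out
}

#' Export an immunomap as GeoJSON
#'
#' Writes the phenotype point layers (CD8+, TCF1+CD8+, MHC-II+), the tumor
#' outline and the detected niche region into one GeoJSON FeatureCollection
#' (coordinates in um). Writing is idempotent: write -> read -> write
#' produces a byte-identical file.
#'
#' @param pheno A `phenotype_table`.
#' @param niche_map A `niche_map` from [detect_niches()], or NULL to omit
#'   the niche layer.
#' @param mask A [tumor_mask()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_immunomap <- function(pheno, niche_map, mask, path) {
  stopifnot(inherits(pheno, "phenotype_table"), inherits(mask, "tumor_mask"))
  bbox <- mask_bbox(mask)
  pad <- 1e-6
  bad <- nrow(pheno) > 0 &
    (pheno$x_um < bbox[1] - pad | pheno$x_um > bbox[3] + pad |
       pheno$y_um < bbox[2] - pad | pheno$y_um > bbox[4] + pad)
  if (any(bad)) {
    stop("geometry error: ", sum(bad),
         " cell(s) fall outside the tissue frame", call. = FALSE)
  }
  feats <- list()
  for (p in mask$polygons) {
    feats <- c(feats, list(geojson_feature(
      polygon_geometry(p), list(layer = "tumor_mask", units = "um"))))
  }
  for (ph in c("CD8", "TCF1_CD8", "MHCII")) {
    idx <- which(pheno[[paste0("pheno_", ph)]])
    for (i in idx) {
      feats <- c(feats, list(geojson_feature(
        list(type = "Point",
             coordinates = round(c(pheno$x_um[i], pheno$y_um[i]),
                                 GEOJSON_COORD_DIGITS)),
        list(layer = "cells", phenotype = ph, units = "um"))))
    }
  }
  if (!is.null(niche_map)) {
    rects <- raster_row_runs(niche_map$raster)
    if (length(rects) > 0) {
      feats <- c(feats, list(geojson_feature(
        multipolygon_geometry(lapply(rects, list)),
        list(layer = "niche", units = "um"))))
    }
  }
  write_feature_collection(
    feats, path,
    extra = list(frame = list(xmin_um = bbox[1], ymin_um = bbox[2],
                              xmax_um = bbox[3], ymax_um = bbox[4]))
  )
}

# Convert the niche raster into per-row run rectangles (exterior rings).
raster_row_runs <- function(raster) {
  s <- raster$stride_um
  rects <- list()
  for (j in seq_along(raster$y)) {
    row <- raster$covered[, j]
    if (!any(row)) next
    r <- rle(row)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      x0 <- raster$x[starts[k]] - s / 2
      x1 <- raster$x[ends[k]] + s / 2
      y0 <- raster$y[j] - s / 2
      y1 <- raster$y[j] + s / 2
      rects <- c(rects, list(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))))
    }
  }
  rects
}

#' Read an immunomap written by [export_immunomap()]
#'
#' @param path Path to the GeoJSON file.
#' @return List with `points` (data.frame `x_um, y_um, phenotype`),
#'   `mask_polygons`, `niche_polygons` and `frame`.
#' @export
read_immunomap <- function(path) {
  doc <- jsonlite::read_json(path)
  pts <- list()
  mask_polys <- list()
  niche_polys <- list()
  for (f in doc$features) {
    layer <- f$properties$layer
    g <- f$geometry
    if (identical(layer, "cells")) {
      pts <- c(pts, list(data.frame(
        x_um = as.numeric(g$coordinates[[1]]),
        y_um = as.numeric(g$coordinates[[2]]),
        phenotype = f$properties$phenotype)))
    } else if (identical(layer, "tumor_mask")) {
      mask_polys <- c(mask_polys, list(lapply(g$coordinates, coords_to_ring)))
    } else if (identical(layer, "niche")) {
      niche_polys <- c(niche_polys,
                       lapply(g$coordinates, function(p) lapply(p, coords_to_ring)))
    }
  }
  list(
    points = if (length(pts)) do.call(rbind, pts) else
      data.frame(x_um = numeric(0), y_um = numeric(0), phenotype = character(0)),
    mask_polygons = mask_polys,
    niche_polygons = niche_polys,
    frame = doc$frame
  )
}
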