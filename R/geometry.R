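# Planar geometry primitives for tissue masks.
#
# All coordinates are micrometres (um) in the image convention: origin at the
# top-left of the slide frame, y increasing downward. Areas are reported in
# mm^2 (1 mm^2 = 1e6 um^2).

#' Construct a tumor mask from planar polygons
#'
#' A tumor mask is one or more simple polygons (holes allowed) outlining the
#' tumor region of a tissue section, with coordinates in micrometres.
#'
#' @param polygons Either a single two-column matrix (one exterior ring), a
#'   list of rings (first ring exterior, subsequent rings holes), or a list of
#'   such lists (multiple disjoint polygons). Rings need not repeat their
#'   first vertex.
#' @return An object of class `tumor_mask` with elements `polygons` (list of
#'   polygons, each a list of ring matrices) and `area_mm2`.
#' @examples
#' sq <- cbind(c(0, 2000, 2000, 0), c(0, 0, 2000, 2000))
#' mask <- tumor_mask(sq)
#' mask$area_mm2  # 4 mm^2
#' @export
tumor_mask <- function(polygons) {
  polys <- normalize_polygons(polygons)
  area_um2 <- sum(vapply(polys, polygon_area_um2, numeric(1)))
  if (!is.finite(area_um2) || area_um2 <= 0) {
    stop("tumor mask must have positive area", call. = FALSE)
  }
  structure(
    list(polygons = polys, area_mm2 = area_um2 / 1e6),
    class = "tumor_mask"
  )
}

#' @export
print.tumor_mask <- function(x, ...) {
  n_holes <- sum(vapply(x$polygons, function(p) length(p) - 1L, integer(1)))
  cat(sprintf(
    "<tumor_mask> %d polygon(s), %d hole(s), area %.4f mm^2\n",
    length(x$polygons), n_holes, x$area_mm2
  ))
  invisible(x)
}

# Coerce the accepted polygon inputs into list-of-polygons form and validate.
normalize_polygons <- function(polygons) {
  as_ring <- function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2) stop("polygon rings must be two-column", call. = FALSE)
    storage.mode(r) <- "double"
    # drop an explicitly closed last vertex
    n <- nrow(r)
    if (n >= 2 && all(r[1, ] == r[n, ])) r <- r[-n, , drop = FALSE]
    if (nrow(r) < 3) stop("polygon rings need >= 3 vertices", call. = FALSE)
    if (!all(is.finite(r))) stop("polygon coordinates must be finite", call. = FALSE)
    r
  }
  if (is.matrix(polygons) || is.data.frame(polygons)) {
    return(list(list(as_ring(polygons))))
  }
  if (!is.list(polygons) || length(polygons) == 0) {
    stop("polygons must be a matrix or a non-empty list", call. = FALSE)
  }
  if (is.matrix(polygons[[1]]) || is.data.frame(polygons[[1]])) {
    # a single polygon given as list of rings
    return(list(lapply(polygons, as_ring)))
  }
  lapply(polygons, function(p) lapply(p, as_ring))
}

# Signed shoelace area of one ring, um^2.
ring_area_signed <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

# Unsigned area of a polygon (exterior minus holes), um^2.
polygon_area_um2 <- function(polygon) {
  a <- abs(ring_area_signed(polygon[[1]]))
  if (length(polygon) > 1) {
    a <- a - sum(vapply(polygon[-1], function(r) abs(ring_area_signed(r)), numeric(1)))
  }
  a
}

# Vectorized even-odd ray casting: are points (px, py) inside `ring`?
# Points exactly on an edge may fall either side; callers that care about
# boundaries should not place data exactly on ring edges.
points_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Test points against a tumor mask
#'
#' @param mask A [tumor_mask()].
#' @param x_um,y_um Numeric vectors of point coordinates in micrometres.
#' @return Logical vector: `TRUE` where the point lies inside the mask
#'   (inside an exterior ring and outside its holes).
#' @export
points_in_mask <- function(mask, x_um, y_um) {
  stopifnot(inherits(mask, "tumor_mask"), length(x_um) == length(y_um))
  inside <- logical(length(x_um))
  for (poly in mask$polygons) {
    in_poly <- points_in_ring(x_um, y_um, poly[[1]])
    if (length(poly) > 1) {
      for (hole in poly[-1]) {
        in_poly <- in_poly & !points_in_ring(x_um, y_um, hole)
      }
    }
    inside <- inside | in_poly
  }
  inside
}

# Bounding box of a mask: c(xmin, ymin, xmax, ymax) in um.
mask_bbox <- function(mask) {
  pts <- do.call(rbind, lapply(mask$polygons, function(p) do.call(rbind, p)))
  c(min(pts[, 1]), min(pts[, 2]), max(pts[, 1]), max(pts[, 2]))
}

# Fraction of the axis-aligned rectangle [x0,x1]x[y0,y1] lying inside the
# mask, estimated on a centred k x k sample lattice. Deterministic.
rect_mask_fraction <- function(mask, x0, x1, y0, y1, k = 10L) {
  u <- (seq_len(k) - 0.5) / k
  gx <- x0 + u * (x1 - x0)
  gy <- y0 + u * (y1 - y0)
  g <- expand.grid(x = gx, y = gy)
  mean(points_in_mask(mask, g$x, g$y))
}

#' Build a regular polygon approximating a disc
#'
#' Used by the synthetic generator for niche discs and circular tumor
#' outlines.
#'
#' @param cx,cy Centre in micrometres.
#' @param r Radius in micrometres.
#' @param n Number of vertices.
#' @return A two-column coordinate matrix (one exterior ring).
#' @export
disc_polygon <- function(cx, cy, r, n = 128L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}
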