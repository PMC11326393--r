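# GeoJSON reading/writing for masks and immunomaps.
#
# Geometry travels as standard GeoJSON FeatureCollections, with coordinates
# in micrometres and a `units: "um"` property on every feature so that files
# are self-describing. Coordinates are rounded to 1e-6 um before writing,
# which makes write -> read -> write byte-stable.

GEOJSON_COORD_DIGITS <- 6L

# ring matrix -> closed GeoJSON ring (list of [x, y])
ring_to_coords <- function(ring) {
  ring <- round(ring, GEOJSON_COORD_DIGITS)
  ring <- rbind(ring, ring[1, , drop = FALSE])
  lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
}

coords_to_ring <- function(coords) {
  m <- do.call(rbind, lapply(coords, as.numeric))
  m
}

polygon_geometry <- function(polygon) {
  list(type = "Polygon", coordinates = lapply(polygon, ring_to_coords))
}

multipolygon_geometry <- function(polygons) {
  list(
    type = "MultiPolygon",
    coordinates = lapply(polygons, function(p) lapply(p, ring_to_coords))
  )
}

geojson_feature <- function(geometry, properties) {
  list(type = "Feature", properties = properties, geometry = geometry)
}

write_feature_collection <- function(features, path, extra = NULL) {
  fc <- c(list(type = "FeatureCollection"), extra, list(features = features))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE, null = "null")
  invisible(path)
}

#' Write a tumor mask to GeoJSON
#'
#' @param mask A [tumor_mask()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_mask_geojson <- function(mask, path) {
  stopifnot(inherits(mask, "tumor_mask"))
  feats <- lapply(mask$polygons, function(p) {
    geojson_feature(polygon_geometry(p),
                    list(layer = "tumor_mask", units = "um"))
  })
  write_feature_collection(feats, path)
}

#' Read a tumor mask from GeoJSON
#'
#' Accepts Polygon and MultiPolygon features; all features in the file are
#' combined into one mask.
#'
#' @param path Path to a GeoJSON FeatureCollection.
#' @return A [tumor_mask()].
#' @export
read_mask_geojson <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$features)) stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  polys <- list()
  for (f in doc$features) {
    g <- f$geometry
    if (is.null(g)) next
    if (identical(g$type, "Polygon")) {
      polys <- c(polys, list(lapply(g$coordinates, coords_to_ring)))
    } else if (identical(g$type, "MultiPolygon")) {
      polys <- c(polys, lapply(g$coordinates, function(p) lapply(p, coords_to_ring)))
    } else {
      stop("unsupported geometry type in mask file: ", g$type, call. = FALSE)
    }
  }
  if (length(polys) == 0) stop("no polygon features in ", path, call. = FALSE)
  tumor_mask(polys)
}
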