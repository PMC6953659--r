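# Minimal GeoJSON I/O via jsonlite. Geometries are converted to the
# package's internal representation: polygons as lists of ring matrices
# (outer rings and holes flattened, even-odd rule), lines as lists of
# two-column matrices.

coords_to_matrix <- function(coords) {
  do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
}

geom_to_rings <- function(geom) {
  type <- geom$type
  if (type == "Polygon") {
    lapply(geom$coordinates, coords_to_matrix)
  } else if (type == "MultiPolygon") {
    unlist(lapply(geom$coordinates, function(poly) lapply(poly, coords_to_matrix)),
           recursive = FALSE)
  } else {
    stop("unsupported polygon geometry type: ", type)
  }
}

geom_to_lines <- function(geom) {
  type <- geom$type
  if (type == "LineString") {
    list(coords_to_matrix(geom$coordinates))
  } else if (type == "MultiLineString") {
    lapply(geom$coordinates, coords_to_matrix)
  } else {
    stop("unsupported line geometry type: ", type)
  }
}

#' Read polygon features from a GeoJSON file
#'
#' Accepts a FeatureCollection, a single Feature, or a bare geometry, with
#' Polygon/MultiPolygon geometries. Holes are kept and handled by the
#' even-odd point-in-polygon rule.
#'
#' @param path path to a GeoJSON file.
#' @return list of features, each `list(rings = <list of matrices>,
#'   properties = <named list>)`.
#' @export
read_geojson_polygons <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- switch(g$type,
    FeatureCollection = g$features,
    Feature = list(g),
    list(list(geometry = g, properties = list())))
  lapply(feats, function(f) {
    list(rings = geom_to_rings(f$geometry),
         properties = if (is.null(f$properties)) list() else f$properties)
  })
}

#' Read line features from a GeoJSON file
#'
#' @param path path to a GeoJSON file with LineString/MultiLineString features.
#' @return list of features, each `list(lines = <list of matrices>,
#'   properties = <named list>)`.
#' @export
read_geojson_lines <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- switch(g$type,
    FeatureCollection = g$features,
    Feature = list(g),
    list(list(geometry = g, properties = list())))
  lapply(feats, function(f) {
    list(lines = geom_to_lines(f$geometry),
         properties = if (is.null(f$properties)) list() else f$properties)
  })
}

ring_to_coords <- function(ring) {
  m <- ring_matrix(ring)
  m <- rbind(m, m[1, ])  # GeoJSON rings are closed
  lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
}

#' Write polygon features to a GeoJSON FeatureCollection
#'
#' @param rings_list list of ring matrices (one Polygon per feature) or list
#'   of lists of rings.
#' @param properties data.frame of per-feature properties (optional).
#' @param path output file.
#' @export
write_geojson_polygons <- function(rings_list, properties = NULL, path) {
  feats <- lapply(seq_along(rings_list), function(i) {
    r <- rings_list[[i]]
    if (is.matrix(r) || is.data.frame(r)) r <- list(r)
    props <- if (is.null(properties)) structure(list(), names = character(0))
             else as.list(properties[i, , drop = FALSE])
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = lapply(r, ring_to_coords)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
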