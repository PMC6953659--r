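# Thiessen (Voronoi) sampling-activity map: each sampled cell's centroid
# generates the polygon of territory nearer to it than to any other sampled
# centroid. Large polygons mean regionally sparse sampling.

#' Thiessen polygon map of sampling activity
#'
#' Computes the planar Voronoi diagram of the sampled-cell centroids in a
#' Lambert azimuthal equal-area projection centered on the study region
#' (so areas are in honest km^2), clipped to the region boundary.
#'
#' @param centroids data.frame/matrix with `lon`, `lat` of sampled-cell
#'   centroids (rows may carry an `ecoregion` column, propagated to the
#'   output).
#' @param boundary polygon set (ring matrix, list of rings, or
#'   [read_geojson_polygons()] features) in lon/lat.
#' @return a `VoronoiMap`: list with `polygons` (lon/lat ring per
#'   generator), `areas_km2`, `generators` (the input table), `region_km2`.
#' @export
thiessen <- function(centroids, boundary) {
  cent <- as.data.frame(centroids)
  if (nrow(cent) < 1) stop("no sampled cells")
  rings <- boundary_rings(boundary)
  allv <- do.call(rbind, lapply(rings, ring_matrix))
  lon0 <- mean(range(allv[, 1])); lat0 <- mean(range(allv[, 2]))
  pts <- laea_project(cent$lon, cent$lat, lon0, lat0)
  brings <- lapply(rings, function(r) {
    m <- ring_matrix(r)
    laea_project(m[, 1], m[, 2], lon0, lat0)
  })
  bb <- do.call(rbind, brings)
  pad <- 0.1 * max(diff(range(bb[, 1])), diff(range(bb[, 2]))) +
    max(abs(bb)) * 1e-9
  box <- c(min(bb[, 1], pts[, 1]) - pad, max(bb[, 1], pts[, 1]) + pad,
           min(bb[, 2], pts[, 2]) - pad, max(bb[, 2], pts[, 2]) + pad)
  vcells <- voronoi_polygons(pts, box)
  # clip each (convex) Voronoi cell against the boundary rings
  polys <- vector("list", length(vcells))
  areas <- numeric(length(vcells))
  for (i in seq_along(vcells)) {
    if (nrow(vcells[[i]]) < 3) { polys[[i]] <- vcells[[i]]; next }
    clipped <- lapply(brings, function(br) clip_polygon_convex(br, vcells[[i]]))
    areas[i] <- sum(vapply(clipped, function(cp) abs(ring_area_signed(cp)), 0))
    best <- clipped[[which.max(vapply(clipped, nrow, 0L))]]
    polys[[i]] <- unproject_ring(best, lon0, lat0)
  }
  structure(list(polygons = polys, areas_km2 = areas, generators = cent,
                 region_km2 = sum(vapply(brings, function(b)
                   abs(ring_area_signed(b)), 0)),
                 center = c(lon0 = lon0, lat0 = lat0)),
            class = "voronoi_map")
}

# inverse Lambert azimuthal equal-area (km -> lon/lat degrees)
unproject_ring <- function(m, lon0, lat0, R = 6371) {
  if (nrow(m) == 0) return(m)
  to <- pi / 180
  x <- m[, 1] / R; y <- m[, 2] / R
  rho <- sqrt(x^2 + y^2)
  c_ <- 2 * asin(pmin(1, rho / 2))
  phi0 <- lat0 * to
  lat <- ifelse(rho < 1e-12, lat0,
                asin(cos(c_) * sin(phi0) + y * sin(c_) * cos(phi0) / pmax(rho, 1e-300)) / to)
  lon <- lon0 + atan2(x * sin(c_),
                      rho * cos(phi0) * cos(c_) - y * sin(phi0) * sin(c_)) / to
  cbind(lon = ifelse(rho < 1e-12, lon0, lon), lat = lat)
}

#' Large-polygon summary of a Thiessen map
#'
#' Counts and describes polygons at least `threshold_km2` large — the areas
#' whose faunal knowledge rests on a single sampled cell each.
#'
#' @param vmap a `VoronoiMap` from [thiessen()].
#' @param threshold_km2 area threshold (the conventional figure is
#'   10,000 km^2).
#' @return list with `count`, `total_km2`, `max_km2`, and `large`
#'   (data.frame of the large polygons' generator rows and areas, with
#'   `ecoregion` when the generators carried one).
#' @export
large_polygon_summary <- function(vmap, threshold_km2 = 10000) {
  sel <- which(vmap$areas_km2 >= threshold_km2)
  large <- vmap$generators[sel, , drop = FALSE]
  large$area_km2 <- vmap$areas_km2[sel]
  list(count = length(sel),
       total_km2 = sum(vmap$areas_km2[sel]),
       max_km2 = if (length(vmap$areas_km2)) max(vmap$areas_km2) else 0,
       large = large[order(-large$area_km2), , drop = FALSE])
}

#' @export
print.voronoi_map <- function(x, ...) {
  cat(sprintf("Thiessen map: %d polygons over %.0f km^2 (largest %.0f km^2)\n",
              length(x$polygons), x$region_km2, max(x$areas_km2)))
  invisible(x)
}

#' Export a Thiessen map as GeoJSON
#'
#' @param vmap a `VoronoiMap`.
#' @param path output file.
#' @export
thiessen_to_geojson <- function(vmap, path) {
  props <- vmap$generators
  props$area_km2 <- vmap$areas_km2
  keep <- vapply(vmap$polygons, nrow, 0L) >= 3
  write_geojson_polygons(vmap$polygons[keep], props[keep, , drop = FALSE], path)
}
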