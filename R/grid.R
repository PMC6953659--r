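#' Build an analysis grid over a study region
#'
#' Lays a regular lon/lat lattice at the given resolution over the bounding
#' box of the boundary, aligned to integer multiples of the resolution from
#' the lattice origin, and flags a cell as land when its centroid falls
#' inside the boundary. Cell areas use the spherical rectangle formula
#' `R^2 * dlam * dphi * cos(lat)` with `R = 6371` km.
#'
#' @param boundary polygon set: a ring matrix, a list of ring matrices, or
#'   the result of [read_geojson_polygons()].
#' @param resolution cell size in arc-minutes (default 5, the standard
#'   resolution for this kind of gap analysis).
#' @return an object of class `surveygap_grid`: list with `resolution`
#'   (arc-minutes), `bbox`, `nrow`, `ncol` and `cells`, a data.frame with one
#'   row per lattice cell: `cell_id` (dense, 0-based, row-major), `row`,
#'   `col`, `lon`, `lat` (centroid), `area_km2`, `land`, `ecoregion`
#'   (NA until [set_ecoregions()] is called).
#' @export
build_grid <- function(boundary, resolution = 5) {
  rings <- boundary_rings(boundary)
  if (length(rings) == 0) stop("empty boundary")
  allv <- do.call(rbind, lapply(rings, ring_matrix))
  if (nrow(allv) < 3) stop("empty boundary")
  res <- resolution / 60  # degrees
  xmin <- floor(min(allv[, 1]) / res) * res
  xmax <- ceiling(max(allv[, 1]) / res) * res
  ymin <- floor(min(allv[, 2]) / res) * res
  ymax <- ceiling(max(allv[, 2]) / res) * res
  ncol <- max(1L, round((xmax - xmin) / res))
  nrow <- max(1L, round((ymax - ymin) / res))
  cells <- lattice_cells(xmin, ymin, nrow, ncol, res)
  cells$land <- point_in_polygon(cells$lon, cells$lat, rings)
  g <- structure(list(resolution = resolution,
                      bbox = c(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax),
                      nrow = nrow, ncol = ncol, cells = cells),
                 class = "surveygap_grid")
  g
}

boundary_rings <- function(boundary) {
  if (is.matrix(boundary) || is.data.frame(boundary)) return(list(ring_matrix(boundary)))
  if (is.list(boundary) && length(boundary) > 0) {
    first <- boundary[[1]]
    if (is.list(first) && !is.matrix(first) && !is.data.frame(first) &&
        !is.null(first$rings)) {
      return(unlist(lapply(boundary, `[[`, "rings"), recursive = FALSE))
    }
  }
  lapply(boundary, ring_matrix)
}

# Row-major lattice of cells with centroids and spherical-rectangle areas.
lattice_cells <- function(xmin, ymin, nrow, ncol, res, R = 6371) {
  row <- rep(seq_len(nrow), each = ncol)
  col <- rep(seq_len(ncol), times = nrow)
  lon <- xmin + (col - 0.5) * res
  lat <- ymin + (row - 0.5) * res
  to <- pi / 180
  area <- R^2 * (res * to)^2 * cos(lat * to)
  data.frame(cell_id = seq_len(nrow * ncol) - 1L, row = row, col = col,
             lon = lon, lat = lat, area_km2 = area,
             land = TRUE, ecoregion = NA_integer_)
}

#' @export
print.surveygap_grid <- function(x, ...) {
  cat(sprintf("surveygap grid: %d x %d cells at %.3g arc-min (%d land)\n",
              x$nrow, x$ncol, x$resolution, sum(x$cells$land)))
  invisible(x)
}

#' Locate points on the grid
#'
#' Maps lon/lat points to cell ids using half-open cell intervals
#' `[west, east) x [south, north)`, so boundary points belong to exactly
#' one cell.
#'
#' @param grid a `surveygap_grid`.
#' @param lon,lat point coordinates in degrees.
#' @return integer vector of 0-based cell ids; `NA` for points outside the
#'   lattice.
#' @export
locate_cells <- function(grid, lon, lat) {
  res <- grid$resolution / 60
  col <- floor((lon - grid$bbox["xmin"]) / res) + 1
  row <- floor((lat - grid$bbox["ymin"]) / res) + 1
  ok <- col >= 1 & col <= grid$ncol & row >= 1 & row <= grid$nrow &
    is.finite(lon) & is.finite(lat)
  id <- rep(NA_integer_, length(lon))
  id[ok] <- as.integer((row[ok] - 1) * grid$ncol + (col[ok] - 1))
  id
}

# West/south/east/north bounds of a 0-based cell id.
cell_bounds <- function(grid, cell_id) {
  res <- grid$resolution / 60
  row <- cell_id %/% grid$ncol
  col <- cell_id %% grid$ncol
  cbind(west = grid$bbox[["xmin"]] + col * res,
        south = grid$bbox[["ymin"]] + row * res,
        east = grid$bbox[["xmin"]] + (col + 1) * res,
        north = grid$bbox[["ymin"]] + (row + 1) * res)
}

#' Assign ecoregion labels to land cells
#'
#' Each land cell takes the label of the ecoregion polygon containing its
#' centroid (one label per cell by construction). Land cells whose centroid
#' falls in no ecoregion polygon take the label of the nearest labeled
#' centroid, so every land cell ends up labeled.
#'
#' @param grid a `surveygap_grid`.
#' @param ecoregions features from [read_geojson_polygons()]; each feature's
#'   label is taken from a `name`/`ecoregion`/`id` property, else its index.
#' @return the grid with `cells$ecoregion` filled for land cells.
#' @export
set_ecoregions <- function(grid, ecoregions) {
  cells <- grid$cells
  land <- which(cells$land)
  lab <- rep(NA_integer_, length(land))
  for (i in seq_along(ecoregions)) {
    f <- ecoregions[[i]]
    hit <- point_in_polygon(cells$lon[land], cells$lat[land], f$rings)
    lab[hit & is.na(lab)] <- i
  }
  if (any(is.na(lab))) {
    known <- which(!is.na(lab))
    if (length(known) == 0) stop("no land cell falls inside any ecoregion polygon")
    for (k in which(is.na(lab))) {
      d2 <- (cells$lon[land[known]] - cells$lon[land[k]])^2 +
        (cells$lat[land[known]] - cells$lat[land[k]])^2
      lab[k] <- lab[known[which.min(d2)]]
    }
  }
  grid$cells$ecoregion[land] <- lab
  grid
}

#' Export grid cell polygons as GeoJSON
#'
#' @param grid a `surveygap_grid`.
#' @param path output file.
#' @param land_only write land cells only (default TRUE).
#' @export
grid_to_geojson <- function(grid, path, land_only = TRUE) {
  cells <- grid$cells
  if (land_only) cells <- cells[cells$land, , drop = FALSE]
  b <- cell_bounds(grid, cells$cell_id)
  rings <- lapply(seq_len(nrow(cells)), function(i) {
    cbind(c(b[i, "west"], b[i, "east"], b[i, "east"], b[i, "west"]),
          c(b[i, "south"], b[i, "south"], b[i, "north"], b[i, "north"]))
  })
  write_geojson_polygons(rings,
    properties = cells[, c("cell_id", "ecoregion", "area_km2")], path = path)
}
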