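#' Tally occurrence records into grid cells
#'
#' Each record maps to the unique cell whose half-open interval
#' `[west, east) x [south, north)` contains it. Records outside the lattice
#' or on non-land cells are dropped and the drop counts reported as an
#' attribute; they are never fatal.
#'
#' @param records data.frame with columns `species`, `lon`, `lat`.
#' @param grid a `surveygap_grid`.
#' @return a `CellTable`: data.frame over land cells with `cell_id`, `row`,
#'   `col`, `lon`, `lat`, `area_km2`, `ecoregion`, `record_count`,
#'   `species_count` and `sampled` (`record_count >= 1`). Attribute
#'   `dropped` holds `c(outside = , sea = )`.
#' @export
assign_records <- function(records, grid) {
  stopifnot(all(c("species", "lon", "lat") %in% names(records)))
  cells <- grid$cells[grid$cells$land, , drop = FALSE]
  id <- locate_cells(grid, records$lon, records$lat)
  outside <- sum(is.na(id))
  onland <- !is.na(id) & id %in% cells$cell_id
  sea <- sum(!is.na(id) & !onland)
  idx <- match(id[onland], cells$cell_id)
  rc <- tabulate(idx, nbins = nrow(cells))
  sc <- integer(nrow(cells))
  if (any(onland)) {
    per <- unique(data.frame(idx = idx, species = records$species[onland]))
    sc <- tabulate(per$idx, nbins = nrow(cells))
  }
  out <- cells[, c("cell_id", "row", "col", "lon", "lat", "area_km2", "ecoregion")]
  out$record_count <- rc
  out$species_count <- sc
  out$sampled <- rc >= 1L
  rownames(out) <- NULL
  attr(out, "dropped") <- c(outside = outside, sea = sea)
  out
}

#' Count in-range grid cells per species
#'
#' A cell is in a species' range when its centroid lies inside the species'
#' range polygon (`rule = "centroid"`, the default) or when the polygon
#' overlaps any part of the cell (`rule = "intersect"`). Counts are over
#' land cells only. Species with zero in-range cells are flagged.
#'
#' @param range_polygons named list: per species a ring matrix, list of
#'   rings, or a feature from [read_geojson_polygons()].
#' @param grid a `surveygap_grid`.
#' @param rule `"centroid"` or `"intersect"`.
#' @return data.frame with `species`, `range_cells`; attribute `empty_range`
#'   names species with no in-range cell (excluded downstream with warning).
#' @export
range_size <- function(range_polygons, grid, rule = c("centroid", "intersect")) {
  rule <- match.arg(rule)
  inc <- range_incidence(range_polygons, grid, rule)
  n <- colSums(inc)
  out <- data.frame(species = colnames(inc), range_cells = as.integer(n))
  empty <- out$species[out$range_cells == 0]
  if (length(empty)) {
    warning("species with empty range on the grid: ", paste(empty, collapse = ", "))
  }
  attr(out, "empty_range") <- empty
  out
}

# land-cell x species incidence matrix
range_incidence <- function(range_polygons, grid, rule = "centroid") {
  cells <- grid$cells[grid$cells$land, , drop = FALSE]
  sp <- names(range_polygons)
  if (is.null(sp)) sp <- paste0("sp", seq_along(range_polygons))
  inc <- matrix(FALSE, nrow(cells), length(range_polygons),
                dimnames = list(NULL, sp))
  for (s in seq_along(range_polygons)) {
    rings <- species_rings(range_polygons[[s]])
    if (rule == "centroid") {
      inc[, s] <- point_in_polygon(cells$lon, cells$lat, rings)
    } else {
      b <- cell_bounds(grid, cells$cell_id)
      hit <- point_in_polygon(cells$lon, cells$lat, rings)
      for (i in which(!hit)) {
        rect <- cbind(c(b[i, "west"], b[i, "east"], b[i, "east"], b[i, "west"]),
                      c(b[i, "south"], b[i, "south"], b[i, "north"], b[i, "north"]))
        a <- sum(vapply(rings, function(r)
          abs(ring_area_signed(clip_polygon_convex(r, rect))), 0))
        hit[i] <- a > 0
      }
      inc[, s] <- hit
    }
  }
  inc
}

species_rings <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) return(list(x))
  if (is.list(x) && !is.null(x$rings)) return(x$rings)
  x
}

#' Species richness per cell from overlaid range maps
#'
#' Per-cell count of species whose range contains the cell (centroid rule):
#' the column sum of the species-by-cell incidence.
#'
#' @inheritParams range_size
#' @return integer vector of richness over land cells, in land-cell order.
#' @export
richness_overlay <- function(range_polygons, grid, rule = "centroid") {
  if (length(range_polygons) < 1) stop("need at least one species range")
  rowSums(range_incidence(range_polygons, grid, rule))
}

#' Build per-cell covariates from map layers
#'
#' Implements the standard cell summaries for a gap analysis: elevational
#' heterogeneity as max - min of elevation samples whose locations fall in
#' the cell; road density as total clipped road length (km) in the cell;
#' urban and protected percentages as area fractions times 100; population
#' density and homicide rate as area-weighted means of intersecting
#' polygons' values.
#'
#' @param layers named list; recognized elements:
#'   * `elevation`: data.frame `lon`, `lat`, `value` (raster samples),
#'   * `roads`: list of line matrices (lon/lat) or [read_geojson_lines()]
#'     features; lengths measured in km on the sphere,
#'   * `urban`, `protected`: polygon sets (area percentage per cell),
#'   * `population`, `homicide`: features with a `value` property
#'     (area-weighted mean per cell).
#' @param grid a `surveygap_grid`.
#' @return data.frame over land cells with one column per supplied layer
#'   (`elev_het`, `road_km`, `urban_pct`, `protected_pct`, `pop_density`,
#'   `homicide_rate`).
#' @export
covariate_build <- function(layers, grid) {
  cells <- grid$cells[grid$cells$land, , drop = FALSE]
  b <- cell_bounds(grid, cells$cell_id)
  out <- data.frame(cell_id = cells$cell_id)

  if (!is.null(layers$elevation)) {
    e <- layers$elevation
    id <- locate_cells(grid, e$lon, e$lat)
    idx <- match(id, cells$cell_id)
    keep <- !is.na(idx)
    hi <- tapply(e$value[keep], idx[keep], max)
    lo <- tapply(e$value[keep], idx[keep], min)
    het <- rep(0, nrow(cells))
    het[as.integer(names(hi))] <- hi - lo
    if (length(hi) < nrow(cells)) {
      warning(nrow(cells) - length(hi), " cell(s) had no elevation sample; heterogeneity set to 0")
    }
    out$elev_het <- het
  }

  if (!is.null(layers$roads)) {
    first <- layers$roads[[1]]
    lines <- if (is.list(first) && !is.matrix(first) && !is.data.frame(first) &&
                 !is.null(first$lines))
      unlist(lapply(layers$roads, `[[`, "lines"), recursive = FALSE) else layers$roads
    km <- numeric(nrow(cells))
    to <- pi / 180
    for (ln in lines) {
      m <- as.matrix(ln)
      for (s in seq_len(nrow(m) - 1)) {
        seg <- m[s:(s + 1), , drop = FALSE]
        cand <- which(b[, "west"] <= max(seg[, 1]) & b[, "east"] >= min(seg[, 1]) &
                      b[, "south"] <= max(seg[, 2]) & b[, "north"] >= min(seg[, 2]))
        for (i in cand) {
          frac <- segment_length_in_rect(seg[1, 1], seg[1, 2], seg[2, 1], seg[2, 2],
                                         b[i, "west"], b[i, "east"], b[i, "south"], b[i, "north"])
          if (frac > 0) {
            # degree length -> km at the cell's latitude
            full <- sqrt(sum((seg[2, ] - seg[1, ])^2))
            dlon <- (seg[2, 1] - seg[1, 1]) * cos(cells$lat[i] * to)
            dlat <- seg[2, 2] - seg[1, 2]
            kmlen <- 6371 * to * sqrt(dlon^2 + dlat^2)
            km[i] <- km[i] + kmlen * frac / full
          }
        }
      }
    }
    out$road_km <- km
  }

  for (nm in c("urban", "protected")) {
    if (is.null(layers[[nm]])) next
    rings <- boundary_rings(layers[[nm]])
    pct <- numeric(nrow(cells))
    for (i in seq_len(nrow(cells))) {
      rect <- cbind(c(b[i, "west"], b[i, "east"], b[i, "east"], b[i, "west"]),
                    c(b[i, "south"], b[i, "south"], b[i, "north"], b[i, "north"]))
      a <- sum(vapply(rings, function(r)
        abs(ring_area_signed(clip_polygon_convex(r, rect))), 0))
      pct[i] <- 100 * a / abs(ring_area_signed(rect))
    }
    out[[paste0(nm, "_pct")]] <- pmin(pct, 100)
  }

  for (nm in c("population", "homicide")) {
    if (is.null(layers[[nm]])) next
    feats <- layers[[nm]]
    val <- numeric(nrow(cells)); wt <- numeric(nrow(cells))
    for (f in feats) {
      v <- as.numeric(f$properties$value)
      for (i in seq_len(nrow(cells))) {
        rect <- cbind(c(b[i, "west"], b[i, "east"], b[i, "east"], b[i, "west"]),
                      c(b[i, "south"], b[i, "south"], b[i, "north"], b[i, "north"]))
        a <- sum(vapply(f$rings, function(r)
          abs(ring_area_signed(clip_polygon_convex(r, rect))), 0))
        val[i] <- val[i] + a * v
        wt[i] <- wt[i] + a
      }
    }
    col <- ifelse(wt > 0, val / pmax(wt, .Machine$double.eps), 0)
    out[[if (nm == "population") "pop_density" else "homicide_rate"]] <- col
  }
  out
}

#' Screen covariates for collinearity and standardize them
#'
#' Pearson correlations are computed over land cells; any pair with
#' `|r| >= threshold` (default 0.6) is flagged. Columns are standardized to
#' mean 0, SD 1 (n - 1 denominator).
#'
#' @param covariates data.frame of numeric covariate columns.
#' @param threshold absolute-correlation flag level.
#' @return list with `standardized` (data.frame, same names), `center`,
#'   `scale`, `correlation` (matrix) and `flagged` (data.frame of offending
#'   pairs, possibly empty).
#' @export
screen_and_standardize <- function(covariates, threshold = 0.6) {
  x <- as.data.frame(covariates)
  num <- vapply(x, is.numeric, TRUE)
  x <- x[num]
  if (nrow(x) < 2) stop("need at least 2 cells")
  sds <- vapply(x, sd, 0)
  if (any(sds == 0)) {
    stop("zero-variance covariate: ", paste(names(x)[sds == 0], collapse = ", "))
  }
  ctr <- vapply(x, mean, 0)
  std <- as.data.frame(mapply(function(col, m, s) (col - m) / s, x, ctr, sds,
                              SIMPLIFY = FALSE))
  cm <- cor(as.matrix(x))
  ut <- which(upper.tri(cm) & abs(cm) >= threshold, arr.ind = TRUE)
  flagged <- data.frame(var1 = rownames(cm)[ut[, 1]], var2 = colnames(cm)[ut[, 2]],
                        r = cm[ut])
  list(standardized = std, center = ctr, scale = sds,
       correlation = cm, flagged = flagged)
}
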