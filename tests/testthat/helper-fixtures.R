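# Shared fixtures, built in code.

unit_square <- function(x0 = 0, y0 = 0, w = 1, h = 1) {
  cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
}

# A fully-land rectangular grid without going through a boundary polygon.
toy_grid <- function(nrow, ncol, resolution = 5, origin = c(-100, 20)) {
  res <- resolution / 60
  boundary <- unit_square(origin[1], origin[2], ncol * res, nrow * res)
  build_grid(boundary, resolution)
}

# Independent Moran's I: direct double loop over the adjacency.
moran_oracle <- function(x, graph) {
  xc <- x - mean(x)
  num <- 0; W <- 0
  for (i in seq_len(graph$n)) for (j in graph$nbr[[i]]) {
    num <- num + xc[i] * xc[j]
    W <- W + 1
  }
  (graph$n / W) * num / sum(xc^2)
}

# Nearest-centroid rasterization: share of a fine lattice nearest to each
# generator, an independent oracle for Voronoi polygon areas.
voronoi_raster_shares <- function(pts, bbox, nside = 400) {
  gx <- seq(bbox[1], bbox[2], length.out = nside)
  gy <- seq(bbox[3], bbox[4], length.out = nside)
  pts <- as.matrix(pts)
  counts <- integer(nrow(pts))
  for (yy in gy) {
    d2 <- outer(gx, pts[, 1], function(a, b) (a - b)^2) +
      matrix((yy - pts[, 2])^2, length(gx), nrow(pts), byrow = TRUE)
    w <- max.col(-d2, ties.method = "first")
    tab <- tabulate(w, nbins = nrow(pts))
    counts <- counts + tab
  }
  counts / sum(counts)
}

default_landscape <- function(rows = 20, cols = 20, seed = 7, ...) {
  cfg <- sim_config(grid_rows = rows, grid_cols = cols, seed = seed, ...)
  list(cfg = cfg, land = make_landscape(cfg))
}
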