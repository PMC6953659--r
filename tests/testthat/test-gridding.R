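test_that("build_grid lays the documented lattice over a square boundary", {
  sq <- unit_square(0, 0, 1, 1)
  g30 <- build_grid(sq, resolution = 30)
  expect_equal(sum(g30$cells$land), 4)
  g5 <- build_grid(sq, resolution = 5)
  expect_equal(sum(g5$cells$land), 144)  # (60/5)^2
  expect_equal(g5$cells$cell_id, seq_len(nrow(g5$cells)) - 1L)
  expect_error(build_grid(sq[0, ]), "boundary")
})

test_that("cell area follows the spherical rectangle formula", {
  sq <- unit_square(10, -1, 2, 2)  # straddles the equator
  g <- build_grid(sq, resolution = 5)
  eq_cells <- g$cells[abs(g$cells$lat) < 5 / 60, ]
  expected <- (6371 * 5 * pi / (180 * 60))^2  # ~85.9 km^2 at lat 0
  expect_equal(mean(eq_cells$area_km2), expected, tolerance = 1e-4)
  # latitude dependence: cos factor
  far <- g$cells[which.max(g$cells$lat), ]
  expect_equal(far$area_km2, expected * cos(far$lat * pi / 180), tolerance = 1e-12)
})

test_that("assign_records tallies, classifies and reports drops", {
  g <- toy_grid(4, 4)
  empty <- assign_records(data.frame(species = character(), lon = numeric(),
                                     lat = numeric()), g)
  expect_equal(sum(empty$sampled), 0)
  expect_true(all(empty$record_count == 0))

  cells <- g$cells
  c1 <- cells[1, ]; c2 <- cells[7, ]
  rec <- data.frame(species = c("a", "a", "b", "b", "c"),
                    lon = c(rep(c1$lon, 3), c2$lon, -50),
                    lat = c(rep(c1$lat, 3), c2$lat, 0))
  ct <- assign_records(rec, g)
  expect_equal(sort(ct$record_count[ct$record_count > 0]), c(1, 3))
  expect_equal(sum(ct$sampled), 2)
  expect_equal(ct$species_count[ct$cell_id == c1$cell_id], 2)
  expect_equal(unname(attr(ct, "dropped")["outside"]), 1)
})

test_that("records re-grid to their generating cell (round trip)", {
  sc <- default_landscape(rows = 12, cols = 12, seed = 3)
  pool <- make_species_pool(sc$cfg, sc$land)
  sim <- simulate_records(sc$land, pool, sc$cfg)
  expect_gt(nrow(sim$records), 0)
  relocated <- locate_cells(sc$land$grid, sim$records$lon, sim$records$lat)
  expect_equal(relocated, sim$records$cell_id)
  # independent of record order
  perm <- sample(nrow(sim$records))
  ct1 <- assign_records(sim$records, sc$land$grid)
  ct2 <- assign_records(sim$records[perm, ], sc$land$grid)
  expect_equal(ct1, ct2, ignore_attr = TRUE)
})

test_that("range_size counts centroid-in-polygon cells over land", {
  g <- toy_grid(12, 12)
  bb <- g$bbox
  whole <- unit_square(bb["xmin"], bb["ymin"],
                       bb["xmax"] - bb["xmin"], bb["ymax"] - bb["ymin"])
  west <- unit_square(bb["xmin"], bb["ymin"],
                      (bb["xmax"] - bb["xmin"]) / 2, bb["ymax"] - bb["ymin"])
  rs <- range_size(list(all = whole, west = west), g)
  expect_equal(rs$range_cells[rs$species == "all"], 144)
  expect_equal(rs$range_cells[rs$species == "west"], 72)
  # disjoint two-part polygon: count is additive
  res <- g$resolution / 60
  part1 <- unit_square(bb["xmin"], bb["ymin"], 2 * res, 2 * res)
  part2 <- unit_square(bb["xmax"] - 3 * res, bb["ymax"] - 3 * res, 3 * res, 3 * res)
  rs2 <- range_size(list(p1 = part1, p2 = part2, both = list(part1, part2)), g)
  expect_equal(rs2$range_cells[rs2$species == "both"],
               rs2$range_cells[rs2$species == "p1"] +
               rs2$range_cells[rs2$species == "p2"])
  expect_equal(rs2$range_cells[rs2$species == "p1"], 4)
  # empty range flagged
  far <- unit_square(50, 50, 1, 1)
  expect_warning(rs3 <- range_size(list(gone = far), g), "empty range")
  expect_equal(attr(rs3, "empty_range"), "gone")
})

test_that("richness overlay equals the incidence column sums", {
  g <- toy_grid(10, 10)
  bb <- g$bbox
  w <- bb["xmax"] - bb["xmin"]; h <- bb["ymax"] - bb["ymin"]
  one <- unit_square(bb["xmin"], bb["ymin"], w, h)
  expect_true(all(richness_overlay(list(a = one), g) == 1))
  # two half-grid species overlapping in a central strip
  left <- unit_square(bb["xmin"], bb["ymin"], 0.6 * w, h)
  right <- unit_square(bb["xmin"] + 0.4 * w, bb["ymin"], 0.6 * w, h)
  rich <- richness_overlay(list(l = left, r = right), g)
  expect_setequal(unique(rich), c(1, 2))
  lon <- g$cells$lon[g$cells$land]
  overlap <- lon > bb["xmin"] + 0.4 * w & lon < bb["xmin"] + 0.6 * w
  expect_true(all(rich[overlap] == 2))
  expect_true(all(rich[!overlap] == 1))
  # double-counting identity on a random pool
  set.seed(5)
  pool <- lapply(1:6, function(i) {
    x0 <- runif(1, bb["xmin"], bb["xmax"] - 0.2)
    y0 <- runif(1, bb["ymin"], bb["ymax"] - 0.2)
    unit_square(x0, y0, runif(1, 0.05, 0.5), runif(1, 0.05, 0.5))
  })
  names(pool) <- paste0("s", 1:6)
  rich2 <- richness_overlay(pool, g)
  rs <- suppressWarnings(range_size(pool, g))
  expect_equal(sum(rich2), sum(rs$range_cells))
})

test_that("covariate_build summarises layers per cell", {
  g <- toy_grid(3, 3)
  cells <- g$cells
  b <- surveygap:::cell_bounds(g, cells$cell_id)
  # flat elevation -> heterogeneity 0 everywhere
  elev_pts <- data.frame(lon = rep(cells$lon, 2) + c(0, 0.01),
                         lat = rep(cells$lat, 2), value = 100)
  cov_flat <- covariate_build(list(elevation = elev_pts), g)
  expect_true(all(cov_flat$elev_het == 0))
  # per-cell max - min
  elev2 <- data.frame(lon = c(cells$lon[1], cells$lon[1] + 0.01),
                      lat = rep(cells$lat[1], 2), value = c(120, 350))
  cov2 <- suppressWarnings(covariate_build(list(elevation = elev2), g))
  expect_equal(cov2$elev_het[1], 230)
  # road segment of known km length inside one cell
  to <- pi / 180
  lat0 <- cells$lat[5]
  dlat <- 7.3 / (6371 * to)  # meridian arc of exactly 7.3 km
  road <- list(cbind(c(cells$lon[5], cells$lon[5]),
                     c(lat0 - dlat / 2, lat0 + dlat / 2)))
  cov3 <- covariate_build(list(roads = road), g)
  expect_equal(cov3$road_km[5], 7.3, tolerance = 1e-9)
  expect_equal(sum(cov3$road_km), 7.3, tolerance = 1e-9)
  # city polygon covering the western half of cell 1 -> urban 50%
  half <- unit_square(b[1, "west"], b[1, "south"],
                      (b[1, "east"] - b[1, "west"]) / 2,
                      b[1, "north"] - b[1, "south"])
  cov4 <- covariate_build(list(urban = list(half)), g)
  expect_equal(cov4$urban_pct[1], 50, tolerance = 1e-9)
  expect_equal(sum(cov4$urban_pct[-1]), 0)
  # area-weighted mean for polygon-valued layers
  g1 <- toy_grid(1, 1)
  b1 <- surveygap:::cell_bounds(g1, 0L)
  wcell <- b1[1, "east"] - b1[1, "west"]
  left <- list(rings = list(unit_square(b1[1, "west"], b1[1, "south"],
                                        wcell / 4, b1[1, "north"] - b1[1, "south"])),
               properties = list(value = 10))
  rest <- list(rings = list(unit_square(b1[1, "west"] + wcell / 4, b1[1, "south"],
                                        3 * wcell / 4, b1[1, "north"] - b1[1, "south"])),
               properties = list(value = 50))
  cov5 <- covariate_build(list(homicide = list(left, rest)), g1)
  expect_equal(cov5$homicide_rate, 0.25 * 10 + 0.75 * 50, tolerance = 1e-9)
})

test_that("screening flags collinear pairs and standardization is exact", {
  set.seed(1)
  x <- as.data.frame(matrix(rnorm(700), 100, 7))
  names(x) <- paste0("v", 1:7)
  x$v7 <- x$v1  # identical copy
  sc <- screen_and_standardize(x)
  expect_true(any(sc$flagged$var1 == "v1" & sc$flagged$var2 == "v7"))
  expect_equal(sc$correlation["v1", "v7"], 1)
  for (cn in names(sc$standardized)) {
    expect_equal(mean(sc$standardized[[cn]]), 0, tolerance = 1e-10)
    expect_equal(sd(sc$standardized[[cn]]), 1, tolerance = 1e-10)
  }
  # correlation matrix equals the brute-force pairwise formula
  brute <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  for (i in 1:6) for (j in (i + 1):7) {
    expect_equal(sc$correlation[i, j], brute(x[[i]], x[[j]]), tolerance = 1e-12)
  }
  # de-standardization recovers the input
  back <- sweep(sweep(as.matrix(sc$standardized), 2, sc$scale, "*"),
                2, sc$center, "+")
  expect_equal(unname(back), unname(as.matrix(x)), tolerance = 1e-9)
  # zero-variance column is an error naming the column
  x$v3 <- 5
  expect_error(screen_and_standardize(x), "v3")
})
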