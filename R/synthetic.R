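# Synthetic-landscape generator: lattice landscapes with contiguous
# ecoregions, autocorrelated covariates, species pools with connected
# log-spread ranges and foraging guilds, and occurrence records whose
# intensity carries covariate effects plus an exact ICAR spatial effect.
# Ground truth is returned alongside, so every downstream stage of the
# pipeline can be tested against known parameters.

#' Configuration for the synthetic landscape generator
#'
#' Defaults emulate the study conditions the pipeline is designed for: a
#' 5 arc-minute land grid partitioned into 7 contiguous ecoregions, a
#' bat-like species pool with log-spread range sizes and three foraging
#' guilds (open/edge/narrow-space, mixed 20/45/35 as in a typical
#' assemblage where edge-space vespertilionids dominate and narrow-space
#' phyllostomids are common), spatially autocorrelated covariates, and
#' per-guild detectability reflecting that narrow-space foragers are the
#' easiest to capture with mist nets.
#'
#' @param grid_rows,grid_cols lattice dimensions (all cells land).
#' @param n_ecoregions number of contiguous ecoregions (>= 2; default 7).
#' @param n_species species pool size (default 134).
#' @param guild_mix proportions (open, edge, narrow) summing to 1.
#' @param beta_true covariate effects on log sampling intensity (length 7).
#' @param alpha_true intercept of log sampling intensity.
#' @param tau_true ICAR precision of the spatial effect (> 0; `Inf` for no
#'   spatial effect).
#' @param guild_detect per-guild detection multiplier in (0, 1]
#'   (open, edge, narrow).
#' @param b_target optional per-guild power-law exponents; when set,
#'   per-species detection is calibrated so the expected number of sampled
#'   cells scales as `range_cells^b` within each guild.
#' @param range_min,range_max range-size bounds in cells for the log-uniform
#'   draw (defaults 1 and the full grid).
#' @param nb_size optional negative-binomial size for per-cell record
#'   counts; `NULL` (default) keeps Poisson counts.
#' @param origin lon/lat of the grid's south-west corner.
#' @param resolution cell size in arc-minutes.
#' @param seed integer RNG seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(grid_rows = 30, grid_cols = 30, n_ecoregions = 7,
                       n_species = 134,
                       guild_mix = c(open = 0.20, edge = 0.45, narrow = 0.35),
                       beta_true = c(richness = 0.4, elev_het = 0.3,
                                     protected_pct = 0.25, road_km = 0.35,
                                     urban_pct = 0.25, pop_density = 0.1,
                                     homicide_rate = -0.2),
                       alpha_true = -1.5, tau_true = 2,
                       guild_detect = c(open = 0.3, edge = 0.5, narrow = 1),
                       b_target = NULL, range_min = 1, range_max = NULL,
                       nb_size = NULL, origin = c(-105, 18), resolution = 5,
                       seed = 1L) {
  stopifnot(grid_rows * grid_cols >= 4,
            n_ecoregions >= 2, n_species >= 3,
            length(guild_mix) == 3, length(beta_true) == 7,
            tau_true > 0)
  if (abs(sum(guild_mix) - 1) > 1e-9) stop("guild_mix must sum to 1")
  if (any(guild_detect <= 0 | guild_detect > 1)) {
    stop("guild_detect multipliers must lie in (0, 1]")
  }
  if (!is.null(b_target) && length(b_target) != 3) {
    stop("b_target needs one exponent per guild")
  }
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 n_ecoregions = as.integer(n_ecoregions),
                 n_species = as.integer(n_species),
                 guild_mix = guild_mix, beta_true = beta_true,
                 alpha_true = alpha_true, tau_true = tau_true,
                 guild_detect = guild_detect, b_target = b_target,
                 range_min = range_min, range_max = range_max,
                 nb_size = nb_size, origin = origin, resolution = resolution,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic landscape
#'
#' Builds a full land grid, grows the requested number of contiguous
#' ecoregions from random seed cells (multi-source random-frontier
#' expansion: a Voronoi-like partition in graph distance), and draws 7
#' covariate surfaces with first-order spatial autocorrelation by repeated
#' neighbor-kernel smoothing of white noise, then transforms them onto
#' plausible scales (species richness counts, meters of relief, percentages,
#' km of road, densities).
#'
#' @param config a [sim_config()].
#' @return list with `grid` (a `surveygap_grid` with ecoregions set),
#'   `covariates` (data.frame, 7 columns over land cells), `cor`
#'   (pairwise covariate correlations) and `graph` (queen adjacency).
#' @export
make_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  res <- config$resolution / 60
  xmin <- config$origin[1]; ymin <- config$origin[2]
  nrow <- config$grid_rows; ncol <- config$grid_cols
  cells <- lattice_cells(xmin, ymin, nrow, ncol, res)
  g <- structure(list(resolution = config$resolution,
                      bbox = c(xmin = xmin, ymin = ymin,
                               xmax = xmin + ncol * res, ymax = ymin + nrow * res),
                      nrow = nrow, ncol = ncol, cells = cells),
                 class = "surveygap_grid")
  graph <- build_adjacency(g, type = "queen")
  g$cells$ecoregion <- grow_partition(graph, config$n_ecoregions)

  n <- nrow * ncol
  smooth_field <- function(passes = 4) {
    x <- rnorm(n)
    for (p in seq_len(passes)) {
      x <- vapply(seq_len(n), function(i) {
        js <- graph$nbr[[i]]
        mean(c(x[i], x[js]))
      }, 0)
    }
    (x - mean(x)) / sd(x)
  }
  z <- replicate(7, smooth_field())
  covariates <- data.frame(
    richness = pmax(0, round(25 + 10 * z[, 1])),
    elev_het = pmax(0, 400 + 300 * z[, 2]),
    protected_pct = 100 * pnorm(z[, 3] - 1),
    road_km = pmax(0, 8 + 5 * z[, 4]),
    urban_pct = 100 * pnorm(z[, 5] - 1.5),
    pop_density = exp(3 + z[, 6]),
    homicide_rate = pmax(0, 10 + 6 * z[, 7]))
  list(grid = g, covariates = covariates,
       cor = cor(as.matrix(covariates)), graph = graph)
}

# contiguous partition by multi-source random-frontier growth
grow_partition <- function(graph, k) {
  n <- graph$n
  lab <- integer(n)
  seeds <- sample.int(n, k)
  lab[seeds] <- seq_len(k)
  frontier <- unique(unlist(lapply(seeds, function(s) graph$nbr[[s]])))
  frontier <- frontier[lab[frontier] == 0L]
  while (length(frontier)) {
    v <- if (length(frontier) == 1) frontier else sample(frontier, 1)
    labs <- lab[graph$nbr[[v]]]
    labs <- labs[labs > 0L]
    lab[v] <- if (length(labs) == 1) labs else sample(labs, 1)
    frontier <- frontier[frontier != v]
    new <- graph$nbr[[v]]
    frontier <- unique(c(frontier, new[lab[new] == 0L]))
  }
  # any stranded cells (possible only on disconnected graphs): nearest label
  if (any(lab == 0L)) lab[lab == 0L] <- 1L
  lab
}

#' Generate a synthetic species pool
#'
#' Range sizes are drawn log-uniformly between `range_min` and `range_max`
#' cells; each range is grown as a connected blob from a random seed cell
#' by uniform random frontier expansion (contiguous, like an IUCN range
#' polygon rasterized to the grid). Guilds are assigned independently with
#' probabilities `guild_mix`.
#'
#' @param config a [sim_config()].
#' @param landscape result of [make_landscape()].
#' @return list with `species` (data.frame: `species`, `guild`,
#'   `range_cells`) and `ranges` (list of 0-based cell-id vectors).
#' @export
make_species_pool <- function(config, landscape) {
  grid <- landscape$grid
  graph <- landscape$graph
  set.seed(config$seed + 1L)
  n_land <- graph$n
  rmin <- max(1, config$range_min)
  rmax <- min(if (is.null(config$range_max)) n_land else config$range_max, n_land)
  sizes <- pmin(pmax(round(exp(runif(config$n_species, log(rmin), log(rmax)))),
                     rmin), rmax)
  guilds <- c("open", "edge", "narrow")[
    sample.int(3, config$n_species, replace = TRUE, prob = config$guild_mix)]
  ranges <- lapply(sizes, function(sz) grow_blob(graph, sz))
  data_sp <- data.frame(species = sprintf("sp%03d", seq_len(config$n_species)),
                        guild = guilds,
                        range_cells = vapply(ranges, length, 0L))
  names(ranges) <- data_sp$species
  # 0-based cell ids
  ranges <- lapply(ranges, function(idx) graph$ids[idx])
  list(species = data_sp, ranges = ranges)
}

# connected blob of `size` nodes by uniform random frontier expansion
grow_blob <- function(graph, size) {
  n <- graph$n
  inset <- logical(n)
  start <- sample.int(n, 1)
  inset[start] <- TRUE
  cur <- 1L
  frontier <- graph$nbr[[start]]
  while (cur < size && length(frontier)) {
    v <- if (length(frontier) == 1) frontier else sample(frontier, 1)
    inset[v] <- TRUE
    cur <- cur + 1L
    frontier <- frontier[frontier != v]
    new <- graph$nbr[[v]]
    frontier <- unique(c(frontier, new[!inset[new]]))
    frontier <- frontier[!inset[frontier]]
  }
  which(inset)
}

#' Simulate biased occurrence records
#'
#' Per-cell log sampling intensity is `alpha + beta'x + phi` with `x` the
#' standardized covariates and `phi` an exact ICAR draw at `tau_true`
#' (sum-to-zero per component; all zeros when `tau_true = Inf`). Per
#' species and cell, record counts are Poisson
#' (`intensity * detect * [cell in range]`), where `detect` is the guild
#' detection multiplier — or, when `b_target` is set, a per-species value
#' calibrated so the expected sampled-cell count follows the requested
#' power law of range size. Each record is emitted at the cell centroid
#' jittered uniformly within the cell, so records re-grid exactly to their
#' generating cell.
#'
#' @param landscape result of [make_landscape()].
#' @param pool result of [make_species_pool()].
#' @param config the same [sim_config()].
#' @return list with `records` (data.frame: `species`, `lon`, `lat`,
#'   `cell_id`) and `truth` (list: `alpha`, `beta`, `phi`, `tau`, `lambda`,
#'   `detect`, `ranges`, `guilds`).
#' @export
simulate_records <- function(landscape, pool, config) {
  grid <- landscape$grid
  graph <- landscape$graph
  if (nrow(landscape$covariates) != graph$n) stop("landscape and grid mismatch")
  set.seed(config$seed + 2L)
  X <- scale(as.matrix(landscape$covariates))
  phi <- sample_icar_phi(graph, config$tau_true)
  eta <- config$alpha_true + drop(X %*% config$beta_true) + phi
  lambda <- exp(eta)

  guild_idx <- match(pool$species$guild, c("open", "edge", "narrow"))
  if (is.null(config$b_target)) {
    detect <- config$guild_detect[guild_idx]
  } else {
    # calibrate so E[# sampled cells] = a * range^b within each guild:
    # per-cell sampling probability p_s = a * range^(b-1), with a chosen so
    # the largest probability in the guild stays at 0.9
    x <- pool$species$range_cells
    b <- config$b_target[guild_idx]
    p_s <- numeric(length(x))
    for (gidx in 1:3) {
      sel <- guild_idx == gidx
      if (!any(sel)) next
      bg <- config$b_target[gidx]
      a <- 0.9 / max(x[sel]^(bg - 1))
      p_s[sel] <- a * x[sel]^(bg - 1)
    }
    detect <- p_s  # interpreted per cell below
  }

  rec_sp <- character(0); rec_cell <- integer(0)
  counts_list <- vector("list", nrow(pool$species))
  for (s in seq_len(nrow(pool$species))) {
    cells0 <- pool$ranges[[s]]
    idx <- match(cells0, graph$ids)
    if (is.null(config$b_target)) {
      mu <- lambda[idx] * detect[s]
    } else {
      # per-cell rate giving P(count >= 1) = p_s exactly
      mu <- rep(-log(1 - detect[s]), length(idx))
    }
    cnt <- if (is.null(config$nb_size)) rpois(length(mu), mu)
           else rnbinom(length(mu), size = config$nb_size, mu = mu)
    pos <- cnt > 0
    if (any(pos)) {
      rec_sp <- c(rec_sp, rep(pool$species$species[s], sum(cnt[pos])))
      rec_cell <- c(rec_cell, rep(cells0[pos], cnt[pos]))
    }
  }
  b <- cell_bounds(grid, rec_cell)
  res <- grid$resolution / 60
  lon <- b[, "west"] + runif(length(rec_cell)) * res
  lat <- b[, "south"] + runif(length(rec_cell)) * res
  records <- data.frame(species = rec_sp, lon = lon, lat = lat,
                        cell_id = rec_cell)
  truth <- list(alpha = config$alpha_true, beta = config$beta_true,
                phi = phi, tau = config$tau_true, lambda = lambda,
                detect = detect, ranges = pool$ranges,
                guilds = pool$species$guild)
  list(records = records, truth = truth)
}

#' Simulate four threat-change surfaces
#'
#' Smooth (neighbor-kernel) fields for the 2050s-minus-current changes in
#' annual mean temperature (degrees C), annual precipitation (mm), forest
#' proportion and cropland proportion (percentage points). An optional
#' hotspot ecoregion gets amplified warming/drying/deforestation, for
#' constructing scenarios where threat concentrates in a known stratum.
#'
#' @param landscape result of [make_landscape()].
#' @param config a [sim_config()] (seed source).
#' @param scenario `"business-as-usual"` (larger land-use change) or
#'   `"sustainable"`.
#' @param hotspot_ecoregion optional ecoregion label whose cells get an
#'   amplified threat signal.
#' @return data.frame over land cells: `cell_id`, `delta_T`, `delta_P`,
#'   `delta_forest`, `delta_farmland`, with attribute `scenario`.
#' @export
make_threats <- function(landscape, config,
                         scenario = c("business-as-usual", "sustainable"),
                         hotspot_ecoregion = NULL) {
  scenario <- match.arg(scenario)
  graph <- landscape$graph
  set.seed(config$seed + 3L)
  n <- graph$n
  smooth <- function() {
    x <- rnorm(n)
    for (p in 1:4) {
      x <- vapply(seq_len(n), function(i) mean(c(x[i], x[graph$nbr[[i]]])), 0)
    }
    (x - mean(x)) / sd(x)
  }
  lu <- if (scenario == "business-as-usual") 1 else 0.4
  out <- data.frame(cell_id = graph$ids,
                    delta_T = 2 + 0.6 * smooth(),
                    delta_P = -20 + 60 * smooth(),
                    delta_forest = lu * (-8 + 5 * smooth()),
                    delta_farmland = lu * (6 + 4 * smooth()))
  if (!is.null(hotspot_ecoregion)) {
    eco <- landscape$grid$cells$ecoregion[match(graph$ids,
                                                landscape$grid$cells$cell_id)]
    hot <- eco == hotspot_ecoregion
    out$delta_T[hot] <- out$delta_T[hot] + 2
    out$delta_P[hot] <- out$delta_P[hot] - 80
    out$delta_forest[hot] <- out$delta_forest[hot] - 15
    out$delta_farmland[hot] <- out$delta_farmland[hot] + 12
  }
  attr(out, "scenario") <- scenario
  out
}

#' Write a simulated study to disk
#'
#' Emits `records.csv` (species, lon, lat), `cells.csv`, `species.csv`,
#' `truth.json` and `grid.geojson` into a directory.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
simulate_study <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  land <- make_landscape(config)
  pool <- make_species_pool(config, land)
  sim <- simulate_records(land, pool, config)
  cells <- assign_records(sim$records, land$grid)
  cells <- cbind(cells, land$covariates)
  sampled_per_sp <- tapply(sim$records$cell_id, sim$records$species,
                           function(x) length(unique(x)))
  sp <- pool$species
  sp$sampled_cells <- as.integer(sampled_per_sp[sp$species])
  sp$sampled_cells[is.na(sp$sampled_cells)] <- 0L
  paths <- list(
    records = file.path(dir, "records.csv"),
    cells = file.path(dir, "cells.csv"),
    species = file.path(dir, "species.csv"),
    truth = file.path(dir, "truth.json"),
    grid = file.path(dir, "grid.geojson"))
  write.csv(sim$records[, c("species", "lon", "lat")], paths$records,
            row.names = FALSE)
  write.csv(cells, paths$cells, row.names = FALSE)
  write.csv(sp, paths$species, row.names = FALSE)
  jsonlite::write_json(
    list(alpha = sim$truth$alpha, beta = as.list(sim$truth$beta),
         tau = sim$truth$tau, phi = sim$truth$phi,
         guilds = sim$truth$guilds),
    paths$truth, auto_unbox = TRUE, digits = NA)
  grid_to_geojson(land$grid, paths$grid)
  invisible(paths)
}
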