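# Threat overlay: 2050s-minus-current change surfaces, univariate
# presence-vs-threat spatial models, and priority survey areas.

#' Build the four threat-change variables
#'
#' Future-minus-current differences per land cell for annual mean
#' temperature (degrees C), annual precipitation (mm), and forest and
#' cropland cover (percentage points; land-class proportions are computed
#' before differencing). Inputs must be co-registered with the grid: per
#' land cell in land-cell order, or point samples resampled by nearest
#' cell.
#'
#' @param current,future named lists with elements `temperature`,
#'   `precipitation`, `forest`, `cropland`; each a numeric vector over land
#'   cells (proportions in `[0, 1]` for the land classes) or a data.frame
#'   `lon`, `lat`, `value` of samples to resample by nearest cell.
#' @param grid a `surveygap_grid`.
#' @param scenario label attached to the output.
#' @return a `ThreatTable`: data.frame over land cells with `cell_id`,
#'   `delta_T`, `delta_P`, `delta_forest`, `delta_farmland` and a `missing`
#'   flag for cells lacking any input; attribute `scenario`.
#' @export
build_threats <- function(current, future, grid,
                          scenario = c("business-as-usual", "sustainable")) {
  scenario <- match.arg(scenario)
  need <- c("temperature", "precipitation", "forest", "cropland")
  if (!all(need %in% names(current)) || !all(need %in% names(future))) {
    stop("current and future need elements: ", paste(need, collapse = ", "))
  }
  cells <- grid$cells[grid$cells$land, ]
  as_cell_vector <- function(x) {
    if (is.data.frame(x)) {
      id <- locate_cells(grid, x$lon, x$lat)
      idx <- match(cells$cell_id, id)
      return(x$value[idx])
    }
    if (length(x) != nrow(cells)) stop("layer not aligned with land cells")
    as.numeric(x)
  }
  cur <- lapply(current[need], as_cell_vector)
  fut <- lapply(future[need], as_cell_vector)
  for (nm in c("forest", "cropland")) {
    bad <- c(cur[[nm]], fut[[nm]])
    if (any(bad < 0 | bad > 1, na.rm = TRUE)) {
      stop(nm, " proportions must lie in [0, 1] before differencing")
    }
  }
  out <- data.frame(cell_id = cells$cell_id,
                    delta_T = fut$temperature - cur$temperature,
                    delta_P = fut$precipitation - cur$precipitation,
                    delta_forest = 100 * (fut$forest - cur$forest),
                    delta_farmland = 100 * (fut$cropland - cur$cropland))
  out$missing <- !complete.cases(out)
  if (any(out$missing)) {
    warning(sum(out$missing), " cell(s) lack threat inputs; excluded from model fits")
  }
  attr(out, "scenario") <- scenario
  out
}

#' Univariate presence-vs-threat spatial model
#'
#' Bernoulli-logit ICAR regression of record presence on one standardized
#' threat variable, for a coefficient dot-and-whisker comparison across
#' threats.
#'
#' @param presence 0/1 vector over graph nodes.
#' @param threat numeric threat column over graph nodes (standardized
#'   internally).
#' @param graph `AdjacencyGraph` over the same cells.
#' @param config an [icar_config()]; the family is forced to
#'   bernoulli-logit.
#' @return list with `summary` (the threat coefficient row: posterior
#'   median, 50%/95% credible intervals, credibly-nonzero flag) and `fit`
#'   (the full `ICARFit`).
#' @export
univariate_threat_car <- function(presence, threat, graph,
                                  config = icar_config(schedule = "desk")) {
  keep <- is.finite(threat)
  if (!all(keep)) stop("threat column has missing values; subset the graph first")
  x <- (threat - mean(threat)) / sd(threat)
  config$family <- "bernoulli-logit"
  fit <- fit_icar(presence, matrix(x, dimnames = list(NULL, "threat")),
                  graph, config)
  s <- summarize_icar(fit)
  list(summary = s[s$parameter == "threat", , drop = FALSE], fit = fit)
}

#' Priority survey areas from sampling gaps and threat exposure
#'
#' Composite threat score per cell: the mean of the standardized magnitudes
#' of the four threats, oriented so larger = worse — `|delta_T|`,
#' `|delta_P|`, deforestation (`-delta_forest` clipped at 0) and farmland
#' expansion (`delta_farmland` clipped at 0). Priority cells are un-sampled
#' cells whose score falls in the top `top_fraction` among un-sampled
#' cells (ties broken by cell id).
#'
#' @param cells a `CellTable` (needs `cell_id`, `sampled`, `ecoregion`).
#' @param threats a `ThreatTable` from [build_threats()] or
#'   [make_threats()].
#' @param top_fraction fraction of un-sampled cells to flag (default 0.1).
#' @return a `PriorityMap`: data.frame with `cell_id`, `sampled`,
#'   `threat_score`, `priority`, plus `ecoregion`.
#' @export
priority_map <- function(cells, threats, top_fraction = 0.1) {
  stopifnot(top_fraction > 0, top_fraction < 1)
  idx <- match(cells$cell_id, threats$cell_id)
  if (any(is.na(idx))) stop("threat table does not cover all cells")
  th <- threats[idx, ]
  comp <- cbind(abs(th$delta_T), abs(th$delta_P),
                pmax(-th$delta_forest, 0), pmax(th$delta_farmland, 0))
  comp <- apply(comp, 2, function(col) {
    s <- sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  score <- rowMeans(comp)
  out <- data.frame(cell_id = cells$cell_id, ecoregion = cells$ecoregion,
                    sampled = cells$sampled, threat_score = score,
                    priority = FALSE)
  uns <- which(!out$sampled)
  n_pri <- max(1L, floor(length(uns) * top_fraction + 1e-9))
  if (length(uns)) {
    ord <- uns[order(-out$threat_score[uns], out$cell_id[uns])]
    out$priority[ord[seq_len(min(n_pri, length(ord)))]] <- TRUE
  }
  out
}
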