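# Randomization-calibrated ecoregion sampling-bias statistic and the
# chi-squared representativeness test.

#' Randomization estimate of ecoregion cell-share under unbiased sampling
#'
#' Draws `n_reps` sets of `N` distinct land cells uniformly without
#' replacement (a cell cannot be "sampled" twice) and returns the mean
#' fraction falling in each ecoregion, together with the replicate-level
#' counts used for chi-squared expected values.
#'
#' @param grid a `surveygap_grid` with ecoregions assigned.
#' @param N number of cells per random set (the observed number of sampled
#'   cells).
#' @param n_reps number of random sets (default 100).
#' @param seed optional integer seed.
#' @return list with `p` (named mean fractions per ecoregion, summing to 1),
#'   `counts` (replicate x ecoregion matrix) and `ecoregions` (labels).
#' @export
estimate_p <- function(grid, N, n_reps = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  land <- grid$cells[grid$cells$land, ]
  if (any(is.na(land$ecoregion))) stop("land cells lack ecoregion labels")
  if (N > nrow(land)) stop("N exceeds the number of land cells")
  eco <- sort(unique(land$ecoregion))
  counts <- matrix(0L, n_reps, length(eco), dimnames = list(NULL, eco))
  for (r in seq_len(n_reps)) {
    draw <- land$ecoregion[sample.int(nrow(land), N)]
    counts[r, ] <- tabulate(match(draw, eco), nbins = length(eco))
  }
  p <- colMeans(counts) / N
  list(p = p, counts = counts, ecoregions = eco)
}

#' Ecoregion sampling-bias statistic
#'
#' `(n_d - p_d N) / sqrt(p_d (1 - p_d) N)`: the standardized deviation of
#' the observed sampled-cell count in stratum d from its randomization
#' expectation. Positive values indicate over-sampling of the stratum,
#' negative values under-sampling.
#'
#' @param n_d observed sampled-cell count in the stratum.
#' @param p_d expected fraction of sampled cells in the stratum (0 < p < 1).
#' @param N total sampled cells.
#' @return the bias score (vectorized over strata).
#' @export
bias_d <- function(n_d, p_d, N) {
  stopifnot(N >= 1)
  if (any(p_d <= 0 | p_d >= 1)) stop("degenerate stratum: p_d must lie in (0, 1)")
  (n_d - p_d * N) / sqrt(p_d * (1 - p_d) * N)
}

#' Chi-squared representativeness test
#'
#' `chi2 = sum (obs - exp)^2 / exp` with `df = k - 1`, upper-tail p-value:
#' do sampled cells fall into different proportions of strata than expected
#' by chance?
#'
#' @param observed per-stratum observed counts.
#' @param expected per-stratum expected counts (`p_d * N`); all > 0.
#' @return list with `chi2`, `df`, `p_value`.
#' @export
chisq_representativeness <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  if (any(expected <= 0)) stop("expected counts must be positive")
  if (any(expected < 1)) {
    warning("expected count < 1 in some stratum; test validity is doubtful")
  }
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(chi2 = chi2, df = df, p_value = pchisq(chi2, df, lower.tail = FALSE))
}

#' Per-ecoregion sampling-bias table
#'
#' Ties the pieces together for a cell table: counts sampled cells per
#' ecoregion, estimates `p_d` by randomization, computes the bias score
#' for every ecoregion and the chi-squared representativeness test.
#'
#' @param cells a `CellTable` from [assign_records()] (needs `ecoregion`
#'   and `sampled`).
#' @param grid the `surveygap_grid` the cells came from.
#' @param n_reps random sets for the `p_d` estimate (default 100).
#' @param seed optional integer seed for the randomization.
#' @param expected `"replicate-mean"` (default) uses `p_d * N` from the
#'   mean over random sets; `"single-set"` uses the counts of one random
#'   set, for sensitivity checks.
#' @return a `BiasTable`: data.frame with `ecoregion`, `n_d`, `p_d`,
#'   `bias_d`; attributes `N`, `chi2`, `df`, `p_value`.
#' @export
ecoregion_bias <- function(cells, grid, n_reps = 100, seed = NULL,
                           expected = c("replicate-mean", "single-set")) {
  expected <- match.arg(expected)
  N <- sum(cells$sampled)
  if (N < 1) stop("no sampled cells")
  est <- estimate_p(grid, N, n_reps = n_reps, seed = seed)
  eco <- est$ecoregions
  n_d <- vapply(eco, function(e) sum(cells$sampled & cells$ecoregion == e), 0L)
  tab <- data.frame(ecoregion = eco, n_d = n_d, p_d = est$p,
                    bias_d = bias_d(n_d, est$p, N), row.names = NULL)
  exp_counts <- if (expected == "replicate-mean") est$p * N else est$counts[1, ]
  test <- chisq_representativeness(n_d, exp_counts)
  attr(tab, "N") <- N
  attr(tab, "chi2") <- test$chi2
  attr(tab, "df") <- test$df
  attr(tab, "p_value") <- test$p_value
  tab
}
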