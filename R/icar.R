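#' Lattice adjacency graph for a set of grid cells
#'
#' Queen (8-neighbor, default) or rook (4-neighbor) adjacency restricted to
#' a subset of cells. The graph is symmetric with no self-loops; isolated
#' nodes and connected components are reported.
#'
#' @param grid a `surveygap_grid`.
#' @param subset 0-based cell ids to include; default all land cells.
#' @param type `"queen"` or `"rook"`.
#' @return an `AdjacencyGraph`: list with `n`, `ids` (cell ids in order),
#'   `nbr` (list of 1-based neighbor indices), `m` (neighbor counts),
#'   `comp` (1-based component labels), `n_comp`, `n_isolated`.
#' @export
build_adjacency <- function(grid, subset = NULL, type = c("queen", "rook")) {
  type <- match.arg(type)
  if (is.null(subset)) subset <- grid$cells$cell_id[grid$cells$land]
  if (length(subset) == 0) stop("empty cell subset")
  ids <- sort(unique(as.integer(subset)))
  row <- ids %/% grid$ncol
  col <- ids %% grid$ncol
  key <- row * grid$ncol + col
  offsets <- if (type == "queen") {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  index <- rep(NA_integer_, grid$nrow * grid$ncol)
  index[key + 1L] <- seq_along(ids)
  nbr <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rr <- row[i] + offsets[, "dr"]
    cc <- col[i] + offsets[, "dc"]
    ok <- rr >= 0 & rr < grid$nrow & cc >= 0 & cc < grid$ncol
    cand <- index[rr[ok] * grid$ncol + cc[ok] + 1L]
    nbr[[i]] <- sort(cand[!is.na(cand)])
  }
  m <- lengths(nbr)
  comp <- graph_components(nbr)
  structure(list(n = length(ids), ids = ids, nbr = nbr, m = m,
                 comp = comp, n_comp = max(comp),
                 n_isolated = sum(m == 0), type = type),
            class = "surveygap_adjacency")
}

# connected components by BFS over a neighbor list
graph_components <- function(nbr) {
  n <- length(nbr)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in nbr[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

#' ICAR pairwise-difference log-density
#'
#' `(n - C)/2 * log(tau) - (tau/2) * sum_{i~j} (phi_i - phi_j)^2` over
#' unique neighbor pairs (constant terms in 2*pi dropped). `n - C` counts
#' non-isolated nodes minus their components: the rank of the graph
#' Laplacian, i.e. the dimension the improper prior is proper on.
#'
#' @param phi numeric vector of spatial effects.
#' @param graph an `AdjacencyGraph`.
#' @param tau ICAR precision (> 0).
#' @return log-density up to an additive constant.
#' @export
icar_logdensity <- function(phi, graph, tau) {
  stopifnot(length(phi) == graph$n, tau > 0)
  ssq <- 0
  for (i in seq_len(graph$n)) {
    js <- graph$nbr[[i]]
    js <- js[js > i]
    if (length(js)) ssq <- ssq + sum((phi[i] - phi[js])^2)
  }
  non_iso <- sum(graph$m > 0)
  c_eff <- length(unique(graph$comp[graph$m > 0]))
  (non_iso - c_eff) / 2 * log(tau) - tau / 2 * ssq
}

#' Exact draw from the ICAR prior on its proper subspace
#'
#' Uses the eigendecomposition of the graph Laplacian with null eigenvectors
#' removed, so draws sum to zero within every connected component and have
#' the exact pairwise-difference covariance structure at precision `tau`.
#' Isolated nodes get 0. Uses the current RNG state.
#'
#' @param graph an `AdjacencyGraph`.
#' @param tau ICAR precision; `Inf` returns all zeros.
#' @return numeric vector of length `graph$n`.
#' @export
sample_icar_phi <- function(graph, tau) {
  if (!is.finite(tau)) return(numeric(graph$n))
  L <- icar_laplacian(graph)
  e <- eigen(L, symmetric = TRUE)
  tol <- max(e$values) * 1e-9
  keep <- e$values > tol
  z <- rnorm(sum(keep))
  drop(e$vectors[, keep, drop = FALSE] %*% (z / sqrt(tau * e$values[keep])))
}

icar_laplacian <- function(graph) {
  n <- graph$n
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- graph$nbr[[i]]
    L[i, js] <- -1
    L[i, i] <- length(js)
  }
  L
}

#' Moran's I spatial autocorrelation over an adjacency graph
#'
#' @param x numeric vector over graph nodes.
#' @param graph an `AdjacencyGraph` (binary weights).
#' @return Moran's I statistic.
#' @export
morans_i <- function(x, graph) {
  xc <- x - mean(x)
  num <- 0
  for (i in seq_len(graph$n)) {
    js <- graph$nbr[[i]]
    if (length(js)) num <- num + sum(xc[i] * xc[js])
  }
  W <- sum(graph$m)
  (graph$n / W) * num / sum(xc^2)
}

#' MCMC configuration for the spatial ICAR models
#'
#' The `"full"` schedule is the published one: 3 chains of 100,000
#' iterations, 50,000 burn-in, thinned 1-in-10, coefficient priors
#' N(0, 1000), improper uniform intercept, and Gamma(shape 0.001, rate
#' 0.001) on the ICAR precision (mean 1, variance 1,000 by moment match).
#' The `"desk"` schedule (3 x 5,000, 2,500 burn-in, thin 5) is for tests
#' and small simulations.
#'
#' @param family `"bernoulli-logit"` or `"poisson-log"`.
#' @param schedule `"full"` or `"desk"`, or override the fields directly.
#' @param chains,iterations,burn_in,thin MCMC schedule.
#' @param coef_prior_var prior variance of covariate coefficients.
#' @param tau_shape,tau_rate Gamma prior on the ICAR precision.
#' @param phi_enabled set FALSE to drop the spatial effect (plain Bayesian
#'   GLM; the `tau -> Inf` limit).
#' @param phi_store_thin store phi only every this many retained draws.
#' @param seed integer seed (applied via `set.seed` inside [fit_icar()]).
#' @return list of class `icar_config`.
#' @export
icar_config <- function(family = c("bernoulli-logit", "poisson-log"),
                        schedule = c("full", "desk"),
                        chains = 3, iterations = NULL, burn_in = NULL,
                        thin = NULL, coef_prior_var = 1000,
                        tau_shape = 0.001, tau_rate = 0.001,
                        phi_enabled = TRUE, phi_store_thin = 10,
                        seed = 1L) {
  family <- match.arg(family)
  schedule <- match.arg(schedule)
  def <- if (schedule == "full") c(100000L, 50000L, 10L) else c(5000L, 2500L, 5L)
  iterations <- if (is.null(iterations)) def[1] else as.integer(iterations)
  burn_in <- if (is.null(burn_in)) def[2] else as.integer(burn_in)
  thin <- if (is.null(thin)) def[3] else as.integer(thin)
  stopifnot(burn_in < iterations, thin >= 1)
  structure(list(family = family, chains = as.integer(chains),
                 iterations = iterations, burn_in = burn_in, thin = thin,
                 coef_prior_var = coef_prior_var, tau_shape = tau_shape,
                 tau_rate = tau_rate, phi_enabled = phi_enabled,
                 phi_store_thin = as.integer(phi_store_thin),
                 seed = as.integer(seed)),
            class = "icar_config")
}

#' Fit a Bayesian spatial GLM with an intrinsic CAR random effect
#'
#' Metropolis-within-Gibbs sampler: the ICAR precision tau by its conjugate
#' Gamma full conditional; each spatial effect phi_i by single-site
#' random-walk Metropolis against its ICAR full conditional (neighbor mean,
#' conditional variance `1/(tau m_i)`) times the likelihood; intercept and
#' coefficients by adaptive random-walk Metropolis. phi is recentered to
#' sum to zero per connected component after every sweep (the global shift
#' is absorbed into the improper-uniform intercept); isolated cells carry
#' phi = 0. Chains start overdispersed: coefficients jittered N(0, 1) and
#' tau cycled through 0.1, 1, 10.
#'
#' @param y response: 0/1 for `bernoulli-logit`, nonnegative counts for
#'   `poisson-log`.
#' @param X matrix/data.frame of standardized covariates, rows aligned with
#'   `graph` nodes.
#' @param graph `AdjacencyGraph` from [build_adjacency()].
#' @param config an [icar_config()].
#' @return an `ICARFit`: list with `draws` (per chain, matrix of retained
#'   draws for alpha, beta, tau), `phi_draws`, `summaries` (posterior
#'   median, 50% and 95% credible intervals per parameter), `rhat`,
#'   `converged` (all R-hat <= 1.1), `accept`, `family`, `config`.
#' @export
fit_icar <- function(y, X, graph, config = icar_config()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != graph$n || length(y) != graph$n) {
    stop("y and X must be aligned with the adjacency graph nodes")
  }
  fam <- config$family
  if (fam == "bernoulli-logit" && !all(y %in% c(0, 1))) {
    stop("bernoulli-logit family needs a 0/1 response")
  }
  if (fam == "poisson-log" && any(y < 0 | y != round(y))) {
    stop("poisson-log family needs nonnegative integer counts")
  }
  p <- ncol(X)
  # CSR adjacency, 0-based
  adj <- unlist(graph$nbr, use.names = FALSE)
  adj <- if (length(adj)) as.integer(adj - 1L) else integer(0)
  adj_ptr <- as.integer(c(0, cumsum(graph$m)))
  comp0 <- as.integer(graph$comp - 1L)

  set.seed(config$seed)
  tau_starts <- rep(c(0.1, 1, 10), length.out = config$chains)
  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    alpha0 <- rnorm(1)
    beta0 <- rnorm(p)
    phi0 <- numeric(graph$n)
    res <- icar_mcmc_chain(as.numeric(y), X, if (fam == "bernoulli-logit") 0L else 1L,
                           adj, adj_ptr, comp0,
                           config$iterations, config$burn_in, config$thin,
                           config$coef_prior_var, config$tau_shape, config$tau_rate,
                           alpha0, beta0, tau_starts[ch], phi0,
                           config$phi_enabled, config$phi_store_thin)
    colnames(res$samples) <- c("alpha", colnames(X) %||% paste0("beta", seq_len(p)), "tau")
    chains[[ch]] <- res
  }
  draws <- lapply(chains, `[[`, "samples")
  if (!config$phi_enabled) {
    # tau is never updated without a spatial effect; drop it
    draws <- lapply(draws, function(d) d[, setdiff(colnames(d), "tau"), drop = FALSE])
  }
  rh <- rhat(draws)
  all_draws <- do.call(rbind, draws)
  summaries <- summarize_draws(all_draws)
  fit <- structure(list(
    draws = draws,
    phi_draws = if (config$phi_enabled)
      lapply(chains, function(c) c$phi_samples[seq_len(c$n_phi_kept), , drop = FALSE])
      else NULL,
    summaries = summaries,
    rhat = rh,
    converged = all(rh <= 1.1, na.rm = TRUE),
    accept = lapply(chains, `[[`, "accept"),
    family = fam, config = config, n = graph$n),
    class = "icar_fit")
  if (!fit$converged) {
    warning("R-hat > 1.1 for: ", paste(names(rh)[rh > 1.1], collapse = ", "),
            " (non-convergence flag set)")
  }
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Potential scale reduction factor (R-hat)
#'
#' `sqrt((((n - 1)/n) W + B/n) / W)` with `n` the draws per chain, `W` the
#' mean within-chain variance and `B` the between-chain variance of chain
#' means multiplied by `n`.
#'
#' @param chains list (one element per chain) of equal-size draw matrices,
#'   or of numeric vectors for a single parameter.
#' @return named numeric vector of R-hat values.
#' @export
rhat <- function(chains) {
  if (length(chains) < 2) stop("R-hat needs at least 2 chains")
  if (is.null(dim(chains[[1]]))) chains <- lapply(chains, as.matrix)
  n <- nrow(chains[[1]])
  if (n < 10) stop("R-hat needs at least 10 retained draws per chain")
  p <- ncol(chains[[1]])
  out <- numeric(p)
  for (j in seq_len(p)) {
    mat <- vapply(chains, function(c) c[, j], numeric(n))
    W <- mean(apply(mat, 2, var))
    B <- n * var(colMeans(mat))
    out[j] <- if (W == 0) 1 else sqrt(((n - 1) / n * W + B / n) / W)
  }
  names(out) <- colnames(chains[[1]])
  out
}

# effective sample size by Geyer's initial positive sequence: sum
# autocorrelations in lag pairs while the pair sums stay positive
ess <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 400), plot = FALSE)$acf[-1]
  s <- 0
  k <- 1
  while (k + 1 <= length(ac)) {
    pair <- ac[k] + ac[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, n / (1 + 2 * s))
}

#' Monte Carlo standard error of posterior means
#'
#' @param fit an `ICARFit`.
#' @return named vector: posterior-mean MCSE per parameter, computed as
#'   `sd / sqrt(ESS)` with ESS from the pooled chains' autocorrelation.
#' @export
mcse <- function(fit) {
  all <- do.call(rbind, fit$draws)
  vapply(colnames(all), function(p) {
    per_chain <- vapply(fit$draws, function(d) ess(d[, p]), 0)
    sd(all[, p]) / sqrt(sum(per_chain))
  }, 0)
}

summarize_draws <- function(all_draws) {
  qs <- t(apply(all_draws, 2, quantile, probs = c(0.025, 0.25, 0.5, 0.75, 0.975)))
  data.frame(parameter = colnames(all_draws),
             median = qs[, 3], lo50 = qs[, 2], hi50 = qs[, 4],
             lo95 = qs[, 1], hi95 = qs[, 5],
             mean = colMeans(all_draws),
             row.names = NULL)
}

#' Coefficient table with credible intervals
#'
#' Per parameter: posterior median, 50% and 95% credible intervals, and a
#' credibly-nonzero flag (95% interval excludes 0) — the content of a
#' coefficient dot-and-whisker display.
#'
#' @param fit an `ICARFit`.
#' @return data.frame with `parameter`, `median`, `lo50`, `hi50`, `lo95`,
#'   `hi95`, `credibly_nonzero`.
#' @export
summarize_icar <- function(fit) {
  s <- fit$summaries
  s$credibly_nonzero <- s$lo95 > 0 | s$hi95 < 0
  s
}

#' @export
print.icar_fit <- function(x, ...) {
  cat(sprintf("ICAR %s fit: %d cells, %d chains x %d retained draws; %s\n",
              x$family, x$n, length(x$draws), nrow(x$draws[[1]]),
              if (x$converged) "converged (all R-hat <= 1.1)" else "NOT converged"))
  print(summarize_icar(x), digits = 3)
  invisible(x)
}
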