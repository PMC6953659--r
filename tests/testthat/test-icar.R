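test_that("lattice adjacency matches hand enumeration", {
  g13 <- toy_grid(1, 3)
  a <- build_adjacency(g13, type = "queen")
  expect_equal(a$m, c(1, 2, 1))
  g33 <- toy_grid(3, 3)
  aq <- build_adjacency(g33, type = "queen")
  center <- which(aq$ids == 4)  # row-major center of a 3x3 block
  expect_equal(aq$m[center], 8)
  ar <- build_adjacency(g33, type = "rook")
  expect_equal(ar$m[center], 4)
  expect_equal(sort(aq$m), c(3, 3, 3, 3, 5, 5, 5, 5, 8))
})

test_that("adjacency is symmetric on random subsets and tracks components", {
  g <- toy_grid(8, 8)
  set.seed(17)
  sub <- sample(g$cells$cell_id, 30)
  a <- build_adjacency(g, subset = sub)
  for (i in seq_len(a$n)) for (j in a$nbr[[i]]) {
    expect_true(i %in% a$nbr[[j]])
    expect_false(i == j)
  }
  # two far-apart blocks form two components
  b <- build_adjacency(g, subset = c(0, 1, 62, 63))
  expect_equal(b$n_comp, 2)
  expect_equal(b$n_isolated, 0)
  c1 <- build_adjacency(g, subset = c(0, 63))
  expect_equal(c1$n_isolated, 2)
})

test_that("ICAR log-density equals a dense generalized-inverse MVN evaluation", {
  # on small graphs: density differences must match the proper MVN on the
  # Laplacian's row space
  for (dims in list(c(2, 3), c(2, 2), c(1, 5))) {
    g <- toy_grid(dims[1], dims[2])
    gr <- build_adjacency(g)
    L <- surveygap:::icar_laplacian(gr)
    tau <- 1.7
    e <- eigen(L, symmetric = TRUE)
    keep <- e$values > 1e-9
    set.seed(18)
    phi1 <- sample_icar_phi(gr, tau)
    phi2 <- sample_icar_phi(gr, tau)
    dense <- function(phi) {
      z <- crossprod(e$vectors[, keep, drop = FALSE], phi)
      sum(-0.5 * tau * e$values[keep] * z^2) +
        0.5 * sum(log(tau * e$values[keep])) - sum(keep) / 2 * log(2 * pi)
    }
    d_mod <- icar_logdensity(phi1, gr, tau) - icar_logdensity(phi2, gr, tau)
    d_dense <- dense(phi1) - dense(phi2)
    expect_equal(d_mod, d_dense, tolerance = 1e-8)
  }
})

test_that("the tau full conditional is the moment-matched conjugate Gamma", {
  # 4-node cycle: rook adjacency on a 2x2 block
  g <- toy_grid(2, 2)
  gr <- build_adjacency(g, type = "rook")
  expect_true(all(gr$m == 2))
  set.seed(19)
  phi <- sample_icar_phi(gr, 2)
  ssq <- 0
  for (i in 1:4) for (j in gr$nbr[[i]]) if (j > i) ssq <- ssq + (phi[i] - phi[j])^2
  a0 <- 0.001; b0 <- 0.001
  # brute force: normalize exp(joint log density) over a tau grid and compare
  # with the claimed Gamma(a0 + (n-C)/2, b0 + ssq/2) density
  taus <- seq(0.01, 30, length.out = 4000)
  joint <- vapply(taus, function(t)
    icar_logdensity(phi, gr, t) + dgamma(t, a0, b0, log = TRUE), 0)
  w <- exp(joint - max(joint))
  dens_grid <- w / sum(w * diff(taus)[1])
  dens_gamma <- dgamma(taus, a0 + (4 - 1) / 2, b0 + ssq / 2)
  expect_lt(max(abs(dens_grid - dens_gamma)), 5e-3)  # grid-spacing limited
})

test_that("exact ICAR draws have the advertised moments and constraints", {
  g <- toy_grid(6, 6)
  gr <- build_adjacency(g)
  set.seed(20)
  draws <- t(replicate(600, sample_icar_phi(gr, 3)))
  expect_true(all(abs(rowSums(draws)) < 1e-8))
  # covariance of draws ~ generalized inverse of tau*L
  L <- surveygap:::icar_laplacian(gr)
  e <- eigen(L, symmetric = TRUE)
  keep <- e$values > 1e-9
  Sigma <- e$vectors[, keep] %*% diag(1 / (3 * e$values[keep])) %*% t(e$vectors[, keep])
  emp <- cov(draws)
  expect_lt(max(abs(emp - Sigma)), 0.08)
  expect_equal(sample_icar_phi(gr, Inf), rep(0, 36))
})

test_that("R-hat follows the closed-form formula in its edge cases", {
  set.seed(22)
  x <- rnorm(1000)
  # identical chains: R-hat equals 1 (to the (n-1)/n factor)
  expect_equal(unname(rhat(list(x, x, x))), 1, tolerance = 1e-3)
  # chains from the same distribution, large n
  big <- lapply(1:3, function(i) rnorm(10000))
  expect_lt(unname(rhat(big)), 1.01)
  # separated chains: closed-form evaluation
  c1 <- rnorm(1000, 0, 1); c2 <- rnorm(1000, 10, 1)
  got <- unname(rhat(list(c1, c2)))
  n <- 1000
  W <- (var(c1) + var(c2)) / 2
  B <- n * var(c(mean(c1), mean(c2)))
  expect_equal(got, sqrt(((n - 1) / n * W + B / n) / W), tolerance = 1e-12)
  expect_gt(got, 3)
  expect_error(rhat(list(c1)), "2 chains")
})

test_that("posterior summaries match brute-force percentiles", {
  set.seed(23)
  draws <- cbind(a = rnorm(500), b = rexp(500))
  s <- surveygap:::summarize_draws(draws)
  expect_equal(s$median, unname(apply(draws, 2, quantile, 0.5)))
  expect_equal(s$lo95, unname(apply(draws, 2, quantile, 0.025)))
  expect_equal(s$hi50, unname(apply(draws, 2, quantile, 0.75)))
  # nesting of intervals
  expect_true(all(s$lo95 <= s$lo50 & s$hi50 <= s$hi95))
  # degenerate draws: point mass
  dg <- surveygap:::summarize_draws(cbind(k = rep(2, 100)))
  expect_equal(dg$median, 2)
  expect_equal(dg$lo95, 2)
  expect_equal(dg$hi95, 2)
  # credibly-nonzero logic via summarize_icar
  fake <- structure(list(summaries = surveygap:::summarize_draws(
    cbind(pos = rep(2, 50), sym = seq(-1, 1, length.out = 50)))), class = "icar_fit")
  si <- summarize_icar(fake)
  expect_true(si$credibly_nonzero[si$parameter == "pos"])
  expect_false(si$credibly_nonzero[si$parameter == "sym"])
})

test_that("a zero covariate column returns its prior", {
  sc <- default_landscape(rows = 10, cols = 10, seed = 24)
  gr <- sc$land$graph
  X <- cbind(real = scale(sc$land$covariates$richness)[, 1],
             null = rep(0, gr$n))
  set.seed(25)
  y <- rbinom(gr$n, 1, plogis(0.2 * X[, 1]))
  # heavy thinning: the KS comparison needs near-independent draws
  fit <- fit_icar(y, X, gr, icar_config(family = "bernoulli-logit",
                                        iterations = 60000, burn_in = 10000,
                                        thin = 50, phi_enabled = FALSE,
                                        seed = 2))
  nulldraws <- do.call(rbind, fit$draws)[, "null"]
  ks <- suppressWarnings(ks.test(nulldraws, function(q) pnorm(q, 0, sqrt(1000))))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("with the spatial effect disabled the fit matches ML logistic", {
  sc <- default_landscape(rows = 20, cols = 10, seed = 5)
  X <- scale(as.matrix(sc$land$covariates))[, 1:3]
  set.seed(1)
  y <- rbinom(nrow(X), 1, plogis(-0.2 + X %*% c(0.2, -0.15, 0.1)))
  gr <- build_adjacency(sc$land$grid)
  fit <- fit_icar(y, X, gr, icar_config(family = "bernoulli-logit",
                                        schedule = "desk", phi_enabled = FALSE,
                                        seed = 1))
  ml <- unname(coef(glm(y ~ X, family = binomial)))
  pm <- fit$summaries$mean[match(c("alpha", colnames(X)), fit$summaries$parameter)]
  z <- abs(pm - ml) / mcse(fit)[c("alpha", colnames(X))]
  expect_lt(max(z), 2)
  expect_true(fit$converged)
})

test_that("the Poisson-log family recovers strong count signals", {
  sc <- default_landscape(rows = 12, cols = 12, seed = 26)
  X <- scale(as.matrix(sc$land$covariates))[, 1:2]
  gr <- sc$land$graph
  set.seed(27)
  y <- rpois(gr$n, exp(2 + X %*% c(0.5, -0.3)))
  fit <- suppressWarnings(
    fit_icar(y, X, gr, icar_config(family = "poisson-log", schedule = "desk",
                                   seed = 3)))
  s <- fit$summaries
  expect_lt(abs(s$median[s$parameter == "richness"] - 0.5), 0.1)
  expect_lt(abs(s$median[s$parameter == "elev_het"] + 0.3), 0.1)
  expect_error(fit_icar(y + 0.5, X, gr, icar_config(family = "poisson-log")),
               "integer")
})

test_that("fits are reproducible and draw counts follow the schedule", {
  sc <- default_landscape(rows = 8, cols = 8, seed = 28)
  X <- scale(as.matrix(sc$land$covariates))[, 1, drop = FALSE]
  gr <- sc$land$graph
  set.seed(29)
  y <- rbinom(gr$n, 1, 0.4)
  cfg <- icar_config(family = "bernoulli-logit", chains = 2, iterations = 2000,
                     burn_in = 1000, thin = 4, seed = 7)
  f1 <- suppressWarnings(fit_icar(y, X, gr, cfg))
  f2 <- suppressWarnings(fit_icar(y, X, gr, cfg))
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws[[1]]), (2000 - 1000) / 4)
  expect_length(f1$draws, 2)
  # per-component sum-to-zero of stored phi draws
  phis <- f1$phi_draws[[1]]
  expect_true(all(abs(rowSums(phis)) < 1e-8))
})
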