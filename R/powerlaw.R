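# Power-law model of taxonomic sampling bias: sampled cells y vs. range
# size x as y = a x^b, fitted per foraging guild as a linear model on
# log-log axes with a guild-by-range interaction.

#' Fit the power-law model of sampled cells vs. range size
#'
#' Response: ln(sampled_cells). Predictors: ln(range_cells) centered at its
#' mean, foraging guild (edge-space foragers the reference category), and
#' their interaction. Ordinary least squares with sequential (type-I)
#' F-tests in the order range size, guild, interaction. Species with zero
#' sampled cells are excluded (log undefined) and their count logged as an
#' attribute. Natural logs: the slope — the power-law exponent b — is
#' invariant to the log base.
#'
#' @param species data.frame with `species`, `guild`
#'   (open/edge/narrow), `range_cells`, `sampled_cells` (positive values
#'   enter the fit; need not be integer).
#' @return a `powerlaw_fit`: list with `model` (the `lm`), `anova`
#'   (sequential F table), `center` (mean of ln range size), `n_used`,
#'   `n_excluded`, `data`.
#' @export
fit_powerlaw <- function(species) {
  stopifnot(all(c("guild", "range_cells", "sampled_cells") %in% names(species)))
  d <- as.data.frame(species)
  excl <- d$sampled_cells <= 0
  d <- d[!excl, , drop = FALSE]
  d$guild <- factor(d$guild, levels = c("edge", "narrow", "open"))
  missing_guild <- setdiff(levels(d$guild), unique(as.character(d$guild)))
  if (length(missing_guild)) {
    stop("no species with sampled cells in guild: ",
         paste(missing_guild, collapse = ", "))
  }
  if (any(table(d$guild) < 3)) {
    stop("need at least 3 sampled species per guild")
  }
  d$logy <- log(d$sampled_cells)
  ctr <- mean(log(d$range_cells))
  d$logx <- log(d$range_cells) - ctr
  fit <- lm(logy ~ logx + guild + logx:guild, data = d)
  an <- anova(fit)  # sequential type-I SS in model order
  structure(list(model = fit, anova = an, center = ctr,
                 n_used = nrow(d), n_excluded = sum(excl), data = d),
            class = "powerlaw_fit")
}

#' Tukey HSD contrasts between foraging guilds
#'
#' Pairwise differences of guild adjusted means at the centered mean of log
#' range size (where, under centering, they equal intercept differences),
#' with family-wise adjusted p-values. The default `"single-step"` method
#' is the multivariate-t general-linear-hypothesis procedure of
#' `multcomp::glht`; `"classic"` gives the equal-variance studentized-range
#' HSD from `TukeyHSD` on the guild factor for comparison.
#'
#' @param fit a `powerlaw_fit`.
#' @param method `"single-step"` or `"classic"`.
#' @return data.frame with `contrast` (e.g. `"N-E"` = narrow minus edge),
#'   `estimate`, `se`, `t`, `p_adj`.
#' @export
tukey_guild_contrasts <- function(fit, method = c("single-step", "classic")) {
  method <- match.arg(method)
  if (method == "classic") {
    av <- aov(logy ~ guild + logx + logx:guild, data = fit$data)
    # TukeyHSD warns about the covariate terms it ignores; that is the point
    tk <- suppressWarnings(stats::TukeyHSD(av, which = "guild"))$guild
    lab <- rownames(tk)
    lab <- vapply(strsplit(lab, "-"), function(p)
      paste(toupper(substr(p, 1, 1)), collapse = "-"), "")
    return(data.frame(contrast = lab, estimate = tk[, "diff"], se = NA,
                      t = NA, p_adj = tk[, "p adj"], row.names = NULL))
  }
  K <- rbind("N-E" = c(0, 0, 1, 0, 0, 0),
             "O-N" = c(0, 0, -1, 1, 0, 0),
             "O-E" = c(0, 0, 0, 1, 0, 0))
  gl <- multcomp::glht(fit$model, linfct = K)
  s <- summary(gl, test = multcomp::adjusted("single-step"))
  data.frame(contrast = rownames(K),
             estimate = unname(s$test$coefficients),
             se = unname(s$test$sigma),
             t = unname(s$test$tstat),
             p_adj = unname(as.numeric(s$test$pvalues)),
             row.names = NULL)
}

#' Per-guild power-law exponents with confidence intervals
#'
#' Each guild's slope is the base slope plus its interaction term; its
#' standard error comes from the linear-combination variance formula, and
#' the 95% interval from the t distribution on the residual df. Guilds are
#' classified by where the interval sits relative to 1: an exponent above 1
#' means wide-ranging species have proportionally better-sampled ranges;
#' below 1, narrow-ranging species do.
#'
#' @param fit a `powerlaw_fit`.
#' @param level confidence level (default 0.95).
#' @return data.frame with `guild`, `b`, `se`, `lo`, `hi`,
#'   `classification` in `"below 1"`, `"not distinguishable from 1"`,
#'   `"above 1"`.
#' @export
guild_slopes <- function(fit, level = 0.95) {
  m <- fit$model
  V <- vcov(m)
  cf <- coef(m)
  combos <- list(edge = c("logx"), narrow = c("logx", "logx:guildnarrow"),
                 open = c("logx", "logx:guildopen"))
  dfres <- m$df.residual
  tq <- qt(1 - (1 - level) / 2, dfres)
  out <- lapply(names(combos), function(g) {
    k <- setNames(numeric(length(cf)), names(cf))
    k[combos[[g]]] <- 1
    b <- sum(k * cf)
    se <- sqrt(drop(t(k) %*% V %*% k))
    c(b = b, se = se, lo = b - tq * se, hi = b + tq * se)
  })
  out <- as.data.frame(do.call(rbind, out))
  out <- cbind(guild = names(combos), out)
  out$classification <- ifelse(out$hi < 1, "below 1",
                        ifelse(out$lo > 1, "above 1",
                               "not distinguishable from 1"))
  rownames(out) <- NULL
  out
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: %d species (%d excluded, zero sampled cells)\n",
              x$n_used, x$n_excluded))
  print(x$anova, signif.stars = FALSE)
  print(guild_slopes(x), digits = 3)
  invisible(x)
}
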