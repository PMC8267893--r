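#' Configuration of the probabilistic sensitivity analysis
#'
#' @param n_draws Number of Monte Carlo draws; default 10000.
#' @param seed Integer seed for the run's single RNG stream; default
#'   20210625.
#' @param probability_scale Sampling scale for the improvement
#'   probability: `"log_or"` (default) draws the log odds ratio from a
#'   normal distribution matched to the plausible range and maps it back
#'   through [or_to_probability()], so sampled probabilities always lie in
#'   (0, 1) and honour the range's asymmetry on the probability scale;
#'   `"truncated_normal_p"` draws the probability itself from a normal
#'   distribution truncated to (0, 1), for robustness comparison.
#' @param share_draws_across_baselines If `TRUE` (default) one draw matrix
#'   of effect sizes is reused for every baseline column (the baseline only
#'   shifts the utility argument); if `FALSE`, fresh draws are taken per
#'   baseline.
#' @return An object of class `psa_config`.
#' @export
psa_config <- function(n_draws = 10000, seed = 20210625,
                       probability_scale = c("log_or", "truncated_normal_p"),
                       share_draws_across_baselines = TRUE) {
  if (!is.numeric(n_draws) || length(n_draws) != 1L || n_draws < 1 ||
      n_draws != round(n_draws))
    stop("`n_draws` must be a positive integer", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  probability_scale <- match.arg(probability_scale)
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 probability_scale = probability_scale,
                 share_draws_across_baselines =
                   isTRUE(share_draws_across_baselines)),
            class = "psa_config")
}

#' Sample effect sizes from their uncertainty distributions
#'
#' Draws, per treatment, `n_draws` pairs of (improvement probability, QTc
#' shift). QTc shifts are normal on the natural scale with mean the point
#' estimate and `sd = (hi - lo) / (2 * 1.959964)`. Probabilities are drawn
#' on the scale named by the config (see [psa_config()]). Draws are
#' independent across treatments and between the two quantities. A
#' degenerate plausible range (`lo == point == hi`) yields constant draws.
#'
#' @param table An [effect_table()].
#' @param config A [psa_config()]; its seed is set before sampling, so
#'   identical inputs reproduce identical draws.
#' @return List with matrices `p` and `dqtc`, each `n_draws` rows by
#'   `nrow(table)` columns (columns named by treatment).
#' @export
sample_effects <- function(table, config = psa_config()) {
  stopifnot(inherits(table, "effect_table"), inherits(config, "psa_config"))
  set.seed(config$seed)
  draw_effects(table, config, config$n_draws)
}

# draws from the current RNG state (no seeding) — run_psa seeds once
draw_effects <- function(table, config, n) {
  pars <- logit_scale_params(table)
  k <- nrow(table)
  p <- matrix(NA_real_, n, k, dimnames = list(NULL, table$name))
  dqtc <- p
  for (i in seq_len(k)) {
    if (config$probability_scale == "log_or") {
      z <- stats::rnorm(n, pars$log_or_mean[i], pars$log_or_sd[i])
      p[, i] <- or_to_probability(exp(z), attr(table, "p0"))
    } else {
      p[, i] <- rtrunc_norm01(n, table$p[i],
                              (table$p_hi[i] - table$p_lo[i]) / (2 * Z95))
    }
    dqtc[, i] <- stats::rnorm(n, pars$dqtc_mean[i], pars$dqtc_sd[i])
  }
  list(p = p, dqtc = dqtc)
}

# normal truncated to the open unit interval via inverse-CDF; sd = 0
# degenerates to the mean
rtrunc_norm01 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Run the Monte Carlo probabilistic sensitivity analysis
#'
#' Per draw, each treatment's expected utility is evaluated at the drawn
#' (probability, QTc shift); the placebo utility is the deterministic fixed
#' value. Summaries per treatment and baseline: mean and SD of utility,
#' Monte Carlo standard error, the percentage of draws in which the option
#' attains the highest utility among all options including placebo (ties
#' go to the first option in table order), and the percentage of draws in
#' which the treatment's utility strictly exceeds placebo's.
#'
#' @param table An [effect_table()]; default the packaged six-drug table.
#' @param baselines Baseline QTc grid in ms; default
#'   `c(420, 450, 480, 510)`.
#' @param pair A [utility_pair()].
#' @param config A [psa_config()].
#' @return An object of class `qtc_psa`: list with `summary` (one row per
#'   option and baseline: `name`, `baseline`, `mean`, `sd`, `mc_se`,
#'   `p_highest`, `p_beats_placebo` — percentages on 0-100), `placebo`
#'   (named vector of fixed placebo utilities), `config`, `baselines`.
#' @examples
#' psa <- run_psa(config = psa_config(n_draws = 500, seed = 1))
#' subset(psa$summary, baseline == 510)
#' @export
run_psa <- function(table = delirium_effect_table(),
                    baselines = c(420, 450, 480, 510),
                    pair = utility_pair(),
                    config = psa_config()) {
  stopifnot(inherits(table, "effect_table"), inherits(pair, "utility_pair"),
            inherits(config, "psa_config"))
  check_baselines(baselines)
  n <- config$n_draws
  k <- nrow(table)
  placebo <- expected_utility(attr(table, "p0"), baselines, pair)
  names(placebo) <- baselines

  set.seed(config$seed)
  draws <- draw_effects(table, config, n)
  rows <- vector("list", length(baselines))
  for (j in seq_along(baselines)) {
    if (!config$share_draws_across_baselines && j > 1L)
      draws <- draw_effects(table, config, n)
    u <- draws$p * utility_value(baselines[j] + draws$dqtc, pair, "improved") +
      (1 - draws$p) * utility_value(baselines[j] + draws$dqtc, pair,
                                    "unimproved")
    all_u <- cbind(Placebo = rep(placebo[j], n), u)
    top <- max.col(all_u, ties.method = "first")
    p_highest <- tabulate(top, nbins = k + 1L) / n * 100
    mu <- c(placebo[j], colMeans(u))
    sdev <- c(0, apply(u, 2, stats::sd))
    beats <- c(NA_real_, colMeans(u > placebo[j]) * 100)
    rows[[j]] <- data.frame(
      name = c("Placebo", table$name), baseline = baselines[j],
      mean = mu, sd = sdev, mc_se = sdev / sqrt(n),
      p_highest = p_highest, p_beats_placebo = beats,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(list(summary = res, placebo = placebo, config = config,
                 baselines = baselines, table = table, pair = pair),
            class = "qtc_psa")
}

#' @export
print.qtc_psa <- function(x, digits = 2, ...) {
  cat(sprintf(
    "Probabilistic sensitivity analysis: %d draws, seed %d, %s scale\n",
    x$config$n_draws, x$config$seed, x$config$probability_scale))
  s <- x$summary
  s$mean <- round(s$mean, digits)
  s$sd <- round(s$sd, digits)
  s$mc_se <- signif(s$mc_se, 2)
  s$p_highest <- round(s$p_highest)
  s$p_beats_placebo <- round(s$p_beats_placebo)
  print(s, row.names = FALSE)
  invisible(x)
}

#' @export
summary.qtc_psa <- function(object, ...) {
  s <- object$summary
  top <- vapply(object$baselines, function(b) {
    sb <- s[s$baseline == b, ]
    sb$name[which.max(sb$p_highest)]
  }, character(1))
  names(top) <- object$baselines
  structure(list(psa = object, top_share = top),
            class = "summary.qtc_psa")
}

#' @export
print.summary.qtc_psa <- function(x, ...) {
  print(x$psa)
  cat("  Most-often-highest option per baseline:\n")
  for (b in names(x$top_share))
    cat(sprintf("    %s ms: %s\n", b, x$top_share[[b]]))
  invisible(x)
}

#' Quadrature cross-check of the Monte Carlo mean utility
#'
#' Integrates the decision tree's expected utility over the joint normal
#' density of (log odds ratio, QTc shift) with Gauss-Hermite quadrature,
#' giving an independent deterministic value of the quantity the Monte
#' Carlo PSA estimates by simulation. Only the `"log_or"` sampling scale is
#' supported. Degenerate (zero-sd) dimensions collapse to their point
#' value.
#'
#' @param record One effect-table row.
#' @param baseline Baseline QTc in ms (length 1).
#' @param pair A [utility_pair()].
#' @param p0 Placebo probability used in the odds-ratio mapping; default
#'   0.5.
#' @param nodes Gauss-Hermite nodes per dimension; default 40.
#' @return The exact mean utility under the sampling distribution.
#' @export
quadrature_oracle <- function(record, baseline, pair = utility_pair(),
                              p0 = 0.5, nodes = 40) {
  stopifnot(length(baseline) == 1L)
  lor_mean <- log(probability_to_or(record$p, p0))
  lor_sd <- (qlogis_or(record$p_hi) - qlogis_or(record$p_lo)) / (2 * Z95)
  d_mean <- record$dqtc
  d_sd <- (record$dqtc_hi - record$dqtc_lo) / (2 * Z95)

  gh <- pracma::gaussHermite(nodes)
  # E[f(X)] for X ~ N(m, s): sum w_i f(m + sqrt(2) s x_i) / sqrt(pi)
  gh_nodes <- function(m, s) {
    if (s == 0) list(x = m, w = 1)
    else list(x = m + sqrt(2) * s * gh$x, w = gh$w / sqrt(pi))
  }
  zl <- gh_nodes(lor_mean, lor_sd)
  zd <- gh_nodes(d_mean, d_sd)
  p_nodes <- or_to_probability(exp(zl$x), p0)
  eu <- outer(p_nodes, zd$x, function(p, d)
    expected_utility(p, baseline + d, pair))
  as.numeric(zl$w %*% eu %*% zd$w)
}
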