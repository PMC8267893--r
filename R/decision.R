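#' Expected utility of a treatment branch
#'
#' The decision tree's chance node: with probability `p` delirium improves
#' and the improved-status utility curve applies; otherwise the
#' unimproved-status curve applies. Both are evaluated at the on-treatment
#' QTc interval.
#'
#' @param p Improvement probability in \[0, 1\] (vectorized).
#' @param qtc On-treatment QTc interval in ms (vectorized).
#' @param pair A [utility_pair()]; default the baseline sigmoid setting.
#' @return `p * U_improved(qtc) + (1 - p) * U_unimproved(qtc)`.
#' @examples
#' expected_utility(0.5, 420)  # placebo at baseline 420 ms: 64.10
#' @export
expected_utility <- function(p, qtc, pair = utility_pair()) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("`p` must lie in [0, 1]", call. = FALSE)
  stopifnot(inherits(pair, "utility_pair"))
  p * utility_value(qtc, pair, "improved") +
    (1 - p) * utility_value(qtc, pair, "unimproved")
}

#' Expected utility of one treatment at a baseline QTc
#'
#' The on-treatment QTc interval is the baseline value plus the drug's mean
#' QTc shift; the improvement probability is the drug's transition
#' probability.
#'
#' @param record One effect-table row (a list or one-row data frame with
#'   fields `p` and `dqtc`).
#' @param baseline Baseline QTc interval(s) in ms.
#' @param pair A [utility_pair()].
#' @return Expected utility at each baseline.
#' @export
evaluate_treatment <- function(record, baseline, pair = utility_pair()) {
  if (is.null(record$p) || is.null(record$dqtc))
    stop("`record` must carry fields `p` and `dqtc`", call. = FALSE)
  expected_utility(record$p, baseline + record$dqtc, pair)
}

check_baselines <- function(baselines) {
  if (!is.numeric(baselines) || length(baselines) < 1L ||
      any(!is.finite(baselines)))
    stop("`baselines` must be finite QTc values in ms", call. = FALSE)
  if (is.unsorted(baselines, strictly = TRUE))
    stop("`baselines` must be strictly increasing", call. = FALSE)
  if (any(baselines < 300 | baselines > 700))
    warning("baseline QTc outside the physiologic range 300-700 ms")
  baselines
}

#' Fit the antipsychotic decision model
#'
#' Evaluates the two-branch decision tree for every treatment in an effect
#' table across a grid of baseline QTc intervals, including a placebo
#' option (improvement probability `p0`, zero QTc shift). This is the main
#' entry point; the returned object has `print`, `summary`, `coef`,
#' `predict`, `plot` and `simulate` methods.
#'
#' @param table An [effect_table()]; default the packaged six-drug table.
#' @param baselines Strictly increasing baseline QTc grid in ms; default
#'   `c(420, 450, 480, 510)`. Values outside 300-700 ms draw a warning.
#' @param utilities A [utility_pair()]; default the baseline sigmoid
#'   setting.
#' @return An object of class `qtc_decision` with components
#'   `utilities_matrix` (rows: placebo first, then treatments in table
#'   order; columns: baselines), `table`, `baselines`, `pair`.
#' @examples
#' fit <- decision_analysis(delirium_effect_table())
#' fit
#' summary(fit)
#' @export
decision_analysis <- function(table = delirium_effect_table(),
                              baselines = c(420, 450, 480, 510),
                              utilities = utility_pair()) {
  stopifnot(inherits(table, "effect_table"),
            inherits(utilities, "utility_pair"))
  check_baselines(baselines)
  p0 <- attr(table, "p0")

  m <- matrix(NA_real_, nrow = nrow(table) + 1L, ncol = length(baselines),
              dimnames = list(c("Placebo", table$name), baselines))
  m["Placebo", ] <- expected_utility(p0, baselines, utilities)
  for (i in seq_len(nrow(table)))
    m[i + 1L, ] <- evaluate_treatment(table[i, ], baselines, utilities)

  structure(list(utilities_matrix = m, table = table,
                 baselines = baselines, pair = utilities,
                 call = match.call()),
            class = "qtc_decision")
}

#' Rank treatment options at one baseline QTc
#'
#' Options (placebo included) are sorted by decreasing expected utility.
#' Utility differences smaller than `tol` are treated as ties — the input
#' effect sizes carry about three significant digits, so differences far
#' below the two-decimal reporting precision are not meaningful — and ties
#' are broken by table order (placebo first, then file order).
#'
#' @param fit A `qtc_decision` object from [decision_analysis()].
#' @param baseline One baseline QTc value present in the fit's grid.
#' @param tol Tie tolerance in utility units; default 0.005 (half the
#'   two-decimal reporting precision). Set 0 for exact comparison.
#' @return Data frame with columns `name` and `utility`, best first.
#' @examples
#' fit <- decision_analysis()
#' rank_treatments(fit, 510)
#' @export
rank_treatments <- function(fit, baseline, tol = 0.005) {
  stopifnot(inherits(fit, "qtc_decision"))
  j <- match(baseline, fit$baselines)
  if (is.na(j))
    stop("`baseline` is not in the fitted grid: ",
         paste(fit$baselines, collapse = ", "), call. = FALSE)
  u <- fit$utilities_matrix[, j]
  ord <- order_with_ties(u, tol)
  data.frame(name = names(u)[ord], utility = unname(u[ord]),
             stringsAsFactors = FALSE)
}

# descending order; values within `tol` of a tie-group's leader keep their
# original (table) order
order_with_ties <- function(u, tol) {
  ord <- order(-u, seq_along(u))
  if (tol <= 0 || length(ord) < 2L) return(ord)
  out <- integer(0)
  remaining <- ord
  while (length(remaining)) {
    leader <- remaining[1]
    group <- remaining[u[remaining] >= u[leader] - tol]
    out <- c(out, sort(group))
    remaining <- setdiff(remaining, group)
  }
  out
}

#' @export
print.qtc_decision <- function(x, digits = 2, ...) {
  cat("QTc decision analysis\n")
  cat(sprintf("  %d treatment(s) + placebo (p0 = %g), %s utilities\n",
              nrow(x$table), attr(x$table, "p0"), x$pair$family))
  cat("  Expected utility by baseline QTc (ms):\n")
  print(round(x$utilities_matrix, digits))
  invisible(x)
}

#' @export
summary.qtc_decision <- function(object, tol = 0.005, ...) {
  rankings <- lapply(object$baselines, function(b)
    rank_treatments(object, b, tol = tol))
  names(rankings) <- object$baselines
  best <- vapply(rankings, function(r) r$name[1], character(1))
  structure(list(fit = object, rankings = rankings, best = best, tol = tol),
            class = "summary.qtc_decision")
}

#' @export
print.summary.qtc_decision <- function(x, ...) {
  print(x$fit)
  cat("  Highest-utility option per baseline:\n")
  for (b in names(x$best))
    cat(sprintf("    %s ms: %s\n", b, x$best[[b]]))
  invisible(x)
}

#' @export
coef.qtc_decision <- function(object, ...) {
  tab <- object$table
  out <- cbind(p = c(attr(tab, "p0"), tab$p), dqtc = c(0, tab$dqtc))
  rownames(out) <- c("Placebo", tab$name)
  out
}

#' @describeIn decision_analysis expected utilities at new baseline QTc
#'   values (need not be part of the fitted grid).
#' @param object,... Method arguments.
#' @export
predict.qtc_decision <- function(object, baselines = object$baselines, ...) {
  decision_analysis(object$table, baselines = baselines,
                    utilities = object$pair)$utilities_matrix
}

#' @export
plot.qtc_decision <- function(x, from = min(x$baselines) - 20,
                              to = max(x$baselines) + 20, by = 5, ...) {
  grid <- seq(from, to, by = by)
  m <- predict(x, baselines = grid)
  graphics::matplot(grid, t(m), type = "l", lty = 1,
                    col = seq_len(nrow(m)),
                    xlab = "Baseline QTc (ms)", ylab = "Expected utility",
                    ...)
  graphics::legend("bottomleft", legend = rownames(m), lty = 1,
                   col = seq_len(nrow(m)), bty = "n", cex = 0.8)
  invisible(m)
}

#' @export
simulate.qtc_decision <- function(object, nsim = 10000, seed = 20210625,
                                  ...) {
  run_psa(object$table, baselines = object$baselines, pair = object$pair,
          config = psa_config(n_draws = nsim, seed = seed, ...))
}
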