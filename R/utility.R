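#' Parameters of a QTc-dependent utility curve
#'
#' A utility curve maps a QTc interval (ms) to a utility in
#' `[u_min, u_max]`. The baseline family is a decreasing sigmoid
#' `u_min + (u_max - u_min) / (1 + exp(slope * (qtc - qtc_ref)))` whose
#' inflection sits at `qtc_ref` (default 500 ms, where torsade-de-pointes
#' risk rises sharply): the curve is concave (risk-averse) below the
#' reference and convex (risk-seeking) above it.
#'
#' @param u_min Utility approached as QTc grows without bound, in [0, 100].
#' @param u_max Utility approached as QTc falls without bound, in [0, 100];
#'   must exceed `u_min`.
#' @param slope Sigmoid steepness in 1/ms; must be positive. Default 0.05.
#' @param qtc_ref Inflection point in ms. Default 500.
#' @return An object of class `utility_params`.
#' @export
utility_params <- function(u_min, u_max, slope = 0.05, qtc_ref = 500) {
  stopifnot(is.numeric(u_min), is.numeric(u_max), length(u_min) == 1L,
            length(u_max) == 1L, is.finite(u_min), is.finite(u_max))
  if (u_min < 0 || u_max > 100)
    stop("utilities must lie in [0, 100]", call. = FALSE)
  if (u_min >= u_max)
    stop("`u_min` must be strictly below `u_max`", call. = FALSE)
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) ||
      slope <= 0)
    stop("`slope` must be a positive number", call. = FALSE)
  structure(list(u_min = u_min, u_max = u_max, slope = slope,
                 qtc_ref = qtc_ref),
            class = "utility_params")
}

UTILITY_FAMILIES <- c("sigmoid", "linear", "exp_convex", "exp_concave")

#' Paired utility curves for improved and unimproved delirium
#'
#' The decision tree values each leaf with one of two QTc-dependent curves:
#' one for patients whose delirium improved and one for those whose did
#' not. Defaults fix the improved curve's maximum at 100 and minimum at 30,
#' and the unimproved curve's maximum at 30 and minimum at 0, both sigmoids
#' with slope 0.05 and inflection at 500 ms. The improved curve must
#' dominate the unimproved curve pointwise.
#'
#' @param improved [utility_params()] of the improved-status curve.
#' @param unimproved [utility_params()] of the unimproved-status curve.
#' @param family Curve family, one of `"sigmoid"` (default), `"linear"`,
#'   `"exp_convex"`, `"exp_concave"`. Non-sigmoid families are
#'   endpoint-anchored on `domain`.
#' @param domain Length-2 QTc interval (ms) on which non-sigmoid families
#'   are anchored (`u_max` at the left end, `u_min` at the right end);
#'   default `c(380, 620)`. Values outside are clamped.
#' @param curvature Magnitude of the exponent constant for the exponential
#'   families; default 3.
#' @return An object of class `utility_pair`.
#' @examples
#' utility_pair()  # the default sigmoid setting
#' @export
utility_pair <- function(improved = utility_params(30, 100),
                         unimproved = utility_params(0, 30),
                         family = "sigmoid",
                         domain = c(380, 620),
                         curvature = 3) {
  stopifnot(inherits(improved, "utility_params"),
            inherits(unimproved, "utility_params"))
  family <- match_family(family)
  if (!is.numeric(domain) || length(domain) != 2L || domain[1] >= domain[2])
    stop("`domain` must be an increasing length-2 QTc interval", call. = FALSE)
  pair <- structure(list(improved = improved, unimproved = unimproved,
                         family = family, domain = domain,
                         curvature = curvature),
                    class = "utility_pair")
  grid <- seq(domain[1] - 50, domain[2] + 50, by = 1)
  if (!all(utility_value(grid, pair, "improved") >
           utility_value(grid, pair, "unimproved")))
    stop("improved curve must dominate the unimproved curve at every QTc",
         call. = FALSE)
  pair
}

match_family <- function(family) {
  if (!is.character(family) || length(family) != 1L ||
      !(family %in% UTILITY_FAMILIES))
    stop("unknown utility family; use one of: ",
         paste(UTILITY_FAMILIES, collapse = ", "), call. = FALSE)
  family
}

#' Sigmoid utility of a QTc interval
#'
#' @param qtc QTc interval(s) in ms; `-Inf`/`Inf` map to the limits
#'   `u_max`/`u_min`.
#' @param params A [utility_params()] object.
#' @return Utility value(s) in `(u_min, u_max)` for finite input.
#' @examples
#' sigmoid_utility(480, utility_params(30, 100))  # ~81.17
#' @export
sigmoid_utility <- function(qtc, params) {
  stopifnot(inherits(params, "utility_params"))
  params$u_min + (params$u_max - params$u_min) /
    (1 + exp(params$slope * (qtc - params$qtc_ref)))
}

#' Risk-attitude variant utility curves
#'
#' Decreasing alternatives to the sigmoid used in sensitivity analyses,
#' anchored at a bounded QTc domain `[a, b]` with value `u_max` at `a` and
#' `u_min` at `b`:
#' * `linear` — second derivative 0;
#' * `exp_convex` — exponential with second derivative > 0 (lies below the
#'   linear chord);
#' * `exp_concave` — exponential with second derivative < 0 (lies above the
#'   chord).
#'
#' The exponential form is
#' `u_min + (u_max - u_min) * (exp(k * s) - 1) / (exp(k) - 1)` with
#' `s = (b - qtc) / (b - a)` the reversed normalized position and the sign
#' of `k` selecting the curvature. Outside the domain values are clamped to
#' `[u_min, u_max]`.
#'
#' @inheritParams sigmoid_utility
#' @param family One of `"linear"`, `"exp_convex"`, `"exp_concave"`
#'   (`"sigmoid"` is delegated to [sigmoid_utility()]).
#' @param domain Length-2 anchoring interval in ms; default `c(380, 620)`.
#' @param curvature Positive magnitude of `k`; default 3.
#' @return Utility value(s) in `[u_min, u_max]`.
#' @export
variant_utility <- function(qtc, params, family, domain = c(380, 620),
                            curvature = 3) {
  stopifnot(inherits(params, "utility_params"))
  family <- match_family(family)
  if (family == "sigmoid") return(sigmoid_utility(qtc, params))
  if (curvature <= 0) stop("`curvature` must be positive", call. = FALSE)
  a <- domain[1]; b <- domain[2]
  s <- pmin(pmax((b - qtc) / (b - a), 0), 1)
  frac <- switch(family,
    linear = s,
    exp_convex = expm1(curvature * s) / expm1(curvature),
    exp_concave = expm1(-curvature * s) / expm1(-curvature)
  )
  params$u_min + (params$u_max - params$u_min) * frac
}

# curve lookup used by the decision model: status is "improved"/"unimproved"
utility_value <- function(qtc, pair, status) {
  params <- pair[[status]]
  if (pair$family == "sigmoid") sigmoid_utility(qtc, params)
  else variant_utility(qtc, params, pair$family, pair$domain, pair$curvature)
}

#' Tabulate a utility pair over a QTc grid
#'
#' @param pair A [utility_pair()].
#' @param grid QTc values in ms; `-Inf`/`Inf` rows give the curve limits.
#'   Defaults to the presentation grid
#'   `c(-Inf, 420, 450, 480, 510, 540, 570, Inf)`.
#' @param digits If non-`NULL`, round utilities half away from zero to this
#'   many decimals (0 reproduces the integer presentation convention).
#' @return Data frame with columns `qtc`, `improved`, `unimproved`.
#' @examples
#' utility_table(utility_pair(), digits = 0)
#' @export
utility_table <- function(pair,
                          grid = c(-Inf, 420, 450, 480, 510, 540, 570, Inf),
                          digits = NULL) {
  stopifnot(inherits(pair, "utility_pair"), length(grid) >= 1L)
  out <- data.frame(
    qtc = grid,
    improved = utility_value(grid, pair, "improved"),
    unimproved = utility_value(grid, pair, "unimproved")
  )
  if (!is.null(digits)) {
    out$improved <- round_half_away(out$improved, digits)
    out$unimproved <- round_half_away(out$unimproved, digits)
  }
  out
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @export
print.utility_params <- function(x, ...) {
  cat(sprintf(
    "Utility curve: u_min %g, u_max %g, slope %g /ms, inflection %g ms\n",
    x$u_min, x$u_max, x$slope, x$qtc_ref))
  invisible(x)
}

#' @export
print.utility_pair <- function(x, ...) {
  cat(sprintf("Utility pair (%s family)\n  improved:   ", x$family))
  print(x$improved)
  cat("  unimproved: ")
  print(x$unimproved)
  invisible(x)
}
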