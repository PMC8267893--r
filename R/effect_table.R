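#' Convert an odds ratio to a transition probability
#'
#' Translates a treatment's odds ratio for delirium improvement into the
#' transition probability of improvement, given the placebo improvement
#' probability `p0`. With odds `A = or * p0 / (1 - p0)`, the probability is
#' `A / (1 + A)`.
#'
#' @param or Positive odds ratio(s) of the treatment against placebo.
#' @param p0 Placebo transition probability, strictly inside (0, 1).
#'   Defaults to 0.5 (day-3 placebo response).
#' @return Transition probability in (0, 1), same length as `or`.
#' @seealso [probability_to_or()] for the exact inverse.
#' @examples
#' or_to_probability(1, 0.5)      # 0.5: OR = 1 leaves the rate unchanged
#' or_to_probability(4.102, 0.5)  # ~0.804
#' @export
or_to_probability <- function(or, p0 = 0.5) {
  if (!is.numeric(or) || any(!is.finite(or)) || any(or <= 0))
    stop("`or` must be a finite positive number", call. = FALSE)
  check_prob(p0, "p0")
  a <- or * p0 / (1 - p0)
  a / (1 + a)
}

#' Convert a transition probability to an odds ratio
#'
#' Exact algebraic inverse of [or_to_probability()]:
#' `or = (p / (1 - p)) / (p0 / (1 - p0))`.
#'
#' @param p Transition probability in (0, 1).
#' @inheritParams or_to_probability
#' @return Positive odds ratio, same length as `p`.
#' @export
probability_to_or <- function(p, p0 = 0.5) {
  check_prob(p, "p")
  check_prob(p0, "p0")
  (p / (1 - p)) / (p0 / (1 - p0))
}

# strict open-interval probability check, vectorized
check_prob <- function(x, label) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
    stop(sprintf("`%s` must lie strictly inside (0, 1)", label), call. = FALSE)
  invisible(x)
}

# two-sided 95% normal multiplier, fixed across the package
Z95 <- stats::qnorm(0.975)

#' Construct and validate a treatment effect table
#'
#' An effect table holds, per treatment, the transition probability to
#' improved delirium status with its 95% plausible range, and the mean QTc
#' shift in milliseconds with its 95% confidence interval. The placebo
#' transition probability `p0` is carried as an attribute. Probability
#' uncertainty is interpreted on the log odds-ratio scale, where published
#' network meta-analysis intervals are symmetric; construction checks that
#' each record's implied log-OR interval is approximately symmetric about
#' its point estimate.
#'
#' @param x A data frame with columns `name`, `p`, `p_lo`, `p_hi`, `dqtc`,
#'   `dqtc_lo`, `dqtc_hi` (case-insensitive). Alternatively columns
#'   `or`, `or_lo`, `or_hi` may replace the probability columns; they are
#'   converted via [or_to_probability()] with this table's `p0`.
#' @param p0 Placebo transition probability in (0, 1); default 0.5.
#' @param symmetry_tol Maximum allowed |log-OR interval midpoint - log-OR
#'   point| before a record is rejected; default 0.1. The packaged
#'   six-drug table has a worst case of about 0.018.
#' @return An object of class `effect_table`: a data frame with the seven
#'   canonical columns, attribute `p0`.
#' @seealso [read_effect_table()], [delirium_effect_table()],
#'   [logit_scale_params()]
#' @export
effect_table <- function(x, p0 = 0.5, symmetry_tol = 0.1) {
  check_prob(p0, "p0")
  if (!is.data.frame(x)) stop("`x` must be a data frame", call. = FALSE)
  names(x) <- tolower(names(x))

  prob_cols <- c("p", "p_lo", "p_hi")
  or_cols <- c("or", "or_lo", "or_hi")
  if (!("name" %in% names(x)))
    stop("missing required column: name", call. = FALSE)
  if (all(or_cols %in% names(x)) && !all(prob_cols %in% names(x))) {
    for (j in seq_along(or_cols)) {
      v <- x[[or_cols[j]]]
      check_numeric_col(v, or_cols[j])
      if (any(v <= 0))
        stop(sprintf("row %d, field %s: odds ratio must be positive",
                     which(v <= 0)[1], or_cols[j]), call. = FALSE)
      x[[prob_cols[j]]] <- or_to_probability(v, p0)
    }
  }

  need <- c("name", "p", "p_lo", "p_hi", "dqtc", "dqtc_lo", "dqtc_hi")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- x[need]
  x$name <- as.character(x$name)
  for (col in need[-1]) check_numeric_col(x[[col]], col)

  if (anyDuplicated(x$name))
    stop("treatment names must be unique; duplicated: ",
         paste(unique(x$name[duplicated(x$name)]), collapse = ", "),
         call. = FALSE)

  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    check_record_field(r$p > 0 && r$p < 1, i, "p", "must lie in (0, 1)")
    check_record_field(r$p_lo > 0 && r$p_hi < 1, i, "p_lo/p_hi",
                       "bounds must lie in (0, 1)")
    check_record_field(r$p_lo <= r$p && r$p <= r$p_hi, i, "p",
                       "needs p_lo <= p <= p_hi")
    check_record_field(r$dqtc_lo <= r$dqtc && r$dqtc <= r$dqtc_hi, i, "dqtc",
                       "needs dqtc_lo <= dqtc <= dqtc_hi")
    if (r$p_lo < r$p_hi) {
      mid <- (qlogis_or(r$p_hi) + qlogis_or(r$p_lo)) / 2
      if (abs(mid - qlogis_or(r$p)) > symmetry_tol)
        check_record_field(FALSE, i, "p_lo/p_hi",
          "log odds-ratio interval is not symmetric about the point estimate")
    }
  }

  rownames(x) <- NULL
  structure(x, p0 = p0, class = c("effect_table", "data.frame"))
}

qlogis_or <- function(p) log(p / (1 - p))

check_numeric_col <- function(v, col) {
  if (!is.numeric(v) || any(!is.finite(v)))
    stop(sprintf("row %s, field %s: non-numeric or missing value",
                 paste(which(!is.finite(suppressWarnings(as.numeric(v)))),
                       collapse = ","), col),
         call. = FALSE)
}

check_record_field <- function(ok, row, field, msg) {
  if (!ok)
    stop(sprintf("row %d, field %s: %s", row, field, msg), call. = FALSE)
}

#' Read an effect table from a delimited text file
#'
#' Reads a CSV (or TSV) file with a header row; column names are
#' case-insensitive and either probability columns (`p`, `p_lo`, `p_hi`) or
#' odds-ratio columns (`or`, `or_lo`, `or_hi`) are accepted, always with
#' `name`, `dqtc`, `dqtc_lo`, `dqtc_hi`. Record order in the file defines
#' reporting and tie-breaking order downstream.
#'
#' @param path Path to the delimited file.
#' @param p0 Placebo transition probability; default 0.5.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @return A validated [effect_table()].
#' @export
read_effect_table <- function(path, p0 = 0.5, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  effect_table(df, p0 = p0)
}

#' Write an effect table to CSV
#'
#' Values are written unrounded so that a write/read round trip reproduces
#' the table exactly.
#'
#' @param x An [effect_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(x, path) {
  stopifnot(inherits(x, "effect_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Effect sizes of six antipsychotics for delirium
#'
#' The packaged effect table for amisulpride, haloperidol, olanzapine,
#' quetiapine, risperidone and ziprasidone: transition probabilities to
#' improved delirium status (with 95% plausible ranges) compiled from a
#' network meta-analysis of antipsychotic trials in delirium, and mean QTc
#' shifts in ms (with 95% CIs) from a network meta-analysis of antipsychotic
#' safety trials. Placebo probability `p0` is 0.5.
#'
#' @param p0 Placebo transition probability; default 0.5.
#' @return An [effect_table()] with six records.
#' @examples
#' delirium_effect_table()
#' @export
delirium_effect_table <- function(p0 = 0.5) {
  path <- system.file("extdata", "antipsychotic_effects.csv",
                      package = "qtcda", mustWork = TRUE)
  read_effect_table(path, p0 = p0)
}

#' Log odds-ratio location and scale of each record
#'
#' Maps each record's transition probability and plausible range to the
#' log odds-ratio scale against `p0`: the location is
#' `log(probability_to_or(p, p0))` and the scale is the half-width of the
#' log-OR interval divided by the 95% normal quantile,
#' `(log OR_hi - log OR_lo) / (2 * 1.959964)`. These parameterize the
#' normal sampling distribution used by the probabilistic sensitivity
#' analysis. A degenerate range (`p_lo == p_hi`) yields scale 0.
#'
#' @param x An [effect_table()].
#' @param p0 Placebo probability; defaults to the table's own `p0`.
#' @return Data frame with columns `name`, `log_or_mean`, `log_or_sd`,
#'   plus `dqtc_mean` and `dqtc_sd` (natural-scale normal parameters of the
#'   QTc shift, `sd = (hi - lo) / (2 * 1.959964)`).
#' @export
logit_scale_params <- function(x, p0 = attr(x, "p0")) {
  stopifnot(inherits(x, "effect_table"))
  check_prob(p0, "p0")
  data.frame(
    name = x$name,
    log_or_mean = log(probability_to_or(x$p, p0)),
    log_or_sd = (qlogis_or(x$p_hi) - qlogis_or(x$p_lo)) / (2 * Z95),
    dqtc_mean = x$dqtc,
    dqtc_sd = (x$dqtc_hi - x$dqtc_lo) / (2 * Z95),
    stringsAsFactors = FALSE
  )
}

#' @export
print.effect_table <- function(x, ...) {
  cat(sprintf("Effect table: %d treatment(s), placebo p0 = %g\n",
              nrow(x), attr(x, "p0")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
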