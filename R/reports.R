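#' Write analysis reports to a directory
#'
#' Renders the standard file outputs of a run: the utility lookup table,
#' the deterministic expected-utility matrix, the PSA summary in both a
#' presentation shape (per drug: mean (SD), highest-utility share, share
#' beating placebo, with a fixed-utility placebo row) and a tidy
#' machine-readable shape, the sensitivity-sweep results, and a JSON run
#' manifest (seed, configuration echo, config hash, package and R
#' versions). Machine CSVs carry unrounded numbers; rounding is applied
#' only in the presentation copy. Given identical inputs and seeds the
#' files are byte-identical across runs.
#'
#' @param fit A `qtc_decision` object, or `NULL` to skip its outputs.
#' @param psa A `qtc_psa` object or `NULL`.
#' @param sweep A `qtc_sweep` object or `NULL`.
#' @param dir Output directory; created if missing.
#' @return Character vector of the files written, invisibly.
#' @export
render_reports <- function(fit = NULL, psa = NULL, sweep = NULL, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  if (file.access(dir, mode = 2) != 0)
    stop("output directory is not writable: ", dir, call. = FALSE)
  files <- character(0)
  wr <- function(df, name, quote = FALSE) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE, quote = quote)
    files <<- c(files, path)
  }

  config <- list()
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "qtc_decision"))
    wr(utility_table(fit$pair, digits = 0), "utility_table.csv")
    m <- fit$utilities_matrix
    wr(data.frame(name = rownames(m), m, check.names = FALSE),
       "utility_matrix.csv")
    config$baselines <- fit$baselines
    config$utility <- list(
      family = fit$pair$family,
      improved = unclass(fit$pair$improved),
      unimproved = unclass(fit$pair$unimproved))
    config$p0 <- attr(fit$table, "p0")
  }
  if (!is.null(psa)) {
    stopifnot(inherits(psa, "qtc_psa"))
    wr(psa$summary, "psa_summary.csv")
    wr(psa_presentation(psa), "psa_table.csv", quote = TRUE)
    config$psa <- unclass(psa$config)
  }
  if (!is.null(sweep)) {
    stopifnot(inherits(sweep, "qtc_sweep"))
    wr(sweep$results, "sweep_results.csv")
    wr(data.frame(baseline = names(sweep$modal_argmax),
                  modal_argmax = unname(sweep$modal_argmax),
                  default_argmax = unname(sweep$default_argmax)),
       "sweep_summary.csv")
  }

  manifest <- list(
    package = "qtcda",
    package_version = as.character(utils::packageVersion("qtcda")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = if (!is.null(psa)) psa$config$seed else NA,
    config = config,
    config_hash = config_hash(config),
    files = basename(files))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(files, manifest_path))
}

# md5 of the canonical JSON form of the run configuration
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# per-drug presentation block in the published layout: a fixed-utility
# placebo row, then mean (SD) / highest / beats-placebo rows per drug
psa_presentation <- function(psa) {
  s <- psa$summary
  bl <- psa$baselines
  rows <- list(data.frame(
    option = "Placebo", metric = "Utility (fixed)",
    t(vapply(bl, function(b) sprintf("%.2f", psa$placebo[as.character(b)]),
             character(1))), check.names = FALSE))
  add <- function(option, metric, vals)
    rows[[length(rows) + 1L]] <<- data.frame(
      option = option, metric = metric, t(vals), check.names = FALSE)
  add("Placebo", "Highest utility",
      vapply(bl, function(b)
        sprintf("%d%%", round(s$p_highest[s$name == "Placebo" &
                                            s$baseline == b])),
        character(1)))
  for (drug in unique(s$name[s$name != "Placebo"])) {
    sd_ <- s[s$name == drug, ]
    add(drug, "Utility, mean (SD)",
        sprintf("%.2f (%.2f)", sd_$mean, sd_$sd))
    add(drug, "Highest utility", sprintf("%d%%", round(sd_$p_highest)))
    add(drug, "Higher than placebo",
        sprintf("%d%%", round(sd_$p_beats_placebo)))
  }
  out <- do.call(rbind, rows)
  names(out) <- c("option", "metric", bl)
  out
}
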