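# shared fixtures: the packaged six-drug table and builders for edge cases

drug_table <- delirium_effect_table()

# a table whose plausible ranges all collapse to the point estimates
degenerate_table <- function(tab = drug_table) {
  df <- as.data.frame(tab)
  df$p_lo <- df$p_hi <- df$p
  df$dqtc_lo <- df$dqtc_hi <- df$dqtc
  effect_table(df, p0 = attr(tab, "p0"))
}

# published PSA summary (Table-3 layout) used by the stochastic checks:
# mean utility, highest-utility share (%), beats-placebo share (%)
published_psa <- list(
  mean = matrix(c(78.65, 72.32, 55.59, 35.47,
                  77.61, 73.99, 62.18, 41.58,
                  77.38, 73.32, 60.55, 39.86,
                  81.52, 77.45, 64.48, 42.97,
                  71.06, 67.18, 55.05, 35.65,
                  78.31, 73.10, 58.07, 37.35),
                nrow = 6, byrow = TRUE,
                dimnames = list(drug_table$name, c(420, 450, 480, 510))),
  highest = matrix(c(36, 28, 13, 10,
                     5, 7, 14, 18,
                     9, 11, 14, 15,
                     31, 36, 46, 47,
                     2, 2, 3, 2,
                     18, 16, 11, 8),
                   nrow = 6, byrow = TRUE,
                   dimnames = list(drug_table$name, c(420, 450, 480, 510))),
  beats = matrix(c(80, 77, 68, 64,
                   98, 98, 97, 96,
                   92, 91, 88, 85,
                   91, 90, 89, 88,
                   79, 77, 70, 64,
                   87, 85, 77, 72),
                 nrow = 6, byrow = TRUE,
                 dimnames = list(drug_table$name, c(420, 450, 480, 510))),
  placebo = c(`420` = 64.10, `450` = 61.21, `480` = 51.55, `510` = 33.88)
)

psa_summary_matrix <- function(psa, metric) {
  s <- psa$summary[psa$summary$name != "Placebo", ]
  m <- matrix(s[[metric]], nrow = length(unique(s$name)),
              dimnames = list(unique(s$name), unique(s$baseline)))
  m
}
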