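test_that("sampling honours the plausible ranges by construction", {
  cfg <- psa_config(n_draws = 1e5, seed = 123)
  draws <- sample_effects(drug_table, cfg)
  expect_identical(dim(draws$p), c(100000L, 6L))
  # amisulpride's sampled probabilities recover its plausible-range ends
  q <- quantile(draws$p[, "Amisulpride"], c(0.025, 0.975))
  expect_lt(max(abs(unname(q) - c(0.153, 0.989))), 0.01)
  expect_true(all(draws$p > 0 & draws$p < 1))
  # haloperidol's sampled QTc shift is centred on its point estimate
  mc_se <- sd(draws$dqtc[, "Haloperidol"]) / sqrt(1e5)
  expect_lt(abs(mean(draws$dqtc[, "Haloperidol"]) - 1.69), 3 * mc_se)
})

test_that("sampling is reproducible and degenerate ranges collapse", {
  cfg <- psa_config(n_draws = 200, seed = 42)
  expect_identical(sample_effects(drug_table, cfg),
                   sample_effects(drug_table, cfg))
  d <- sample_effects(degenerate_table(), cfg)
  expect_equal(d$p, matrix(rep(drug_table$p, each = 200), 200,
                           dimnames = dimnames(d$p)))
  expect_equal(d$dqtc[1, ], setNames(drug_table$dqtc, drug_table$name))
  expect_equal(apply(d$dqtc, 2, sd), setNames(rep(0, 6), drug_table$name))
})

test_that("the truncated-normal probability scale stays inside (0, 1)", {
  cfg <- psa_config(n_draws = 2e4, seed = 9,
                    probability_scale = "truncated_normal_p")
  draws <- sample_effects(drug_table, cfg)
  expect_true(all(draws$p > 0 & draws$p < 1))
  # for a narrow, central interval truncation barely bites: the mean is
  # close to the point estimate
  expect_equal(mean(draws$p[, "Haloperidol"]), 0.703, tolerance = 0.01)
})

test_that("the PSA run is seed-reproducible and internally consistent", {
  cfg <- psa_config(n_draws = 2000, seed = 7)
  a <- run_psa(drug_table, config = cfg)
  b <- run_psa(drug_table, config = cfg)
  expect_identical(a$summary, b$summary)
  s <- a$summary
  expect_true(all(s$sd >= 0))
  expect_equal(s$mc_se, s$sd / sqrt(2000))
  # highest-utility shares over all options sum to 100% at each baseline
  for (b_ in unique(s$baseline))
    expect_equal(sum(s$p_highest[s$baseline == b_]), 100, tolerance = 1e-9)
  # placebo rows carry the deterministic fixed utility
  expect_equal(s$mean[s$name == "Placebo"],
               unname(expected_utility(0.5, c(420, 450, 480, 510))))
  expect_equal(s$sd[s$name == "Placebo"], rep(0, 4))
})

test_that("degenerate intervals collapse the PSA onto the deterministic fit", {
  tab <- degenerate_table()
  psa <- run_psa(tab, config = psa_config(n_draws = 500, seed = 3))
  fit <- decision_analysis(tab)
  s <- psa$summary
  for (b in c(420, 450, 480, 510)) {
    sb <- s[s$baseline == b, ]
    expect_equal(sb$mean, unname(fit$utilities_matrix[, as.character(b)]))
    expect_equal(sb$sd, rep(0, 7))
    # exactly one option takes every draw
    expect_equal(sort(sb$p_highest), c(rep(0, 6), 100))
  }
})

test_that("fresh draws per baseline change draws but not conclusions", {
  cfg_shared <- psa_config(n_draws = 4000, seed = 5)
  cfg_fresh <- psa_config(n_draws = 4000, seed = 5,
                          share_draws_across_baselines = FALSE)
  a <- run_psa(drug_table, config = cfg_shared)
  b <- run_psa(drug_table, config = cfg_fresh)
  expect_identical(a$summary[a$summary$baseline == 420, ],
                   b$summary[b$summary$baseline == 420, ])
  expect_false(identical(a$summary, b$summary))
  expect_equal(a$summary$mean, b$summary$mean, tolerance = 1)
})

test_that("Monte Carlo means agree with Gauss-Hermite quadrature", {
  psa <- run_psa(drug_table, config = psa_config(n_draws = 10000, seed = 21))
  s <- psa$summary
  for (i in seq_len(nrow(drug_table))) {
    for (b in c(420, 450, 480, 510)) {
      row <- s[s$name == drug_table$name[i] & s$baseline == b, ]
      oracle <- quadrature_oracle(drug_table[i, ], b)
      expect_lt(abs(row$mean - oracle), 3 * row$mc_se)
    }
  }
})

test_that("quadrature oracle respects degenerate limits and Jensen's gap", {
  rec <- as.list(degenerate_table()[4, ])
  expect_equal(quadrature_oracle(rec, 460), evaluate_treatment(rec, 460),
               tolerance = 1e-9)
  # QTc-only uncertainty confined to the concave region (far below the
  # inflection) pulls the mean utility below the point-estimate utility
  concave_rec <- list(p = 0.7, p_lo = 0.7, p_hi = 0.7,
                      dqtc = 0, dqtc_lo = -15, dqtc_hi = 15)
  expect_lt(quadrature_oracle(concave_rec, 460),
            evaluate_treatment(concave_rec, 460))
})

test_that("PSA configuration is validated", {
  expect_error(psa_config(n_draws = 0), "positive integer")
  expect_error(psa_config(n_draws = 10.5), "positive integer")
  expect_error(psa_config(seed = "a"), "seed")
  expect_error(psa_config(probability_scale = "beta"), "arg")
})

test_that("simulate() on a fit delegates to the PSA with the fit's setup", {
  fit <- decision_analysis(drug_table, baselines = c(450, 480))
  psa <- simulate(fit, nsim = 300, seed = 17)
  expect_s3_class(psa, "qtc_psa")
  expect_identical(psa$baselines, c(450, 480))
  expect_identical(psa$config$n_draws, 300L)
  direct <- run_psa(drug_table, baselines = c(450, 480),
                    config = psa_config(n_draws = 300, seed = 17))
  expect_identical(psa$summary, direct$summary)
})
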