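test_that("placebo expected utilities reproduce the published fixed row", {
  u <- expected_utility(0.5, c(420, 450, 480, 510))
  expect_equal(u, c(64.10, 61.21, 51.55, 33.88), tolerance = 0.005)
})

test_that("expected utility is the stated convex combination", {
  pair <- utility_pair()
  # hand oracle: direct evaluation of both sigmoids
  ui <- function(q) 30 + 70 / (1 + exp(0.05 * (q - 500)))
  uu <- function(q) 30 / (1 + exp(0.05 * (q - 500)))
  for (q in c(400, 470, 505, 560)) {
    for (p in c(0, 0.25, 0.7, 1)) {
      expect_equal(expected_utility(p, q, pair), p * ui(q) + (1 - p) * uu(q),
                   tolerance = 1e-12)
    }
    expect_equal(expected_utility(1, q, pair), ui(q), tolerance = 1e-12)
    expect_equal(expected_utility(0, q, pair), uu(q), tolerance = 1e-12)
  }
  expect_error(expected_utility(-0.1, 450), "0, 1")
  expect_error(expected_utility(1.2, 450), "0, 1")
})

test_that("expected utility is linear in p and bounded by the two curves", {
  pair <- utility_pair()
  set.seed(11)
  for (i in 1:20) {
    q <- runif(1, 350, 650)
    p1 <- runif(1); p2 <- runif(1); a <- runif(1)
    expect_equal(expected_utility(a * p1 + (1 - a) * p2, q, pair),
                 a * expected_utility(p1, q, pair) +
                   (1 - a) * expected_utility(p2, q, pair),
                 tolerance = 1e-10)
    u <- expected_utility(p1, q, pair)
    lo <- min(sigmoid_utility(q, pair$improved),
              sigmoid_utility(q, pair$unimproved))
    hi <- max(sigmoid_utility(q, pair$improved),
              sigmoid_utility(q, pair$unimproved))
    expect_true(u >= lo && u <= hi)
  }
})

test_that("treatment evaluation shifts QTc by the drug effect size", {
  # hand evaluation with haloperidol's point estimates (p .703, shift 1.69)
  q <- 420 + 1.69
  hand <- 0.703 * (30 + 70 / (1 + exp(0.05 * (q - 500)))) +
    0.297 * (30 / (1 + exp(0.05 * (q - 500))))
  expect_equal(evaluate_treatment(drug_table[2, ], 420), hand,
               tolerance = 1e-12)
  expect_equal(hand, 78.07, tolerance = 0.005)
  # amisulpride point estimates at 420
  expect_equal(evaluate_treatment(drug_table[1, ], 420), 84.058,
               tolerance = 5e-4)
  # a drug indistinguishable from placebo scores the placebo value
  sham <- list(p = 0.5, dqtc = 0)
  expect_equal(evaluate_treatment(sham, 465), expected_utility(0.5, 465))
})

test_that("the fitted grid reproduces the published orderings", {
  fit <- decision_analysis(drug_table)
  m <- fit$utilities_matrix
  expect_identical(rownames(m)[1], "Placebo")
  expect_identical(colnames(m), c("420", "450", "480", "510"))
  # amisulpride tops 420 (tie with quetiapine broken by table order),
  # quetiapine tops every prolonged baseline
  expect_identical(rank_treatments(fit, 420)$name[1], "Amisulpride")
  for (b in c(450, 480, 510))
    expect_identical(rank_treatments(fit, b)$name[1], "Quetiapine")
  # risperidone is the weakest drug and placebo trails all drugs at 420
  drugs <- m[-1, ]
  expect_true(all(apply(drugs, 2, which.min) == match("Risperidone",
                                                      rownames(drugs))))
  expect_true(all(drugs[, "420"] > m["Placebo", "420"]))
})

test_that("utilities decrease and stay bounded as baseline QTc grows", {
  fit <- decision_analysis(drug_table, baselines = seq(380, 620, by = 10))
  m <- fit$utilities_matrix
  expect_true(all(t(apply(m, 1, diff)) < 0))
  expect_true(all(m >= 0 & m <= 100))
  # monotone in p at fixed QTc: improved dominance makes EU increasing
  u <- vapply(seq(0.05, 0.95, by = 0.05), expected_utility, numeric(1),
              qtc = 505)
  expect_true(all(diff(u) > 0))
})

test_that("rankings break ties by table order and validate the baseline", {
  df <- data.frame(name = c("b_first", "a_second"),
                   p = 0.7, p_lo = 0.5, p_hi = 0.85,
                   dqtc = 2, dqtc_lo = 1, dqtc_hi = 3)
  fit <- decision_analysis(effect_table(df), baselines = c(450, 480))
  r <- rank_treatments(fit, 450)
  expect_identical(r$name, c("b_first", "a_second", "Placebo"))
  expect_equal(r$utility[1], r$utility[2])
  expect_error(rank_treatments(fit, 500), "not in the fitted grid")
})

test_that("an empty treatment list leaves a placebo-only analysis", {
  empty <- effect_table(data.frame(name = character(), p = numeric(),
                                   p_lo = numeric(), p_hi = numeric(),
                                   dqtc = numeric(), dqtc_lo = numeric(),
                                   dqtc_hi = numeric()))
  fit <- decision_analysis(empty)
  expect_identical(rownames(fit$utilities_matrix), "Placebo")
  expect_equal(fit$utilities_matrix["Placebo", ],
               expected_utility(0.5, c(420, 450, 480, 510)),
               ignore_attr = TRUE)
})

test_that("fit accessors and grid validation behave", {
  fit <- decision_analysis(drug_table)
  cf <- coef(fit)
  expect_equal(cf["Placebo", ], c(p = 0.5, dqtc = 0))
  expect_equal(unname(cf["Quetiapine", "p"]), 0.791)
  pr <- predict(fit, baselines = c(430, 500))
  expect_identical(dim(pr), c(7L, 2L))
  expect_equal(pr["Placebo", "500"], expected_utility(0.5, 500))
  expect_error(decision_analysis(drug_table, baselines = c(450, 420)),
               "increasing")
  expect_warning(decision_analysis(drug_table, baselines = c(250, 420)),
                 "physiologic")
})
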