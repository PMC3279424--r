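test_that("the saturating subscore obeys its boundary conditions", {
  expect_equal(subscore(0, 2.3), 0)
  expect_equal(subscore(0, 0), 0)
  expect_equal(subscore(1, 2.3), 0.899741, tolerance = 1e-6)
  expect_equal(subscore(5, 0), 0)               # degenerate steepness
  expect_lt(subscore(10, 3), 1)                 # finite evidence stays short
  expect_equal(subscore(1e6, 3), 1, tolerance = 1e-9)
  expect_error(subscore(-1, 1), "n >= 0")
  expect_error(subscore(1, -1), "n >= 0")
  # strictly increasing in n and in a
  n <- 0:10
  s <- subscore(n, 1.5)
  expect_true(all(diff(s) > 0))
  a <- seq(0.1, 3, by = 0.1)
  expect_true(all(diff(subscore(2, a)) > 0))
})

test_that("score_interaction reproduces the published landscape", {
  p <- scoring_params()
  expect_equal(unclass(p)[1:6],
               c(a_s = 2.3, a_o = 1.6, a_t = 0.2,
                 w_s = 0.6, w_o = 0.1, w_t = 0.3))
  expect_equal(score_interaction(evidence_counts_values(0, 0, 0), p), 0)
  s1 <- score_interaction(evidence_counts_values(1, 0, 5), p)
  expect_equal(s1, 0.729481, tolerance = 1e-6)
  # saturation limit approaches the weight sum = 1
  expect_equal(score_interaction(evidence_counts_values(1000, 1000, 1000), p),
               1, tolerance = 1e-12)
  expect_lt(score_interaction(evidence_counts_values(3, 2, 10), p), 1)
})

test_that("scores are monotone in every evidence component and weight", {
  p <- scoring_params()
  base <- score_interaction(evidence_counts_values(2, 1, 5), p)
  expect_gt(score_interaction(evidence_counts_values(3, 1, 5), p), base)
  expect_gt(score_interaction(evidence_counts_values(2, 2, 5), p), base)
  expect_gt(score_interaction(evidence_counts_values(2, 1, 7.5), p), base)
  # raising a weight on a positive subscore (rebalancing from another)
  p2 <- scoring_params(w_s = 0.7, w_o = 0.0, w_t = 0.3)
  expect_gt(score_interaction(evidence_counts_values(2, 0, 5), p2),
            score_interaction(evidence_counts_values(2, 0, 5),
                              scoring_params(w_s = 0.6, w_o = 0.1,
                                             w_t = 0.3)))
})

test_that("without organism evidence scores match a two-component oracle", {
  p <- scoring_params()
  set.seed(5)
  ns <- sample(0:6, 50, replace = TRUE)
  tm <- sample(c(0, 2.5, 5, 10, 15), 50, replace = TRUE)
  oracle <- 0.6 * (1 - exp(-2.3 * ns)) + 0.3 * (1 - exp(-0.2 * tm))
  got <- score_interaction(evidence_counts_values(ns, 0, tm), p)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("evidence order never affects the score (set semantics)", {
  tab <- default_technique_scores()
  n1 <- hippie_network("A", "B",
                       studies = list(c("2", "1")),
                       techniques = list(c("Two-hybrid", "FRET")),
                       sources = list("DS"))
  n2 <- hippie_network("B", "A",
                       studies = list(c("1", "2")),
                       techniques = list(c("FRET", "Two-hybrid")),
                       sources = list("DS"))
  expect_equal(score_network(n1, table = tab)$score,
               score_network(n2, table = tab)$score)
})

test_that("invalid parameters are rejected", {
  expect_error(scoring_params(w_s = 0.5, w_o = 0.5, w_t = 0.5), "sum to 1")
  expect_error(scoring_params(a_s = -1), "non-negative")
  expect_error(scoring_params(w_s = 1.2, w_o = -0.2, w_t = 0), "\\[0, 1\\]")
})

test_that("score_network is pure and idempotent", {
  fx <- merged_fixture(seed = 4)
  s1 <- score_network(fx$net)
  s2 <- score_network(s1)  # rescoring a scored network
  expect_identical(s1$score, s2$score)
  # identical evidence -> identical score
  i <- which(lengths(s1$studies) == 1 & lengths(s1$techniques) == 1)
  same <- split(s1$score[i],
                paste(sapply(s1$studies[i], length),
                      sapply(s1$techniques[i], `[`, 1),
                      lengths(s1$organisms[i])))
  for (grp in same) expect_length(unique(grp), 1L)
  expect_true(all(s1$score >= 0 & s1$score < 1))
})

test_that("upper_quartile follows the nearest-rank convention", {
  # ceil(0.75 * 4) = 3rd order statistic
  expect_equal(upper_quartile(c(0.1, 0.2, 0.3, 0.4)), 0.3)
  expect_equal(upper_quartile(rep(0.42, 10)), 0.42)
  expect_equal(upper_quartile(c(0.1, 0.2, 0.3, 0.4, 0.5)), 0.4)
  expect_error(upper_quartile(c(0.1, 0.2)), "at least 4")
  # adding scores below the current Q3 never raises it
  set.seed(8)
  x <- runif(40)
  q <- upper_quartile(x)
  for (rep in 1:10) {
    extra <- runif(sample(1:20, 1), max = q - 1e-9)
    expect_lte(upper_quartile(c(x, extra)), q)
  }
})

test_that("a single-study interaction cannot reach the high-confidence band on techniques alone", {
  p <- scoring_params()
  tab <- default_technique_scores()
  # richest possible technique set: every entry of the table
  all_mass <- sum(tab$score[!duplicated(tab$norm_name)])
  s_max <- score_interaction(evidence_counts_values(1, 0, all_mass), p)
  expect_lt(s_max, 0.6 * subscore(1, 2.3) + 0.3 + 1e-12)
  expect_lt(0.6 * subscore(1, 2.3) + 0.3, 0.84)
  # generated single-study bundles stay below 0.84
  set.seed(9)
  for (rep in 1:50) {
    mass <- sum(sample(tab$score, sample(1:6, 1)))
    expect_lt(score_interaction(evidence_counts_values(1, 0, mass), p), 0.84)
  }
})
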