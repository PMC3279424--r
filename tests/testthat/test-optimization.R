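test_that("the weight simplex enumeration matches brute force", {
  # compositions of 10 into 3 non-negative parts
  brute <- 0L
  for (i in 0:10) for (j in 0:10) if (i + j <= 10) brute <- brute + 1L
  g <- enumerate_grid(a_step = 3, w_step = 0.1)  # a in {0, 3}: 8 triples
  w <- unique(g[, c("w_s", "w_o", "w_t")])
  expect_equal(nrow(w), brute)
  expect_equal(brute, 66L)
  expect_true(all(abs(g$w_s + g$w_o + g$w_t - 1) < 1e-9))
  expect_equal(nrow(g), 2^3 * 66)
})

test_that("reduced grids have the expected cardinality and order", {
  g <- enumerate_grid(a_step = 1, w_step = 0.2)
  expect_equal(nrow(g), 4^3 * 21)
  # deterministic lexicographic order
  expect_identical(g, g[order(g$a_s, g$a_o, g$a_t, g$w_s, g$w_o), ],
                   ignore_attr = TRUE)
  expect_error(enumerate_grid(w_step = 0.3), "integer")
})

test_that("holdout deviation matches direct arithmetic", {
  # dev = (n_high + 0.5) / (0.25 * overlap + 0.5)
  expect_equal((2 + 0.5) / (0.25 * 8 + 0.5), 1)    # observed = expectation
  expect_equal((8 + 0.5) / (0.25 * 8 + 0.5), 3.4)  # enrichment

  fx <- merged_fixture(spec = strong_signal_spec(2))
  pre_study <- attr(fx$net, "provenance")$study
  j <- names(sort(table(pre_study[nzchar(pre_study)]), decreasing = TRUE))[1]
  h <- loso_deviation(fx$net, j)
  expect_true(h$eligible)
  expect_equal(h$dev, (h$n_high + 0.5) / (0.25 * h$overlap + 0.5))
  expect_gte(h$n_high, 0)
  expect_lte(h$n_high, h$overlap)
})

test_that("removing the sole supporting study drops the interaction", {
  map <- tiny_mapping(4)
  d <- rbind(
    tiny_records("S1", "S2", pmids = list("10"), techs = list("Two-hybrid")),
    tiny_records("S1", "S3", pmids = list(c("10", "11")),
                 techs = list("FRET")),
    tiny_records("S2", "S3", pmids = list("11"), techs = list("FRET")))
  class(d) <- c("hippie_records", "data.frame")
  net <- merge_sources(d, map)
  h <- loso_deviation(net, "10", min_interactions = 1L, min_multi = -1L)
  # (P01,P02) was supported only by study 10: its evidence vanishes, so the
  # overlap with the reduced set is only (P01,P03)
  expect_true(h$eligible)
  expect_equal(h$overlap, 1L)
})

test_that("ineligible studies yield a skip notice, not an error", {
  fx <- merged_fixture(spec = strong_signal_spec(3))
  prov <- attr(fx$net, "provenance")
  j <- names(which.min(table(prov$study[nzchar(prov$study)])))
  h <- loso_deviation(fx$net, j, min_interactions = 1000L)
  expect_false(h$eligible)
  expect_error(loso_deviation(fx$net, "not-a-study"), "not present")
})

test_that("the objective is the overlap-weighted geometric mean of dev", {
  hd <- function(dev, v) data.frame(dev = dev, v = v)
  expect_equal(objective_f(hd(c(1, 1, 1), c(5, 1, 9))), 1)
  expect_equal(objective_f(hd(c(2, 2), c(1, 7))), 2)
  expect_equal(objective_f(hd(c(4, 1), c(3, 1))), exp(3 * log(4) / 4))
  expect_equal(objective_f(hd(c(4, 1), c(3, 1))), 2.828, tolerance = 1e-3)
  # invariant under uniform scaling of the weights
  set.seed(3)
  dev <- runif(10, 0.5, 4)
  v <- sample(1:20, 10)
  expect_equal(objective_f(hd(dev, v)), objective_f(hd(dev, 17 * v)))
  # invariant under permutation
  p <- sample(10)
  expect_equal(objective_f(hd(dev, v)), objective_f(hd(dev[p], v[p])))
  expect_error(objective_f(hd(numeric(0), numeric(0))), "at least one")
})

test_that("a grid restricted to one combination returns that combination", {
  fx <- merged_fixture(spec = strong_signal_spec(4))
  g <- data.frame(a_s = 2.3, a_o = 1.6, a_t = 0.2,
                  w_s = 0.6, w_o = 0.1, w_t = 0.3)
  fit <- fit_scoring_params(fx$net, grid = g)
  expect_equal(unname(coef(fit)), c(2.3, 1.6, 0.2, 0.6, 0.1, 0.3))
  expect_false(fit$report$degenerate[1])  # published default not filtered
  expect_equal(fit$n_studies_used, nrow(fit$holdouts))
  # and f equals the objective recomputed from the winner's holdouts
  expect_equal(fit$f, objective_f(fit$holdouts))
})

test_that("technique-free weightings are excluded as degenerate", {
  fx <- merged_fixture(spec = strong_signal_spec(5))
  # w_t = 0: the score only sees study/organism counts -> few distinct values
  g <- rbind(data.frame(a_s = 2.3, a_o = 1.6, a_t = 0.2,
                        w_s = 0.9, w_o = 0.1, w_t = 0),
             data.frame(a_s = 2.3, a_o = 1.6, a_t = 0.2,
                        w_s = 0.6, w_o = 0.1, w_t = 0.3))
  fit <- fit_scoring_params(fx$net, grid = g)
  expect_true(fit$report$degenerate[1])
  expect_false(fit$report$degenerate[2])
  expect_equal(coef(fit)[["w_t"]], 0.3)
  # all-degenerate grid errors
  expect_error(fit_scoring_params(fx$net, grid = g[1, ]), "degenerate")
})

test_that("holdout order never changes the fit", {
  fx <- merged_fixture(seed = 6)  # full technique pool: fine-grained scores
  g <- enumerate_grid(a_step = 1.5, w_step = 0.5)
  f1 <- fit_scoring_params(fx$net, grid = g)
  # permuting the provenance rows permutes holdout evaluation order
  net2 <- fx$net
  prov <- attr(net2, "provenance")
  attr(net2, "provenance") <- prov[rev(seq_len(nrow(prov))), ]
  f2 <- fit_scoring_params(net2, grid = g)
  expect_equal(coef(f1), coef(f2))
  expect_equal(f1$f, f2$f)
})

test_that("predict and coef expose the fitted parameters", {
  fx <- merged_fixture(spec = strong_signal_spec(7))
  g <- data.frame(a_s = 2.3, a_o = 1.6, a_t = 0.2,
                  w_s = 0.6, w_o = 0.1, w_t = 0.3)
  fit <- fit_scoring_params(fx$net, grid = g)
  scored <- predict(fit, fx$net)
  direct <- score_network(fx$net, params = scoring_params())
  expect_equal(scored$score, direct$score)
  expect_named(coef(fit), c("a_s", "a_o", "a_t", "w_s", "w_o", "w_t"))
})
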