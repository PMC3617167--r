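test_that("effective exposure subtracts the threshold and adds persistence", {
  p <- tva_params(C = 20, K = 4, t0 = 0.004, mu = 0.184)
  expect_equal(effective_exposure(display_condition(6, 0.200, TRUE), p),
               0.196)
  expect_equal(effective_exposure(display_condition(6, 0.200, FALSE), p),
               0.380)
  p2 <- tva_params(C = 20, K = 4, t0 = 0.025, mu = 0.184)
  expect_equal(effective_exposure(display_condition(6, 0.010, TRUE), p2), 0)
  # below threshold, persistence does not rescue the trial
  expect_equal(effective_exposure(display_condition(6, 0.010, FALSE), p2), 0)
})

test_that("encoding probability follows the divided-rate exponential law", {
  p <- tva_params(C = 30, K = 6)
  expect_equal(encoding_probability(6, 0, p), 0)
  expect_equal(encoding_probability(6, 0.1, p), 1 - exp(-0.5))
  expect_equal(round(encoding_probability(6, 0.1, p), 5), 0.39347)
  huge <- tva_params(C = 1e6, K = 6)
  expect_gt(encoding_probability(3, 0.01, huge), 1 - 1e-6)
  # monotone in tau and C, decreasing in n
  taus <- seq(0, 0.5, by = 0.01)
  probs <- vapply(taus, encoding_probability, numeric(1), n = 6, params = p)
  expect_true(all(diff(probs) > 0))
  expect_gt(encoding_probability(3, 0.1, p), encoding_probability(6, 0.1, p))
})

test_that("score distribution matches binomial-with-cap closed form", {
  p <- tva_params(C = 30, K = 3, t0 = 0.010)
  cond <- display_condition(6, 0.110, masked = TRUE)
  d <- score_distribution(cond, p)
  expect_equal(round(unname(d[1:4]), 4), c(0.0498, 0.1938, 0.3143, 0.4421))
  expect_equal(unname(d[5:7]), c(0, 0, 0)) # no mass above the cap
  expect_equal(sum(d), 1, tolerance = 1e-12)
})

test_that("score distribution degenerates correctly and always normalizes", {
  p <- tva_params(C = 30, K = 3, t0 = 0.010)
  # no effective exposure -> certain score 0
  d0 <- score_distribution(display_condition(6, 0.005, TRUE), p)
  expect_equal(unname(d0), c(1, rep(0, 6)))
  # zero capacity -> certain score 0
  dk <- score_distribution(display_condition(6, 0.2, TRUE),
                           tva_params(C = 30, K = 0))
  expect_equal(unname(dk), c(1, rep(0, 6)))
  set.seed(11)
  for (i in 1:50) {
    pp <- tva_params(C = runif(1, 2, 80), K = runif(1, 0, 6),
                     t0 = runif(1, 0, 0.03), mu = runif(1, 0, 0.4))
    cond <- display_condition(sample(c(3, 6), 1), runif(1, 0.01, 0.3),
                              sample(c(TRUE, FALSE), 1))
    d <- score_distribution(cond, pp)
    expect_equal(sum(d), 1, tolerance = 1e-12)
    expect_true(all(d >= 0))
    above_cap <- which(0:cond$n > min(cond$n, ceiling(pp$K)))
    expect_true(all(d[above_cap] == 0))
  }
})

test_that("expected score: frozen value, asymptote, threshold behaviour", {
  p <- tva_params(C = 30, K = 3, t0 = 0.010)
  expect_equal(round(expected_score(display_condition(6, 0.110, TRUE), p),
                     4), 2.1488)
  # asymptote min(n, K) for integer K
  expect_equal(expected_score(display_condition(6, 10, FALSE), p), 3,
               tolerance = 1e-9)
  expect_equal(expected_score(display_condition(6, 0.010, TRUE), p), 0)
})

test_that("expected score is nondecreasing and concave in exposure", {
  p <- tva_params(C = 24.6, K = 3.6, t0 = 0.004, mu = 0.184)
  for (n in c(3, 6)) {
    taus <- seq(0.005, 0.4, by = 0.005)
    es <- vapply(taus, function(tt)
      expected_score(display_condition(n, tt, TRUE), p), numeric(1))
    expect_true(all(diff(es) >= -1e-12))
    expect_true(all(diff(diff(es)) <= 1e-9))
  }
})

test_that("initial slope of the expected-score curve equals C", {
  # the slope at the origin is C regardless of display size
  for (C in c(12, 24.6, 55)) for (n in c(3, 6)) {
    p <- tva_params(C = C, K = n, t0 = 0.004)
    h <- 1e-5
    slope <- expected_score(display_condition(n, p$t0 + h, TRUE), p) / h
    expect_equal(slope, C, tolerance = 0.01)
  }
})

test_that("race simulator agrees with the closed-form distribution", {
  p <- tva_params(C = 30, K = 3, t0 = 0.010)
  cond <- display_condition(6, 0.110, masked = TRUE)
  expect_identical(simulate_trials(display_condition(6, 0.005, TRUE), p,
                                   20, seed = 1), integer(20))
  # no cap binding, everything encoded
  fast <- tva_params(C = 1e5, K = 6)
  expect_true(all(simulate_trials(display_condition(3, 1, FALSE), fast,
                                  50, seed = 2) == 3L))
  draws <- simulate_trials(cond, p, 1e5, seed = 3)
  probs <- score_distribution(cond, p)
  obs <- tabulate(draws + 1L, nbins = 7)
  keep <- probs > 0
  gof <- suppressWarnings(
    chisq.test(obs[keep], p = probs[keep] / sum(probs[keep])))
  expect_gt(gof$p.value, 0.001)
})

test_that("simulated scores are reproducible under a seed", {
  p <- typical_params()
  cond <- display_condition(6, 0.110, TRUE)
  expect_identical(simulate_trials(cond, p, 100, seed = 5),
                   simulate_trials(cond, p, 100, seed = 5))
})
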