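# independent grid-search oracle for the kappa^2 maximum: grid each path's
# feasible correlation interval (PSD constraint with the other two
# correlations held fixed) and maximize the magnitude with the observed sign
kappa2_oracle <- function(cohort, x, m, y, covariates) {
  res <- function(v) residuals(lm(reformulate(covariates, v), cohort))
  rx <- res(x); rm_ <- res(m); ry <- res(y)
  r_xm <- cor(rx, rm_); r_xy <- cor(rx, ry); r_my <- cor(rm_, ry)
  b_of <- function(rmy, rxm) (rmy - r_xy * rxm) / (1 - rxm^2)
  ab <- r_xm * b_of(r_my, r_xm)
  # PSD of a 3x3 correlation matrix reduces to a nonnegative determinant
  det3 <- function(rxm, rmy)
    1 + 2 * rxm * r_xy * rmy - rxm^2 - r_xy^2 - rmy^2
  g <- seq(-0.999999, 0.999999, length.out = 400001)
  a_feas <- g[det3(g, r_my) >= -1e-12]
  a_max <- max(abs(a_feas[sign(a_feas) == sign(r_xm)]))
  b_feas <- g[det3(r_xm, g) >= -1e-12]
  b_vals <- b_of(b_feas, r_xm)
  b_max <- max(abs(b_vals[sign(b_vals) == sign(b_of(r_my, r_xm))]))
  ab / (a_max * b_max)
}

test_that("indirect, direct and total effects obey a*b + c' = c", {
  for (seed in c(1, 2, 3)) {
    d <- chain_cohort(n = 50, seed = seed, b_noise = 10, m_noise = 0.6)
    cs <- causal_steps(d, "x", "m", "y", covariates = "age")
    est <- setNames(cs$paths$estimate, cs$paths$path)
    expect_equal(est[["a"]] * est[["b"]] + est[["c_prime"]], est[["c"]],
                 tolerance = 1e-10)
  }
})

test_that("causal-steps verdicts on constructed cohorts", {
  # mediator unrelated to the outcome given x: no mediation
  set.seed(4)
  d <- chain_cohort(n = 120, seed = 4)
  d$m <- rnorm(120) # breaks the x -> m link
  expect_equal(causal_steps(d, "x", "m", "y", "age")$verdict, "none")
  # outcome carried entirely by the mediator: total mediation
  d2 <- chain_cohort(n = 120, seed = 5, b_noise = 0.5, m_noise = 0.8)
  cs2 <- causal_steps(d2, "x", "m", "y", "age")
  expect_equal(cs2$verdict, "total")
  cp <- cs2$paths[cs2$paths$path == "c_prime", ]
  expect_gt(cp$p, 0.05)
})

test_that("bootstrap indirect effect: point estimate free of B, seeded runs
           bit-identical, null CI covers 0", {
  d <- chain_cohort(n = 60, seed = 6, b_noise = 6, m_noise = 0.8)
  b1 <- bootstrap_mediated_effect(d, "x", "m", "y", "age", B = 100,
                                  seed = 1)
  b2 <- bootstrap_mediated_effect(d, "x", "m", "y", "age", B = 200,
                                  seed = 2)
  expect_equal(b1$estimate, b2$estimate)
  b3 <- bootstrap_mediated_effect(d, "x", "m", "y", "age", B = 200,
                                  seed = 2)
  expect_identical(b2$boot, b3$boot)
  expect_identical(b2$ci, b3$ci)
  # x unrelated to m: indirect effect CI straddles zero
  set.seed(8)
  d0 <- data.frame(age = runif(200, 97, 119), x = rnorm(200))
  d0$m <- rnorm(200)
  d0$y <- 3 * d0$m + rnorm(200)
  b0 <- bootstrap_mediated_effect(d0, "x", "m", "y", "age", B = 400,
                                  seed = 3)
  expect_lt(b0$ci[1], 0)
  expect_gt(b0$ci[2], 0)
})

test_that("BCa endpoints are monotone in the confidence level and agree
           with the boot package on shared replicates", {
  skip_if_not_installed("boot")
  set.seed(9)
  x <- rexp(40) # skewed so bias correction and acceleration matter
  theta <- mean(x)
  bo <- boot::boot(x, function(d, i) mean(d[i]), R = 4000)
  jack <- vapply(seq_along(x), function(i) mean(x[-i]), numeric(1))
  mine <- bca_interval(theta, as.vector(bo$t), jack, level = 0.95)
  L <- (length(x) - 1) * (mean(jack) - jack)
  ref <- boot::boot.ci(bo, type = "bca", L = L)$bca[4:5]
  expect_equal(mine, ref, tolerance = 0.01)
  narrow <- bca_interval(theta, as.vector(bo$t), jack, level = 0.80)
  expect_gt(narrow[1], mine[1])
  expect_lt(narrow[2], mine[2])
})

test_that("kappa^2: zero effect, suppression-free maximum, oracle match", {
  # exactly orthogonal x and m: no indirect effect, kappa^2 = 0
  set.seed(10)
  d <- data.frame(age = runif(50, 97, 119), x = rnorm(50), m = rnorm(50),
                  y = rnorm(50))
  d$m <- residuals(lm(m ~ x, d))
  k0 <- kappa_squared(d, "x", "m", "y", character(0), B = 100, seed = 1)
  expect_equal(k0$estimate, 0, tolerance = 1e-10)
  # configuration where both paths sit at their admissible maxima
  vars <- c("x", "m", "y")
  Rstar <- matrix(c(1, 0.7, 0, 0.7, 1, 0.7, 0, 0.7, 1), 3,
                  dimnames = list(vars, vars))
  mom <- cohort_moments(setNames(c(0, 0, 0), vars),
                        setNames(c(1, 1, 1), vars), Rstar, n = 60)
  dmax <- generate_cohort_moment_exact(mom, seed = 2)
  kmax <- kappa_squared(dmax, "x", "m", "y", character(0), B = 100,
                        seed = 3)
  expect_gt(kmax$estimate, 0.9)
  # near-deterministic causal chain x -> m -> y
  dchain <- chain_cohort(n = 100, seed = 11, b_noise = 0.3,
                         m_noise = 0.15)
  kchain <- kappa_squared(dchain, "x", "m", "y", "age", B = 100, seed = 4)
  expect_gt(kchain$estimate, 0.5)
  # component-wise grid oracle agrees with the analytic construction
  cohort <- ref_cohort(seed = 12)
  k <- kappa_squared(cohort, "C", "va_span", "reading_speed", "age",
                     B = 100, seed = 5)
  expect_equal(k$estimate,
               kappa2_oracle(cohort, "C", "va_span", "reading_speed",
                             "age"), tolerance = 1e-4)
  expect_true(abs(k$estimate) <= 1)
})

test_that("kappa^2 is invariant to linear rescaling; a*b rescales", {
  d <- chain_cohort(n = 80, seed = 13, b_noise = 4, m_noise = 0.7)
  k1 <- kappa_squared(d, "x", "m", "y", "age", B = 100, seed = 6)
  ab1 <- bootstrap_mediated_effect(d, "x", "m", "y", "age", B = 100,
                                   seed = 7)
  d2 <- d
  d2$x <- d$x * 3 + 5
  d2$m <- d$m / 4 - 1
  d2$y <- d$y * 10
  k2 <- kappa_squared(d2, "x", "m", "y", "age", B = 100, seed = 6)
  ab2 <- bootstrap_mediated_effect(d2, "x", "m", "y", "age", B = 100,
                                   seed = 7)
  expect_equal(k2$estimate, k1$estimate, tolerance = 1e-10)
  expect_equal(ab2$estimate, ab1$estimate * 10 / 3, tolerance = 1e-10)
})

test_that("zero-variance variables are rejected", {
  d <- data.frame(age = runif(20, 97, 119), x = rnorm(20), m = rnorm(20),
                  y = rep(1, 20))
  expect_error(kappa_squared(d, "x", "m", "y", "age", B = 100),
               "degenerate")
})
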