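test_that("correlation matrix: diagonal, orthogonal pairs, fixtures", {
  set.seed(1)
  n <- 40
  u <- rnorm(n)
  v <- rnorm(n)
  v <- residuals(lm(v ~ u)) # exactly orthogonal to u
  cm <- correlation_matrix(data.frame(u = u, v = v))
  expect_equal(unname(diag(cm$r)), c(1, 1))
  expect_equal(cm$r["u", "v"], 0, tolerance = 1e-12)
  cohort <- ref_cohort(seed = 5)
  mom <- reference_moments()
  cm2 <- correlation_matrix(cohort, mom$variables)
  expect_equal(round(cm2$r, 2), round(mom$corr, 2))
  # stars reproduce the .05/.01/.001 convention
  expect_equal(cm2$stars["va_span", "C"], "***")
  expect_equal(cm2$stars["age", "va_span"], "*")
})

test_that("zero-variance variables yield flagged NA correlations", {
  expect_warning(cm <- correlation_matrix(
    data.frame(a = rnorm(10), b = rep(1, 10))), "zero-variance")
  expect_true(is.na(cm$r["a", "b"]))
})

test_that("partial correlation equals the single-control closed form", {
  cohort <- ref_cohort(seed = 6)
  closed <- function(rxy, rxc, ryc)
    (rxy - rxc * ryc) / sqrt((1 - rxc^2) * (1 - ryc^2))
  R <- reference_moments()$corr
  pr <- partial_correlation(cohort, "va_span", "reading_speed", "age")
  expect_equal(pr$r,
               closed(R["va_span", "reading_speed"], R["va_span", "age"],
                      R["reading_speed", "age"]), tolerance = 1e-10)
  expect_equal(round(pr$r, 4), 0.5033)
  expect_lt(abs(pr$r - 0.51), 0.01)
})

test_that("partial correlation degenerate cases are flagged", {
  cohort <- ref_cohort(seed = 6)
  expect_warning(out <- partial_correlation(cohort, "age", "reading_speed",
                                            "age"), "controls")
  expect_true(is.na(out$r))
  # control uncorrelated with both leaves the full correlation intact
  set.seed(2)
  d <- data.frame(x = rnorm(50), y = rnorm(50), c = rnorm(50))
  d$c <- residuals(lm(c ~ x + y, d))
  expect_equal(partial_correlation(d, "x", "y", "c")$r, cor(d$x, d$y),
               tolerance = 1e-10)
})

test_that("OLS fit: identity regression and matrix closed form", {
  d <- data.frame(x = rnorm(20))
  d$y <- d$x
  fit <- suppressWarnings(ols_fit(d, "y", "x")) # perfect fit by design
  expect_equal(fit$r.squared, 1)
  expect_equal(fit$coefficients$estimate[2], 1)
  # standardized coefficients equal solve(R) %*% r on moment-exact data
  cohort <- ref_cohort(seed = 7)
  R <- reference_moments()$corr
  preds <- c("age", "C", "K")
  beta <- solve(R[preds, preds], R[preds, "va_span"])
  fit2 <- ols_fit(cohort, "va_span", preds)
  expect_equal(fit2$coefficients$std_estimate[-1], unname(beta),
               tolerance = 1e-8)
})

test_that("OLS invariants: orthogonal residuals, scale-free std coefs,
           noise predictors never hurt R2", {
  cohort <- ref_cohort(seed = 8)
  fit <- ols_fit(cohort, "reading_speed", c("age", "va_span"))
  X <- model.matrix(fit$model)
  expect_lt(max(abs(crossprod(X, fit$residuals))), 1e-8)
  rescaled <- cohort
  rescaled$age <- rescaled$age * 12
  rescaled$va_span <- rescaled$va_span / 5
  fit2 <- ols_fit(rescaled, "reading_speed", c("age", "va_span"))
  expect_equal(fit2$coefficients$std_estimate,
               fit$coefficients$std_estimate, tolerance = 1e-10)
  set.seed(3)
  cohort$noise <- rnorm(nrow(cohort))
  fit3 <- ols_fit(cohort, "reading_speed", c("age", "va_span", "noise"))
  expect_gte(fit3$r.squared, fit$r.squared)
})

test_that("rank-deficient designs name the collinear column", {
  cohort <- ref_cohort(seed = 9)
  cohort$C2 <- 2 * cohort$C
  expect_error(ols_fit(cohort, "reading_speed", c("C", "C2")), "C2")
})

test_that("partial-regression residual pairs reproduce the coefficient", {
  cohort <- ref_cohort(seed = 10)
  fit <- ols_fit(cohort, "va_span", c("age", "C", "K"))
  pr <- fit$partial_residuals$C
  slope <- coef(lm(y_resid ~ x_resid, pr))[["x_resid"]]
  expect_equal(slope,
               fit$coefficients$estimate[fit$coefficients$term == "C"],
               tolerance = 1e-10)
})

test_that("R2 from a correlation matrix matches OLS and known cases", {
  R <- reference_moments()$corr
  expect_equal(r2_from_correlations(R, "reading_speed", "va_span"),
               R["va_span", "reading_speed"]^2)
  cohort <- ref_cohort(seed = 11)
  for (spec in list(list(y = "va_span", x = c("age", "C", "K")),
                    list(y = "reading_speed", x = c("age", "va_span")),
                    list(y = "reading_speed", x = c("age", "C", "K")))) {
    expect_equal(r2_from_correlations(R, spec$y, spec$x),
                 ols_fit(cohort, spec$y, spec$x)$r.squared,
                 tolerance = 1e-10)
  }
  # predictors uncorrelated with the response explain nothing
  vars <- c("y", "p1", "p2")
  R0 <- diag(3)
  R0[2, 3] <- R0[3, 2] <- 0.4
  dimnames(R0) <- list(vars, vars)
  expect_equal(r2_from_correlations(R0, "y", c("p1", "p2")), 0)
})
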