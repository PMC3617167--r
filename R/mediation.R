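#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' The bias correction z0 is the normal quantile of the fraction of
#' bootstrap replicates below the point estimate (ties counted half); the
#' acceleration is estimated from the skewness of leave-one-out jackknife
#' values. Both adjust the percentile endpoints of the bootstrap
#' distribution.
#'
#' @param theta_hat Point estimate on the original sample.
#' @param boot Numeric vector of bootstrap replicate estimates (NAs
#'   dropped).
#' @param jack Numeric vector of leave-one-out jackknife estimates.
#' @param level Confidence level (default 0.95).
#' @return Length-2 vector (lower, upper).
#' @export
bca_interval <- function(theta_hat, boot, jack, level = 0.95) {
  boot <- boot[!is.na(boot)]
  B <- length(boot)
  stopifnot(B >= 10, level > 0, level < 1)
  if (stats::sd(boot) == 0) return(c(theta_hat, theta_hat))
  prop <- (sum(boot < theta_hat) + 0.5 * sum(boot == theta_hat)) / B
  prop <- min(max(prop, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(prop)
  jm <- mean(jack) - jack
  denom <- sum(jm^2)^1.5
  a <- if (denom < 1e-30) 0 else sum(jm^3) / (6 * denom)
  alpha <- (1 - level) / 2
  adj <- function(z_alpha) {
    stats::pnorm(z0 + (z0 + z_alpha) / (1 - a * (z0 + z_alpha)))
  }
  probs <- c(adj(stats::qnorm(alpha)), adj(stats::qnorm(1 - alpha)))
  unname(stats::quantile(boot, probs, names = FALSE))
}

# a*b on an index subset of the cohort; NA when a resample is degenerate
indirect_from_rows <- function(Xa, mvec, Xb, yvec, rows) {
  fa <- stats::lm.fit(Xa[rows, , drop = FALSE], mvec[rows])
  fb <- stats::lm.fit(Xb[rows, , drop = FALSE], yvec[rows])
  if (fa$rank < ncol(Xa) || fb$rank < ncol(Xb)) return(NA_real_)
  unname(fa$coefficients[ncol(Xa)] * fb$coefficients[ncol(Xb)])
}

mediation_design <- function(cohort, x, m, y, covariates) {
  stopifnot(all(c(x, m, y, covariates) %in% names(cohort)))
  covs <- if (length(covariates))
    as.matrix(cohort[covariates]) else NULL
  Xa <- cbind(`(Intercept)` = 1, covs, cohort[[x]])
  colnames(Xa)[ncol(Xa)] <- x
  Xb <- cbind(Xa, cohort[[m]])
  colnames(Xb)[ncol(Xb)] <- m
  list(Xa = Xa, Xb = Xb, mvec = cohort[[m]], yvec = cohort[[y]])
}

#' Causal-steps mediation analysis
#'
#' Fits the three regressions of the causal-steps approach, each with the
#' covariates included: the total-effect model y ~ covariates + x (path
#' c), the mediator model m ~ covariates + x (path a), and the full model
#' y ~ covariates + x + m (paths b and c'). Mediation is declared
#' "total" when c, a and b are significant but the direct path c' is not;
#' "partial" when all four are significant; "none" when any of c, a, b
#' fails significance.
#'
#' @param cohort Data frame.
#' @param x,m,y Names of the independent, mediator and dependent
#'   variables.
#' @param covariates Covariates added to every model (e.g. age).
#' @param alpha Two-sided significance level for the verdict (default
#'   0.05).
#' @return Object of class \code{"mediation_result"}: \code{paths} data
#'   frame (path, estimate, se, t, p for a, b, c, c'), \code{indirect}
#'   (a*b), \code{verdict}, \code{models} (the three
#'   \code{\link{ols_fit}} objects), \code{alpha}.
#' @examples
#' cohort <- generate_cohort_moment_exact(reference_moments(), seed = 1)
#' causal_steps(cohort, x = "C", m = "va_span", y = "reading_speed",
#'              covariates = "age")
#' @export
causal_steps <- function(cohort, x, m, y, covariates = character(),
                         alpha = 0.05) {
  total <- ols_fit(cohort, y, c(covariates, x))
  mediator <- ols_fit(cohort, m, c(covariates, x))
  full <- ols_fit(cohort, y, c(covariates, x, m))
  pick <- function(fit, term) {
    row <- fit$coefficients[fit$coefficients$term == term, ]
    data.frame(estimate = row$estimate, se = row$se, t = row$t, p = row$p)
  }
  paths <- rbind(
    cbind(path = "a", pick(mediator, x)),
    cbind(path = "b", pick(full, m)),
    cbind(path = "c", pick(total, x)),
    cbind(path = "c_prime", pick(full, x)))
  sig <- stats::setNames(paths$p < alpha, paths$path)
  verdict <- if (!(sig[["a"]] && sig[["b"]] && sig[["c"]])) "none"
  else if (!sig[["c_prime"]]) "total" else "partial"
  structure(list(paths = paths,
                 indirect = paths$estimate[paths$path == "a"] *
                   paths$estimate[paths$path == "b"],
                 verdict = verdict,
                 models = list(total = total, mediator = mediator,
                               full = full),
                 x = x, m = m, y = y, covariates = covariates,
                 alpha = alpha),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation of", x$x, "on", x$y, "through", x$m)
  if (length(x$covariates))
    cat(" (covariates:", paste(x$covariates, collapse = ", "), ")")
  cat("\n")
  printed <- x$paths
  printed[-1] <- lapply(printed[-1], signif, 4)
  print(printed, row.names = FALSE)
  cat(sprintf("indirect effect a*b = %.4f; causal-steps verdict: %s\n",
              x$indirect, x$verdict))
  invisible(x)
}

#' Bootstrap estimate of the indirect (mediated) effect
#'
#' Resamples whole rows of the cohort with replacement, recomputes the
#' product of paths a and b for each resample, and forms a BCa confidence
#' interval. The point estimate comes from the original sample and does
#' not depend on B. Degenerate (rank-deficient) resamples are dropped and
#' counted.
#'
#' @inheritParams causal_steps
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed; results are bit-reproducible given it.
#' @param level Confidence level (default 0.95).
#' @return List with \code{estimate} (a*b), \code{ci} (BCa bounds),
#'   \code{boot} (replicates), \code{n_dropped}, \code{level}, \code{B}.
#' @export
bootstrap_mediated_effect <- function(cohort, x, m, y,
                                      covariates = character(),
                                      B = 1000L, seed = NULL,
                                      level = 0.95) {
  n <- nrow(cohort)
  stopifnot(n >= 10, B >= 100)
  d <- mediation_design(cohort, x, m, y, covariates)
  est <- indirect_from_rows(d$Xa, d$mvec, d$Xb, d$yvec, seq_len(n))
  if (is.na(est)) stop("rank-deficient design on the original sample")
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(B), function(b)
    indirect_from_rows(d$Xa, d$mvec, d$Xb, d$yvec,
                       sample.int(n, n, replace = TRUE)), numeric(1))
  jack <- vapply(seq_len(n), function(i)
    indirect_from_rows(d$Xa, d$mvec, d$Xb, d$yvec, setdiff(seq_len(n), i)),
    numeric(1))
  list(estimate = est, ci = bca_interval(est, boot, jack, level),
       boot = boot, n_dropped = sum(is.na(boot)), level = level, B = B)
}

# kappa^2 on covariate-residualized data: scale-free, so computed in
# correlation space (the SD ratios in a, b and their maxima cancel)
kappa2_from_correlations <- function(r_xm, r_xy, r_my) {
  if (1 - r_xm^2 < 1e-12 || 1 - r_xy^2 < 1e-12) return(NA_real_)
  ab <- r_xm * (r_my - r_xy * r_xm) / (1 - r_xm^2)
  if (ab == 0) return(0)
  a_sign <- sign(r_xm)
  a_max <- abs(r_xy * r_my + a_sign *
                 sqrt((1 - r_xy^2) * (1 - r_my^2)))
  b_max <- sqrt((1 - r_xy^2) / (1 - r_xm^2))
  if (a_max * b_max < 1e-12) return(NA_real_)
  ab / (a_max * b_max)
}

kappa2_point <- function(cohort, x, m, y, covariates) {
  rx <- residualize(cohort, x, covariates)
  rm_ <- residualize(cohort, m, covariates)
  ry <- residualize(cohort, y, covariates)
  kappa2_from_correlations(stats::cor(rx, rm_), stats::cor(rx, ry),
                           stats::cor(rm_, ry))
}

#' Kappa-squared effect size of a mediated effect
#'
#' The observed indirect effect a*b divided by the maximum indirect
#' effect attainable given the data: following Preacher and Kelley's
#' construction, |a| is maximized holding the variances and the two
#' correlations not involving path a fixed, |b| likewise, each subject to
#' the implied covariance matrix remaining positive semi-definite, and
#' the maxima take the sign of the observed paths. kappa^2 lies in
#' [-1, 1] (its sign follows the observed effect) and is invariant to
#' linear rescaling of x, m and y. Covariates are partialled out of x, m
#' and y before the construction. The confidence interval is BCa over
#' case-resampling bootstrap replicates.
#'
#' @inheritParams bootstrap_mediated_effect
#' @return List with \code{estimate}, \code{ci}, \code{boot},
#'   \code{level}, \code{B}.
#' @examples
#' cohort <- generate_cohort_moment_exact(reference_moments(), seed = 1)
#' kappa_squared(cohort, "C", "va_span", "reading_speed", "age",
#'               B = 200, seed = 2)$estimate # about 0.22
#' @export
kappa_squared <- function(cohort, x, m, y, covariates = character(),
                          B = 1000L, seed = NULL, level = 0.95) {
  n <- nrow(cohort)
  stopifnot(n >= 10, B >= 100)
  sds <- vapply(cohort[c(x, m, y)], stats::sd, numeric(1))
  if (any(sds == 0)) stop("degenerate (zero-variance) variable")
  est <- kappa2_point(cohort, x, m, y, covariates)
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(B), function(b) {
    rows <- sample.int(n, n, replace = TRUE)
    tryCatch(kappa2_point(cohort[rows, , drop = FALSE], x, m, y,
                          covariates),
             error = function(e) NA_real_)
  }, numeric(1))
  jack <- vapply(seq_len(n), function(i)
    kappa2_point(cohort[-i, , drop = FALSE], x, m, y, covariates),
    numeric(1))
  list(estimate = est, ci = bca_interval(est, boot, jack, level),
       boot = boot, level = level, B = B)
}

#' Full mediation analysis: causal steps, bootstrap a*b and kappa^2
#'
#' Convenience wrapper combining \code{\link{causal_steps}},
#' \code{\link{bootstrap_mediated_effect}} and
#' \code{\link{kappa_squared}} on the same model.
#'
#' @inheritParams bootstrap_mediated_effect
#' @param alpha Significance level for the causal-steps verdict.
#' @return A \code{"mediation_result"} augmented with
#'   \code{indirect_ci}, \code{kappa2}, \code{kappa2_ci} and \code{B}.
#' @export
mediation_analysis <- function(cohort, x, m, y, covariates = character(),
                               B = 1000L, seed = NULL, alpha = 0.05,
                               level = 0.95) {
  steps <- causal_steps(cohort, x, m, y, covariates, alpha)
  ab <- bootstrap_mediated_effect(cohort, x, m, y, covariates, B = B,
                                  seed = seed, level = level)
  k2 <- kappa_squared(cohort, x, m, y, covariates, B = B,
                      seed = if (is.null(seed)) NULL else seed + 1L,
                      level = level)
  steps$indirect_ci <- ab$ci
  steps$kappa2 <- k2$estimate
  steps$kappa2_ci <- k2$ci
  steps$B <- B
  steps
}
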