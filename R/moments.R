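#' Summary moments describing a cohort
#'
#' Container for the first and second sample moments of a set of cohort
#' variables: means, standard deviations, the correlation matrix and the
#' sample size. Every regression and mediation quantity in this package is
#' a function of these moments, so a cohort table with exactly these
#' moments (see \code{\link{generate_cohort_moment_exact}}) reproduces the
#' corresponding analyses.
#'
#' @param means Named numeric vector of variable means.
#' @param sds Named numeric vector of standard deviations (> 0), same
#'   names/order as \code{means}.
#' @param corr Correlation matrix (symmetric, unit diagonal, positive
#'   semi-definite), dimnames matching the variables.
#' @param n Sample size.
#' @param ci Optional 2-column matrix of 95% CI bounds per variable.
#' @param range Optional 2-column matrix of observed ranges per variable.
#' @return An object of class \code{"cohort_moments"}.
#' @export
cohort_moments <- function(means, sds, corr, n, ci = NULL, range = NULL) {
  vars <- names(means)
  stopifnot(!is.null(vars), length(sds) == length(means),
            all(names(sds) == vars), all(sds > 0),
            is.matrix(corr), nrow(corr) == length(vars),
            all(rownames(corr) == vars), all(colnames(corr) == vars),
            n > 1)
  if (max(abs(corr - t(corr))) > 1e-8) stop("correlation matrix not symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-8) stop("correlation diagonal must be 1")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation matrix is not positive semi-definite ",
         "(smallest eigenvalue ", signif(min(ev), 3),
         "); consider clipping negative eigenvalues and renormalizing")
  structure(list(variables = vars, means = means, sds = sds, corr = corr,
                 n = as.integer(n), ci = ci, range = range),
            class = "cohort_moments")
}

#' @export
print.cohort_moments <- function(x, ...) {
  cat("Cohort moments (n = ", x$n, ")\n", sep = "")
  print(data.frame(mean = x$means, sd = round(x$sds, 3)))
  cat("Correlations:\n")
  print(round(x$corr, 2))
  invisible(x)
}

#' Recover a standard deviation from a reported 95% confidence interval
#'
#' Published descriptive tables often print a mean with its 95% CI rather
#' than the SD. For a normal-theory interval, SD =
#' (half-width) * sqrt(n) / z(0.975). A t-based interval (method
#' \code{"t"}) uses the t quantile instead, shrinking the result by a few
#' percent at moderate n.
#'
#' @param mean Reported mean (unused in the computation; kept for a
#'   self-documenting call signature).
#' @param ci_low,ci_high Interval bounds.
#' @param n Sample size (> 1).
#' @param method "normal" (default) or "t".
#' @return The implied standard deviation; 0 with a warning for a
#'   zero-width interval.
#' @examples
#' sd_from_ci(80, 74, 86, 47) # 20.99
#' @export
sd_from_ci <- function(mean, ci_low, ci_high, n, method = c("normal", "t")) {
  method <- match.arg(method)
  stopifnot(ci_low <= ci_high, n > 1)
  if (ci_high == ci_low) {
    warning("zero-width confidence interval implies SD 0")
    return(0)
  }
  q <- if (method == "normal") stats::qnorm(0.975) else
    stats::qt(0.975, df = n - 1)
  ((ci_high - ci_low) / 2) * sqrt(n) / q
}

#' Reference cohort moments for 8-9 year-old readers (n = 47)
#'
#' The package's built-in calibration target: descriptive moments (means,
#' 95% CIs, observed ranges) and the full correlation matrix for age
#' (months), VA span (letters), visual processing speed C (elements/s),
#' VSTM capacity K (elements) and text reading speed (words/minute) in a
#' screened cohort of 47 eight-to-nine-year-old children. SDs are derived
#' from the CIs with \code{\link{sd_from_ci}}.
#'
#' @param ci_method Passed to \code{\link{sd_from_ci}}.
#' @return A \code{\link{cohort_moments}} object.
#' @examples
#' reference_moments()
#' @export
reference_moments <- function(ci_method = "normal") {
  mfile <- system.file("extdata", "cohort_moments.csv", package = "vaspan",
                       mustWork = TRUE)
  cfile <- system.file("extdata", "cohort_correlations.csv",
                       package = "vaspan", mustWork = TRUE)
  moments_from_files(mfile, cfile, n = 47L, ci_method = ci_method)
}

#' Build cohort moments from descriptive and correlation tables
#'
#' @param moments_file CSV with columns variable, mean, ci_low, ci_high
#'   and optionally range_low, range_high.
#' @param correlations_file CSV square correlation matrix with a leading
#'   `variable` column.
#' @param n Sample size the CIs refer to.
#' @param ci_method Passed to \code{\link{sd_from_ci}}.
#' @return A \code{\link{cohort_moments}} object.
#' @export
moments_from_files <- function(moments_file, correlations_file, n,
                               ci_method = "normal") {
  m <- utils::read.csv(moments_file, stringsAsFactors = FALSE)
  stopifnot(all(c("variable", "mean", "ci_low", "ci_high") %in% names(m)))
  cm <- utils::read.csv(correlations_file, stringsAsFactors = FALSE)
  corr <- as.matrix(cm[, -1, drop = FALSE])
  rownames(corr) <- cm$variable
  corr <- corr[m$variable, m$variable]
  means <- stats::setNames(m$mean, m$variable)
  sds <- stats::setNames(
    mapply(sd_from_ci, m$mean, m$ci_low, m$ci_high,
           MoreArgs = list(n = n, method = ci_method)),
    m$variable)
  ci <- cbind(low = m$ci_low, high = m$ci_high)
  rownames(ci) <- m$variable
  rng <- NULL
  if (all(c("range_low", "range_high") %in% names(m))) {
    rng <- cbind(low = m$range_low, high = m$range_high)
    rownames(rng) <- m$variable
  }
  cohort_moments(means, sds, corr, n, ci = ci, range = rng)
}
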