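#' Pairwise Pearson correlation matrix with p values
#'
#' @param cohort Data frame of observations.
#' @param variables Columns to correlate (>= 2); needs at least 3 rows.
#' @return Object of class \code{"correlation_matrix"}: list with
#'   \code{r} (correlations), \code{p} (two-sided p values from the t
#'   transform on n - 2 df), \code{stars} (significance codes at
#'   .05/.01/.001), \code{n}. Zero-variance variables give NA entries
#'   with a warning.
#' @export
correlation_matrix <- function(cohort, variables = names(cohort)) {
  X <- as.matrix(cohort[variables])
  n <- nrow(X)
  stopifnot(n >= 3)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance variable(s): ",
            paste(variables[sds == 0], collapse = ", "),
            "; correlations undefined (NA)")
    X[, sds == 0] <- NA_real_
  }
  r <- suppressWarnings(stats::cor(X))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  stars <- matrix(significance_stars(p), nrow(p), ncol(p),
                  dimnames = dimnames(p))
  structure(list(r = r, p = p, stars = stars, n = n),
            class = "correlation_matrix")
}

significance_stars <- function(p) {
  out <- rep("", length(p))
  out[!is.na(p) & p < .05] <- "*"
  out[!is.na(p) & p < .01] <- "**"
  out[!is.na(p) & p < .001] <- "***"
  out
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat("Pearson correlations (n = ", x$n, "):\n", sep = "")
  shown <- matrix(paste0(format(round(x$r, digits)), x$stars),
                  nrow(x$r), dimnames = dimnames(x$r))
  print(shown, quote = FALSE)
  invisible(x)
}

#' Partial correlation controlling for covariates
#'
#' Correlation between the residuals of \code{x} and \code{y} after each
#' is regressed (with intercept) on the control variables. For a single
#' control c it equals
#' \code{(r_xy - r_xc * r_yc) / sqrt((1 - r_xc^2) * (1 - r_yc^2))}.
#'
#' @param cohort Data frame.
#' @param x,y Variable names.
#' @param controls Character vector of control variable names.
#' @return List with \code{r}, two-sided \code{p} (t transform on
#'   n - 2 - length(controls) df) and \code{n}. Degenerate cases (x or y
#'   perfectly explained by the controls, or x among the controls) give
#'   \code{r = NA} with a warning.
#' @export
partial_correlation <- function(cohort, x, y, controls) {
  stopifnot(nrow(cohort) >= 4, all(c(x, y, controls) %in% names(cohort)))
  if (x %in% controls || y %in% controls) {
    warning("variable appears among its own controls; undefined")
    return(list(r = NA_real_, p = NA_real_, n = nrow(cohort)))
  }
  rx <- residualize(cohort, x, controls)
  ry <- residualize(cohort, y, controls)
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12) {
    warning("a variable is collinear with the controls; undefined")
    return(list(r = NA_real_, p = NA_real_, n = nrow(cohort)))
  }
  r <- stats::cor(rx, ry)
  df <- nrow(cohort) - 2L - length(controls)
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = df), n = nrow(cohort))
}

residualize <- function(cohort, var, controls) {
  if (!length(controls)) return(cohort[[var]] - mean(cohort[[var]]))
  f <- stats::reformulate(controls, response = var)
  stats::resid(stats::lm(f, data = cohort))
}

#' Ordinary least-squares fit with partial-regression diagnostics
#'
#' Wraps \code{stats::lm} (intercept always included) and augments the
#' summary with standardized coefficients and, per predictor, the
#' partial-regression residual pair (response and predictor each
#' residualized on the remaining predictors) used for added-variable
#' plots.
#'
#' @param cohort Data frame.
#' @param response Response variable name.
#' @param predictors Character vector of predictor names.
#' @return Object of class \code{"ols_fit"}: list with
#'   \code{coefficients} (term, estimate, std_estimate, se, t, p),
#'   \code{r.squared}, \code{fstatistic} (value, df1, df2, p),
#'   \code{residuals}, \code{fitted}, \code{partial_residuals} (named
#'   list of data frames with columns x_resid, y_resid), \code{model}
#'   (the lm object), \code{n}.
#' @export
ols_fit <- function(cohort, response, predictors) {
  stopifnot(all(c(response, predictors) %in% names(cohort)))
  f <- stats::reformulate(predictors, response = response)
  fit <- stats::lm(f, data = cohort)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  s <- summary(fit)
  coefs <- as.data.frame(s$coefficients)
  names(coefs) <- c("estimate", "se", "t", "p")
  coefs <- cbind(term = rownames(coefs), coefs)
  rownames(coefs) <- NULL
  sy <- stats::sd(cohort[[response]])
  coefs$std_estimate <- NA_real_
  for (v in predictors)
    coefs$std_estimate[coefs$term == v] <-
      coefs$estimate[coefs$term == v] * stats::sd(cohort[[v]]) / sy
  coefs <- coefs[c("term", "estimate", "std_estimate", "se", "t", "p")]

  fs <- s$fstatistic
  fstat <- if (is.null(fs)) NULL else
    list(value = unname(fs[1]), df1 = unname(fs[2]), df2 = unname(fs[3]),
         p = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))

  partial <- stats::setNames(lapply(predictors, function(v) {
    others <- setdiff(predictors, v)
    data.frame(x_resid = residualize(cohort, v, others),
               y_resid = residualize(cohort, response, others))
  }), predictors)

  structure(list(coefficients = coefs, r.squared = s$r.squared,
                 fstatistic = fstat, residuals = stats::resid(fit),
                 fitted = stats::fitted(fit),
                 partial_residuals = partial, model = fit,
                 response = response, predictors = predictors,
                 n = nrow(cohort)),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(x$response, "~", paste(x$predictors, collapse = " + "),
      sprintf(" (n = %d)\n", x$n))
  printed <- x$coefficients
  printed[-1] <- lapply(printed[-1], signif, 4)
  print(printed, row.names = FALSE)
  if (!is.null(x$fstatistic))
    cat(sprintf("R^2 = %.3f, F(%d, %d) = %.2f, p = %.2g\n", x$r.squared,
                x$fstatistic$df1, x$fstatistic$df2, x$fstatistic$value,
                x$fstatistic$p))
  invisible(x)
}

#' R-squared of a regression from a correlation matrix
#'
#' Multiple R^2 of \code{response} on \code{predictors} implied by a
#' correlation matrix: \code{t(r) %*% solve(R) %*% r} with r the
#' response-predictor correlations and R the predictor intercorrelations.
#' Agrees with \code{\link{ols_fit}} on any cohort having those sample
#' moments, which lets published correlation tables reproduce published
#' regressions without raw data.
#'
#' @param corr Correlation matrix with dimnames.
#' @param response Response variable name.
#' @param predictors Predictor names.
#' @return R^2.
#' @examples
#' r2_from_correlations(reference_moments()$corr, "reading_speed",
#'                      c("age", "va_span")) # 0.373
#' @export
r2_from_correlations <- function(corr, response, predictors) {
  stopifnot(all(c(response, predictors) %in% rownames(corr)))
  R <- corr[predictors, predictors, drop = FALSE]
  r <- corr[predictors, response]
  if (rcond(R) < 1e-12) stop("singular predictor correlation matrix")
  drop(crossprod(r, solve(R, r)))
}
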