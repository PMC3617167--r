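#' Univariate z-score outlier screen
#'
#' Computes each child's z-score on every screened variable, using that
#' variable's sample mean and SD over the full input cohort (a single
#' pass: the candidate is included in its own reference moments, and
#' excluded children are not removed before computing others' scores). A
#' child is excluded when any |z| exceeds the threshold.
#'
#' @param cohort Data frame with one row per child, including a
#'   \code{child_id} column and the screened variables.
#' @param variables Variables screened (default: the four experimental
#'   measures reading speed, VA span, C and K).
#' @param z_threshold Exclusion threshold on |z| (default 2.5).
#' @param freeze_moments Optional list with elements \code{means} and
#'   \code{sds} (named by variable) to reuse moments from an earlier pass
#'   instead of re-estimating; makes repeated screening idempotent.
#' @return List with \code{kept} and \code{excluded} (cohort subsets) and
#'   \code{report}, a data frame with one row per offending
#'   (child, variable) pair (child_id, variable, value, z). Zero-variance
#'   variables are skipped with a warning. Also returns \code{moments}
#'   (the means/sds used), suitable for \code{freeze_moments}.
#' @export
zscore_outlier_screen <- function(cohort,
                                  variables = c("reading_speed", "va_span",
                                                "C", "K"),
                                  z_threshold = 2.5,
                                  freeze_moments = NULL) {
  stopifnot(z_threshold > 0, nrow(cohort) >= 3)
  missing <- setdiff(variables, names(cohort))
  if (length(missing))
    stop("screened variable(s) absent from cohort: ",
         paste(missing, collapse = ", "))
  if (is.null(freeze_moments)) {
    means <- vapply(cohort[variables], mean, numeric(1))
    sds <- vapply(cohort[variables], stats::sd, numeric(1))
  } else {
    means <- freeze_moments$means[variables]
    sds <- freeze_moments$sds[variables]
  }
  report <- data.frame(child_id = cohort$child_id[0],
                       variable = character(0), value = numeric(0),
                       z = numeric(0))
  flagged <- rep(FALSE, nrow(cohort))
  for (v in variables) {
    if (is.na(sds[v]) || sds[v] == 0) {
      warning("variable '", v, "' has zero variance; skipped by the screen")
      next
    }
    z <- (cohort[[v]] - means[v]) / sds[v]
    hit <- abs(z) > z_threshold
    if (any(hit)) {
      report <- rbind(report, data.frame(
        child_id = cohort$child_id[hit], variable = v,
        value = cohort[[v]][hit], z = z[hit]))
      flagged <- flagged | hit
    }
  }
  list(kept = cohort[!flagged, , drop = FALSE],
       excluded = cohort[flagged, , drop = FALSE],
       report = report,
       moments = list(means = means, sds = sds))
}

#' Fit-quality screen on TVA fits
#'
#' Children whose fit-quality correlation (empirical vs fitted mean
#' scores, \code{\link{fit_quality}}) is not strictly above the threshold
#' are excluded; a fit exactly at the threshold is excluded.
#'
#' @param cohort Data frame with \code{child_id} and the fit-quality
#'   column.
#' @param r_column Name of the fit-quality column (default "fit_r").
#' @param threshold Minimum acceptable r, exclusive (default 0.75).
#' @return List with \code{kept}, \code{excluded} and \code{report}
#'   (child_id, r for each exclusion).
#' @export
fit_quality_screen <- function(cohort, r_column = "fit_r",
                               threshold = 0.75) {
  stopifnot(threshold > 0, r_column %in% names(cohort))
  r <- cohort[[r_column]]
  drop <- is.na(r) | r <= threshold
  list(kept = cohort[!drop, , drop = FALSE],
       excluded = cohort[drop, , drop = FALSE],
       report = data.frame(child_id = cohort$child_id[drop], r = r[drop]))
}
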