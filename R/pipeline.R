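#' Read whole-report trials from CSV
#'
#' Expects a comma-separated file with header columns \code{child_id},
#' \code{display_size}, \code{exposure_ms}, \code{masked} (0/1) and
#' \code{score}. Exposures are converted from milliseconds (the file
#' unit) to seconds (the internal unit). Malformed rows are reported with
#' their file line numbers.
#'
#' @param path File path.
#' @return Trial data frame (\code{child_id}, \code{display_size},
#'   \code{exposure} in seconds, \code{masked} logical, \code{score}).
#' @export
read_trials <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("child_id", "display_size", "exposure_ms", "masked", "score")
  missing <- setdiff(needed, names(raw))
  if (length(missing))
    stop("trials file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  if (!nrow(raw))
    return(data.frame(child_id = integer(0), display_size = integer(0),
                      exposure = numeric(0), masked = logical(0),
                      score = integer(0)))
  line <- seq_len(nrow(raw)) + 1L # header is line 1
  numeric_cols <- c("display_size", "exposure_ms", "masked", "score")
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals))
    if (length(bad))
      stop("non-numeric '", col, "' in ", path, " at line(s): ",
           paste(utils::head(line[bad], 10L), collapse = ", "))
    raw[[col]] <- vals
  }
  bad <- which(raw$score < 0 | raw$score > raw$display_size)
  if (length(bad))
    stop("score outside [0, display_size] in ", path, " at line(s): ",
         paste(utils::head(line[bad], 10L), collapse = ", "))
  bad <- which(raw$exposure_ms <= 0)
  if (length(bad))
    stop("non-positive exposure in ", path, " at line(s): ",
         paste(utils::head(line[bad], 10L), collapse = ", "))
  bad <- which(!raw$masked %in% c(0, 1))
  if (length(bad))
    stop("masked flag must be 0 or 1 in ", path, " at line(s): ",
         paste(utils::head(line[bad], 10L), collapse = ", "))
  data.frame(child_id = raw$child_id,
             display_size = as.integer(raw$display_size),
             exposure = raw$exposure_ms / 1000,
             masked = raw$masked == 1,
             score = as.integer(raw$score))
}

#' Write whole-report trials to CSV
#'
#' Inverse of \code{\link{read_trials}}: exposures are written in
#' milliseconds, the mask flag as 0/1.
#'
#' @param trials Trial data frame with internal (seconds) units.
#' @param path Output file path.
#' @export
write_trials <- function(trials, path) {
  check_trials(trials)
  out <- data.frame(child_id = trials$child_id,
                    display_size = trials$display_size,
                    exposure_ms = trials$exposure * 1000,
                    masked = as.integer(trials$masked),
                    score = trials$score)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-child cohort table from CSV
#'
#' Requires \code{child_id}, \code{age} (months), \code{va_span}
#' (letters) and \code{reading_speed} (words/minute); extra columns (for
#' example a precomputed reading-age eligibility flag) pass through
#' unchanged.
#'
#' @param path File path.
#' @return Cohort data frame.
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("child_id", "age", "va_span", "reading_speed")
  missing <- setdiff(needed, names(cohort))
  if (length(missing))
    stop("cohort file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  cohort
}

#' @rdname read_cohort
#' @param cohort Cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

descriptives_table <- function(cohort, variables) {
  n <- nrow(cohort)
  rows <- lapply(variables, function(v) {
    xv <- cohort[[v]]
    half <- stats::qnorm(0.975) * stats::sd(xv) / sqrt(n)
    data.frame(variable = v, mean = mean(xv), sd = stats::sd(xv),
               ci_low = mean(xv) - half, ci_high = mean(xv) + half,
               min = min(xv), max = max(xv))
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (one of three modes), TVA fitting
#' (trial-data modes), screening, descriptives, correlations and partial
#' correlations, the three regression models (VA span ~ age + C + K;
#' reading speed ~ age + VA span; reading speed ~ age + C + K) and the
#' mediation analysis of C on reading speed through VA span with age as
#' covariate. Deterministic given the seed, which is fanned out to the
#' stages by fixed offsets.
#'
#' The configuration is a named list (or path to a YAML file with the
#' same keys) selecting exactly one input mode:
#' \describe{
#'   \item{\code{trials_file} + \code{cohort_file}}{CSV paths; TVA
#'     parameters are fitted per child from the trials and merged into
#'     the cohort.}
#'   \item{\code{structural}}{List of
#'     \code{\link{generate_cohort_structural}} arguments
#'     (\code{n_children}, optional \code{config} overrides); trials are
#'     simulated and then fitted.}
#'   \item{\code{moments}}{\code{TRUE} for the built-in reference
#'     moments, or a list with \code{moments_file},
#'     \code{correlations_file}, \code{n}; the cohort is generated
#'     moment-exactly (within the outlier screen, \code{max_abs_z}
#'     default 2.45) and the fitting stage is skipped.}
#' }
#' Other keys: \code{seed} (default 1), \code{B} (bootstrap resamples,
#' default 1000), \code{fit_trials} (set \code{FALSE} in structural mode
#' to analyse true generating parameters instead of refitted ones),
#' \code{z_threshold} (2.5), \code{fit_r_threshold} (0.75),
#' \code{out_dir} (when set, the JSON report, text rendering and
#' exclusion log are written there).
#'
#' @param config Named list or path to a YAML config file.
#' @return Object of class \code{"analysis_report"}.
#' @export
run_pipeline <- function(config = list(moments = TRUE)) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  B <- if (is.null(config$B)) 1000L else as.integer(config$B)
  zthr <- if (is.null(config$z_threshold)) 2.5 else config$z_threshold
  rthr <- if (is.null(config$fit_r_threshold)) 0.75 else
    config$fit_r_threshold
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  stage <- "input"
  report <- tryCatch({
    fits_skipped <- FALSE
    if (!is.null(config$trials_file)) {
      say("stage input: reading %s", config$trials_file)
      trials <- read_trials(config$trials_file)
      cohort <- read_cohort(config$cohort_file)
    } else if (!is.null(config$structural)) {
      say("stage input: structural simulation (seed %d)", seed)
      sc <- config$structural
      gen <- generate_cohort_structural(
        n_children = sc$n_children, seed = seed + 101L,
        config = if (is.null(sc$config)) list() else sc$config)
      cohort <- gen$cohort
      trials <- gen$trials
      if (identical(config$fit_trials, FALSE)) {
        trials <- NULL
        fits_skipped <- TRUE
      }
    } else if (!is.null(config$moments)) {
      say("stage input: moment-exact cohort (seed %d)", seed)
      mom <- if (isTRUE(config$moments)) reference_moments() else
        moments_from_files(config$moments$moments_file,
                           config$moments$correlations_file,
                           n = config$moments$n)
      maz <- if (is.null(config$max_abs_z)) 2.45 else config$max_abs_z
      cohort <- generate_cohort_moment_exact(mom, seed = seed + 202L,
                                             max_abs_z = maz)
      trials <- NULL
      fits_skipped <- TRUE
    } else stop("config selects no input mode")

    if (!fits_skipped) {
      stage <- "tva_fit"
      ids <- unique(trials$child_id)
      say("stage tva_fit: fitting %d children", length(ids))
      fits <- lapply(ids, function(id)
        fit_tva(trials[trials$child_id == id, , drop = FALSE]))
      fit_tab <- data.frame(
        child_id = ids,
        C = vapply(fits, function(f) f$params$C, numeric(1)),
        K = vapply(fits, function(f) f$params$K, numeric(1)),
        t0 = vapply(fits, function(f) f$params$t0, numeric(1)),
        mu = vapply(fits, function(f) f$params$mu, numeric(1)),
        fit_r = vapply(fits, function(f) f$r, numeric(1)))
      cohort <- merge(cohort[setdiff(names(cohort),
                                     c("C", "K", "t0", "mu", "fit_r"))],
                      fit_tab, by = "child_id")
      say("stage tva_fit: mean fit quality r = %.3f (Fisher z)",
          average_fit_quality(fit_tab$fit_r))
    }

    stage <- "screening"
    screen_log <- list()
    if ("fit_r" %in% names(cohort)) {
      fq <- fit_quality_screen(cohort, threshold = rthr)
      screen_log$fit_quality <- fq$report
      say("stage screening: fit quality excluded %d of %d",
          nrow(fq$excluded), nrow(cohort))
      cohort <- fq$kept
    }
    zs <- zscore_outlier_screen(cohort, z_threshold = zthr)
    screen_log$zscore <- zs$report
    say("stage screening: |z| > %.1f excluded %d of %d", zthr,
        nrow(zs$excluded), nrow(cohort))
    cohort <- zs$kept

    stage <- "descriptives"
    vars <- c("age", "va_span", "C", "K", "reading_speed")
    desc <- descriptives_table(cohort, vars)

    stage <- "correlations"
    cors <- correlation_matrix(cohort, vars)
    pvars <- setdiff(vars, "age")
    partial <- matrix(NA_real_, length(pvars), length(pvars),
                      dimnames = list(pvars, pvars))
    for (i in seq_along(pvars)) for (j in seq_along(pvars)) {
      if (i == j) { partial[i, j] <- 1; next }
      partial[i, j] <- partial_correlation(cohort, pvars[i], pvars[j],
                                           "age")$r
    }

    stage <- "regression"
    say("stage regression: models 1-3")
    models <- list(
      va_span = ols_fit(cohort, "va_span", c("age", "C", "K")),
      reading_va = ols_fit(cohort, "reading_speed", c("age", "va_span")),
      reading_tva = ols_fit(cohort, "reading_speed", c("age", "C", "K")))

    stage <- "mediation"
    say("stage mediation: C -> va_span -> reading_speed | age (B = %d)", B)
    med <- mediation_analysis(cohort, x = "C", m = "va_span",
                              y = "reading_speed", covariates = "age",
                              B = B, seed = seed + 303L)

    structure(list(
      descriptives = desc,
      correlations = cors,
      partial_correlations = partial,
      models = models,
      mediation = med,
      screening = screen_log,
      cohort = cohort,
      provenance = list(seed = seed, B = B,
                        package_version =
                          as.character(utils::packageVersion("vaspan")),
                        config = config),
      log = log_lines), class = "analysis_report")
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

report_to_list <- function(report) {
  med <- report$mediation
  list(
    descriptives = report$descriptives,
    correlations = report$correlations$r,
    correlation_p = report$correlations$p,
    partial_correlations = report$partial_correlations,
    models = lapply(report$models, function(m) list(
      response = m$response, predictors = m$predictors,
      coefficients = m$coefficients, r_squared = m$r.squared,
      f = m$fstatistic)),
    mediation = list(paths = med$paths, indirect = med$indirect,
                     indirect_ci = med$indirect_ci,
                     kappa2 = med$kappa2, kappa2_ci = med$kappa2_ci,
                     verdict = med$verdict, alpha = med$alpha,
                     B = med$B),
    screening = report$screening,
    provenance = report$provenance)
}

#' Write an analysis report to disk
#'
#' Writes \code{report.json} (full precision) and \code{report.txt}
#' (human-readable, 4 significant digits) plus the exclusion log to a
#' directory.
#'
#' @param report An \code{"analysis_report"} from
#'   \code{\link{run_pipeline}}.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(report_to_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       matrix = "rowmajor", pretty = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  scr <- do.call(rbind, lapply(names(report$screening), function(nm) {
    r <- report$screening[[nm]]
    if (!nrow(r)) return(NULL)
    data.frame(rule = nm, r)
  }))
  if (!is.null(scr))
    utils::write.csv(scr, file.path(dir, "exclusions.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Cohort descriptives (n = ", nrow(x$cohort), ") ==\n", sep = "")
  printed <- x$descriptives
  printed[-1] <- lapply(printed[-1], signif, 4)
  print(printed, row.names = FALSE)
  cat("\n== Correlations ==\n")
  print(x$correlations)
  cat("\nPartial correlations controlling for age:\n")
  print(round(x$partial_correlations, 2))
  cat("\n== Regression models ==\n")
  for (m in x$models) { print(m); cat("\n") }
  cat("== Mediation ==\n")
  print(x$mediation)
  cat(sprintf("a*b 95%% BCa CI: [%.3f, %.3f]; kappa^2 = %.3f [%.3f, %.3f]\n",
              x$mediation$indirect_ci[1], x$mediation$indirect_ci[2],
              x$mediation$kappa2, x$mediation$kappa2_ci[1],
              x$mediation$kappa2_ci[2]))
  invisible(x)
}
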