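#' Analytic single-letter identification threshold
#'
#' The whole-report design anchors each child's shortest exposure D_min at
#' the 50% accuracy threshold for identifying a single peripheral letter.
#' Under the race model a lone letter receives the full rate C on a masked
#' trial, so the exposure at which it is encoded with probability one half
#' is \code{t0 + log(2)/C}. This closed form replaces an adaptive
#' staircase: the analysis only consumes the staircase's output.
#'
#' @param params A \code{\link{tva_params}} object.
#' @return Threshold exposure in seconds.
#' @examples
#' d_min_analytic(tva_params(C = 24, K = 4, t0 = 0.004)) # 0.0329 s
#' @export
d_min_analytic <- function(params) {
  params$t0 + log(2) / params$C
}

#' The 10-condition whole-report exposure design
#'
#' Two display sizes (3 and 6 letters) crossed with five exposure cells:
#' D_min masked and unmasked, D_min + 70 ms masked, and 200 ms masked and
#' unmasked.
#'
#' @param d_min Per-child minimum exposure in seconds.
#' @param trials_per_condition Trials per condition cell (default 15).
#' @return Data frame with columns \code{display_size}, \code{exposure}
#'   (s), \code{masked}, \code{n_trials}.
#' @export
exposure_design <- function(d_min, trials_per_condition = 15L) {
  stopifnot(d_min > 0, d_min + 0.070 < 0.200)
  cells <- data.frame(
    exposure = c(d_min, d_min, d_min + 0.070, 0.200, 0.200),
    masked = c(TRUE, FALSE, TRUE, TRUE, FALSE))
  out <- merge(data.frame(display_size = c(3L, 6L)), cells)
  out$n_trials <- as.integer(trials_per_condition)
  out[order(out$display_size, out$exposure, out$masked), ]
}

#' Simulate one observer's whole-report session
#'
#' Runs the race simulator over the 10-condition design for one parameter
#' set.
#'
#' @param params A \code{\link{tva_params}} object.
#' @param d_min Minimum exposure (seconds); defaults to the analytic 50%
#'   threshold \code{\link{d_min_analytic}}.
#' @param trials_per_condition Trials per condition (default 15).
#' @param seed Optional integer seed.
#' @param child_id Identifier stamped on the records.
#' @return Trial data frame (\code{child_id}, \code{display_size},
#'   \code{exposure}, \code{masked}, \code{score}).
#' @export
simulate_study_trials <- function(params, d_min = NULL,
                                  trials_per_condition = 15L, seed = NULL,
                                  child_id = 1L) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(d_min)) d_min <- d_min_analytic(params)
  des <- exposure_design(d_min, trials_per_condition)
  recs <- lapply(seq_len(nrow(des)), function(i) {
    cond <- display_condition(des$display_size[i], des$exposure[i],
                              des$masked[i])
    data.frame(child_id = child_id,
               display_size = des$display_size[i],
               exposure = des$exposure[i],
               masked = des$masked[i],
               score = simulate_trials(cond, params, des$n_trials[i]))
  })
  do.call(rbind, recs)
}

#' Simulate a VA-span score
#'
#' Mean letters reported over \code{n_trials} whole-report trials of a
#' five-letter string shown unmasked for 200 ms (identity scoring,
#' maximum 5). The horizontal-string task benefits from perceptual
#' specialization for print that the circular-array parameters do not
#' capture; \code{task_bonus} adds that many effective VSTM slots for this
#' task only (default 1, calibrated so a cohort with typical circular-array
#' C and K reproduces the observed span of about 4.1 letters).
#'
#' @param params A \code{\link{tva_params}} object (circular-array values).
#' @param n_trials Number of trials averaged (default 20).
#' @param task_bonus Extra effective capacity (elements) for the
#'   horizontal-string task.
#' @param seed Optional integer seed.
#' @return Mean correct reports per trial, in [0, 5].
#' @export
simulate_va_span <- function(params, n_trials = 20L, task_bonus = 1,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eff <- tva_params(C = params$C, K = min(5, params$K + task_bonus),
                    t0 = params$t0, mu = params$mu)
  cond <- display_condition(5L, 0.200, masked = FALSE)
  mean(simulate_trials(cond, eff, n_trials))
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

#' Default configuration of the structural cohort generator
#'
#' Distributions are calibrated to the reference cohort: C ~ N(24.6, 7.2)
#' truncated above 5 el/s; K ~ N(3.6, 0.5) truncated to [1, 6]; t0 ~
#' |N(0, 8 ms)|; mu ~ N(184, 60 ms) truncated above 0; age ~ U(97, 119)
#' months. A shared standard-normal latent factor with loadings
#' \code{lambda_C}, \code{lambda_K} induces the C-K correlation. Reading
#' speed is generated from the mediation structure, reading speed =
#' beta0 + beta_age * age + beta_va * VA span + noise, so that full
#' mediation of C on reading speed through VA span holds by construction.
#'
#' @return Named list of generator settings; override any element via the
#'   \code{config} argument of \code{\link{generate_cohort_structural}}.
#' @export
structural_defaults <- function() {
  list(C_mean = 24.6, C_sd = 7.2, C_min = 5,
       K_mean = 3.6, K_sd = 0.5, K_range = c(1, 6),
       t0_sd = 0.008,
       mu_mean = 0.184, mu_sd = 0.060, mu_min = 0.001,
       age_range = c(97, 119),
       lambda_C = 0.7, lambda_K = 0.7,
       beta0 = -84, beta_age = 0.8, beta_va = 19.0, noise_sd = 17,
       va_trials = 20L, va_task_bonus = 1,
       trials_per_condition = 15L,
       d_min_jitter = 0.2)
}

#' Generate a structural synthetic cohort with trial-level data
#'
#' Draws per-child TVA parameters, derives each child's minimum exposure
#' from the analytic 50% threshold (with multiplicative jitter mimicking
#' staircase noise, rounded to the 10 ms monitor frame and clamped to
#' [20, 130] ms), simulates the full 10-condition whole-report session and
#' the 20-trial VA-span task through the race model, and generates reading
#' speed from age and VA span (see \code{\link{structural_defaults}}).
#'
#' @param n_children Number of children.
#' @param seed Integer seed; the run is fully reproducible given it.
#' @param config Named list overriding \code{\link{structural_defaults}}.
#' @return List with \code{cohort} (child_id, age, true C/K/t0/mu, d_min,
#'   va_span, reading_speed) and \code{trials} (one row per whole-report
#'   trial).
#' @examples
#' g <- generate_cohort_structural(3, seed = 1)
#' head(g$cohort)
#' @export
generate_cohort_structural <- function(n_children, seed = NULL,
                                       config = list()) {
  cfg <- structural_defaults()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop("unknown generator setting(s): ", paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  stopifnot(n_children >= 0, cfg$C_sd > 0, cfg$K_sd > 0,
            abs(cfg$lambda_C) <= 1, abs(cfg$lambda_K) <= 1)
  if (!is.null(seed)) set.seed(seed)
  empty_cohort <- data.frame(child_id = integer(0), age = numeric(0),
                             C = numeric(0), K = numeric(0),
                             t0 = numeric(0), mu = numeric(0),
                             d_min = numeric(0), va_span = numeric(0),
                             reading_speed = numeric(0))
  if (n_children == 0)
    return(list(cohort = empty_cohort,
                trials = data.frame(child_id = integer(0),
                                    display_size = integer(0),
                                    exposure = numeric(0),
                                    masked = logical(0),
                                    score = integer(0))))

  z <- stats::rnorm(n_children)
  draw_loaded <- function(lambda, mean, sd, lower, upper) {
    x <- mean + sd * (lambda * z +
                        sqrt(1 - lambda^2) * stats::rnorm(n_children))
    bad <- which(x < lower | x > upper)
    while (length(bad)) { # redraw only the idiosyncratic part
      x[bad] <- mean + sd * (lambda * z[bad] +
                               sqrt(1 - lambda^2) * stats::rnorm(length(bad)))
      bad <- which(x < lower | x > upper)
    }
    x
  }
  C <- draw_loaded(cfg$lambda_C, cfg$C_mean, cfg$C_sd, cfg$C_min, Inf)
  K <- draw_loaded(cfg$lambda_K, cfg$K_mean, cfg$K_sd,
                   cfg$K_range[1], cfg$K_range[2])
  t0 <- abs(stats::rnorm(n_children, 0, cfg$t0_sd))
  mu <- rnorm_trunc(n_children, cfg$mu_mean, cfg$mu_sd, lower = cfg$mu_min)
  age <- stats::runif(n_children, cfg$age_range[1], cfg$age_range[2])

  cohort <- empty_cohort[0, ]
  trials <- vector("list", n_children)
  va_span <- d_min <- numeric(n_children)
  for (i in seq_len(n_children)) {
    p <- tva_params(C[i], K[i], t0[i], mu[i])
    dm <- d_min_analytic(p) *
      stats::runif(1, 1 - cfg$d_min_jitter, 1 + cfg$d_min_jitter)
    dm <- min(max(round(dm, 2), 0.02), 0.12) # 10 ms frames, staircase range
    d_min[i] <- dm
    trials[[i]] <- simulate_study_trials(
      p, d_min = dm, trials_per_condition = cfg$trials_per_condition,
      child_id = i)
    va_span[i] <- simulate_va_span(p, n_trials = cfg$va_trials,
                                   task_bonus = cfg$va_task_bonus)
  }
  reading_speed <- cfg$beta0 + cfg$beta_age * age + cfg$beta_va * va_span +
    stats::rnorm(n_children, 0, cfg$noise_sd)
  list(cohort = data.frame(child_id = seq_len(n_children), age = age,
                           C = C, K = K, t0 = t0, mu = mu, d_min = d_min,
                           va_span = va_span,
                           reading_speed = reading_speed),
       trials = do.call(rbind, trials))
}

#' Generate a cohort whose sample moments match targets exactly
#'
#' Produces an n-row table whose sample means, sample SDs (n - 1
#' denominator) and sample correlation matrix equal the targets to
#' machine precision: a random Gaussian basis is drawn, column-centred and
#' whitened against its own sample covariance, then coloured by the
#' Cholesky factor of the target correlation and rescaled. The seed only
#' rotates individual rows; the moments are identical for every seed, so
#' any statistic that is a function of first and second moments is
#' reproduced exactly.
#'
#' @param moments A \code{\link{cohort_moments}} object (its correlation
#'   matrix must be positive definite; near-singular targets are
#'   rejected).
#' @param n Number of rows (default \code{moments$n}); must exceed the
#'   number of variables.
#' @param seed Integer seed for the random rotation.
#' @param max_abs_z Optional cap on the largest within-sample |z| score;
#'   rotation seeds are advanced deterministically until every value fits
#'   (useful for building cohorts that pass an outlier screen untouched).
#' @return Data frame with a \code{child_id} column plus one column per
#'   variable.
#' @examples
#' cohort <- generate_cohort_moment_exact(reference_moments(), seed = 1)
#' round(cor(cohort$C, cohort$reading_speed), 10) # 0.5 exactly
#' @export
generate_cohort_moment_exact <- function(moments, n = moments$n,
                                         seed = NULL, max_abs_z = NULL) {
  stopifnot(inherits(moments, "cohort_moments"))
  p <- length(moments$variables)
  if (n <= p) stop("need n > number of variables for exact moments")
  L <- tryCatch(chol(moments$corr), error = function(e)
    stop("target correlation matrix is not positive definite; ",
         "clip negative eigenvalues and renormalize before retrying"))
  base_seed <- if (is.null(seed)) sample.int(1e6, 1) else seed
  for (try in 0:499) {
    set.seed(base_seed + try)
    Z <- matrix(stats::rnorm(n * p), n, p)
    Zc <- scale(Z, center = TRUE, scale = FALSE)
    S <- crossprod(Zc) / (n - 1)
    Y <- Zc %*% solve(chol(S)) # exact identity sample covariance
    X <- Y %*% L
    if (!is.null(max_abs_z) && max(abs(X)) > max_abs_z) next
    X <- sweep(X, 2, moments$sds, `*`)
    X <- sweep(X, 2, moments$means, `+`)
    colnames(X) <- moments$variables
    return(cbind(data.frame(child_id = seq_len(n)), as.data.frame(X)))
  }
  stop("no rotation found with max |z| <= ", max_abs_z,
       " in 500 attempts; relax max_abs_z")
}
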