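# Validate a trial table (one or more children). Canonical trial columns:
# child_id, display_size, exposure (seconds), masked (logical), score.
check_trials <- function(trials) {
  needed <- c("display_size", "exposure", "masked", "score")
  missing <- setdiff(needed, names(trials))
  if (length(missing))
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(trials)) {
    bad <- which(trials$score < 0 | trials$score > trials$display_size)
    if (length(bad))
      stop("score exceeds display size (or is negative) in row(s): ",
           paste(utils::head(bad, 10L), collapse = ", "))
    if (any(trials$exposure <= 0)) stop("exposures must be positive")
  }
  invisible(trials)
}

# Collapse trials to per-condition score counts; one row per
# (display_size, exposure, masked, score).
condition_counts <- function(trials) {
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(trials))),
    by = list(display_size = trials$display_size,
              exposure = trials$exposure,
              masked = trials$masked,
              score = trials$score),
    FUN = length)
  agg[order(agg$display_size, agg$exposure, agg$masked, agg$score), ,
      drop = FALSE]
}

#' Negative log-likelihood of TVA parameters for a set of trials
#'
#' Sums \code{-log P(score | condition, params)} over trials, with the
#' score probabilities from \code{\link{score_distribution}}. Additive over
#' any partition of the trials. Returns \code{Inf} when any observed score
#' has model probability zero (e.g. a score above \code{ceiling(K)}),
#' which signals an infeasible parameter region to the optimizer.
#'
#' @param params A \code{\link{tva_params}} object.
#' @param trials Data frame with columns \code{display_size},
#'   \code{exposure} (seconds), \code{masked}, \code{score}.
#' @return Scalar negative log-likelihood (0 for an empty trial list).
#' @export
tva_neg_loglik <- function(params, trials) {
  check_trials(trials)
  if (!nrow(trials)) return(0)
  cc <- condition_counts(trials)
  conds <- unique(cc[c("display_size", "exposure", "masked")])
  nll <- 0
  for (i in seq_len(nrow(conds))) {
    sel <- cc$display_size == conds$display_size[i] &
      cc$exposure == conds$exposure[i] & cc$masked == conds$masked[i]
    probs <- score_distribution(
      display_condition(conds$display_size[i], conds$exposure[i],
                        conds$masked[i]), params)
    p <- probs[cc$score[sel] + 1L]
    if (any(p <= 0)) return(Inf)
    nll <- nll - sum(cc$count[sel] * log(p))
  }
  unname(nll)
}

# map between the bounded parameter box and an unconstrained scale
to_unconstrained <- function(par, lo, hi) {
  stats::qlogis(pmin(pmax((par - lo) / (hi - lo), 1e-6), 1 - 1e-6))
}
from_unconstrained <- function(z, lo, hi) lo + (hi - lo) * stats::plogis(z)

#' Fit TVA parameters by maximum likelihood
#'
#' Minimizes \code{\link{tva_neg_loglik}} over (C, K, t0, mu) with a
#' Nelder-Mead simplex run from a fixed multi-start grid inside the
#' parameter box, keeping the best converged start. Deterministic for
#' given trials and configuration.
#'
#' Default bounds: C in [1, 200] el/s, K in (max score - 1, max display
#' size], t0 in [0, shortest exposure], mu in [0, 1 s]; child cohorts sit
#' comfortably inside these.
#'
#' @param trials Trial table for one observer (see
#'   \code{\link{tva_neg_loglik}}); must span at least two distinct
#'   effective exposures, otherwise C and t0 are not identifiable.
#' @param bounds Optional named list overriding any of \code{C}, \code{K},
#'   \code{t0}, \code{mu}, each a length-2 numeric (lower, upper).
#' @param starts Optional list of \code{\link{tva_params}} start points;
#'   by default a 3 x 3 x 2 x 2 grid over the box.
#' @param maxit Simplex iteration cap per start.
#' @return An object of class \code{"tva_fit"}: list with elements
#'   \code{params} (the estimate), \code{logLik}, \code{conditions}
#'   (per-condition empirical vs fitted mean scores), \code{r} (fit
#'   quality, see \code{\link{fit_quality}}), \code{converged},
#'   \code{identifiable}, \code{n_trials}.
#' @examples
#' truth <- tva_params(C = 24.6, K = 3.6, t0 = 0.004, mu = 0.184)
#' trials <- simulate_study_trials(truth, trials_per_condition = 15, seed = 1)
#' fit <- fit_tva(trials)
#' fit$params
#' @export
fit_tva <- function(trials, bounds = NULL, starts = NULL, maxit = 400L) {
  check_trials(trials)
  if (!nrow(trials)) stop("no trials to fit")
  # effective-exposure cells: masked status changes effective exposure
  cells <- unique(trials[c("exposure", "masked")])
  if (nrow(cells) < 2L)
    stop("trials span a single effective exposure; C and t0 are not identifiable")

  smax <- max(trials$score)
  nmax <- max(trials$display_size)
  b <- list(C = c(1, 200),
            K = c(max(0.5, smax - 1 + 1e-3), nmax),
            t0 = c(0, min(trials$exposure)),
            mu = c(0, 1))
  if (!is.null(bounds)) b[names(bounds)] <- bounds
  lo <- c(b$C[1], b$K[1], b$t0[1], b$mu[1])
  hi <- c(b$C[2], b$K[2], b$t0[2], b$mu[2])
  if (b$K[1] >= b$K[2]) { # cap saturated: pin K at the top of the box
    lo[2] <- hi[2] - 1e-6
  }

  cc <- condition_counts(trials)
  conds <- unique(cc[c("display_size", "exposure", "masked")])
  idx <- lapply(seq_len(nrow(conds)), function(i)
    which(cc$display_size == conds$display_size[i] &
            cc$exposure == conds$exposure[i] &
            cc$masked == conds$masked[i]))

  # flat per-condition views for a tight likelihood loop
  cond_n <- conds$display_size
  cond_expo <- conds$exposure
  cond_masked <- conds$masked
  cond_scores <- lapply(idx, function(ii) cc$score[ii] + 1L)
  cond_counts <- lapply(idx, function(ii) cc$count[ii])

  nll_z <- function(z) {
    par <- from_unconstrained(z, lo, hi)
    C <- par[1]; K <- par[2]; t0 <- par[3]; mu <- par[4]
    k_lo <- floor(K); gamma <- K - k_lo
    val <- 0
    for (i in seq_along(cond_n)) {
      tau <- cond_expo[i] - t0
      if (tau > 0 && !cond_masked[i]) tau <- tau + mu
      n <- cond_n[i]
      pe <- if (tau <= 0) 0 else -expm1(-(C / n) * tau)
      probs <- score_dist_integer_cap(n, pe, k_lo)
      if (gamma > 0)
        probs <- (1 - gamma) * probs +
          gamma * score_dist_integer_cap(n, pe, k_lo + 1L)
      p <- probs[cond_scores[[i]]]
      if (any(p <= 0)) return(1e10)
      val <- val - sum(cond_counts[[i]] * log(p))
    }
    val
  }

  if (is.null(starts)) {
    frac <- function(f) lo + f * (hi - lo)
    grid <- expand.grid(C = c(8, 20, 45),
                        Kf = c(0.3, 0.55, 0.8),
                        t0f = c(0.05, 0.4),
                        muf = c(0.12, 0.3))
    starts <- lapply(seq_len(nrow(grid)), function(i) c(
      grid$C[i],
      lo[2] + grid$Kf[i] * (hi[2] - lo[2]),
      lo[3] + grid$t0f[i] * (hi[3] - lo[3]),
      grid$muf[i]))
  } else {
    starts <- lapply(starts, function(s) c(s$C, s$K, s$t0, s$mu))
  }

  best <- NULL
  for (s in starts) {
    z0 <- to_unconstrained(pmin(pmax(s, lo), hi), lo, hi)
    opt <- stats::optim(z0, nll_z, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-9))
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  par <- from_unconstrained(best$par, lo, hi)
  est <- tva_params(C = par[1], K = par[2], t0 = par[3], mu = par[4])

  conds$empirical <- vapply(seq_len(nrow(conds)), function(i) {
    sel <- idx[[i]]
    sum(cc$score[sel] * cc$count[sel]) / sum(cc$count[sel])
  }, numeric(1))
  conds$fitted <- vapply(seq_len(nrow(conds)), function(i)
    expected_score(display_condition(conds$display_size[i],
                                     conds$exposure[i], conds$masked[i]),
                   est), numeric(1))
  rownames(conds) <- NULL

  identifiable <- !(smax == 0 || est$C <= lo[1] * 1.001)
  fit <- structure(list(
    params = est,
    logLik = -best$value,
    conditions = conds,
    converged = best$convergence == 0,
    identifiable = identifiable,
    n_trials = nrow(trials)), class = "tva_fit")
  fit$r <- fit_quality(fit)
  fit
}

#' @export
print.tva_fit <- function(x, ...) {
  cat("TVA maximum-likelihood fit (", x$n_trials, " trials, ",
      nrow(x$conditions), " conditions)\n", sep = "")
  print(x$params)
  cat(sprintf("logLik = %.3f, fit quality r = %.3f%s\n", x$logLik,
              if (is.na(x$r)) NA else x$r,
              if (!x$identifiable) " [not identifiable]" else ""))
  invisible(x)
}

#' Fit quality: empirical vs fitted mean scores
#'
#' Pearson correlation between the per-condition empirical mean scores and
#' the means implied by the fitted parameters. Individual fits with
#' r above 0.75 are conventionally deemed appropriate.
#'
#' @param fit A \code{"tva_fit"} object (needs >= 3 conditions).
#' @return Correlation in [-1, 1]; \code{NA} (with a warning) when the
#'   empirical means are constant across conditions.
#' @export
fit_quality <- function(fit) {
  conds <- fit$conditions
  if (nrow(conds) < 3L) stop("fit quality needs at least 3 conditions")
  if (stats::sd(conds$empirical) == 0 || stats::sd(conds$fitted) == 0) {
    warning("constant mean scores across conditions; fit quality undefined")
    return(NA_real_)
  }
  stats::cor(conds$empirical, conds$fitted)
}

#' Average correlation coefficients via Fisher's z
#'
#' Correlations are averaged on the variance-stabilized atanh scale and
#' transformed back. Values at |r| = 1 are clipped to 1 - 1e-7 (with a
#' warning) so the transform stays finite.
#'
#' @param rs Numeric vector of correlations in [-1, 1]; NAs are dropped.
#' @return The back-transformed mean correlation.
#' @examples
#' average_fit_quality(c(0.6, 0.9)) # 0.7842
#' @export
average_fit_quality <- function(rs) {
  rs <- rs[!is.na(rs)]
  stopifnot(all(abs(rs) <= 1))
  if (any(abs(rs) == 1)) {
    warning("correlation(s) at |r| = 1 clipped to 1 - 1e-7 before Fisher z")
    rs <- sign(rs) * pmin(abs(rs), 1 - 1e-7)
  }
  tanh(mean(atanh(rs)))
}

#' Bootstrap reliability of a TVA fit
#'
#' Refits the model to \code{B} resamples of the trials, drawn with
#' replacement within each condition cell (preserving the balanced
#' design), and summarizes the parameter distributions. Refits start from
#' the original estimate. Resamples whose refit fails are dropped and
#' counted.
#'
#' @inheritParams fit_tva
#' @param fit Optional \code{"tva_fit"} of the original data (computed if
#'   missing).
#' @param B Number of bootstrap resamples (500 is the conventional
#'   choice for reliability assessment).
#' @param seed Integer seed; results are reproducible given the seed.
#' @param maxit Simplex iteration cap per refit.
#' @return List with \code{samples} (B x 4 matrix of estimates), \code{sd}
#'   and \code{quantiles} (2.5/25/50/75/97.5%) per parameter, and
#'   \code{n_failed}.
#' @export
bootstrap_fit <- function(trials, fit = NULL, B = 500L, seed = NULL,
                          maxit = 200L) {
  check_trials(trials)
  if (is.null(fit)) fit <- fit_tva(trials)
  if (!is.null(seed)) set.seed(seed)
  pars <- c("C", "K", "t0", "mu")
  samples <- matrix(NA_real_, nrow = B, ncol = 4,
                    dimnames = list(NULL, pars))
  if (B == 0)
    return(list(samples = samples, sd = stats::setNames(numeric(4), pars),
                quantiles = NULL, n_failed = 0L))
  key <- interaction(trials$display_size, trials$exposure, trials$masked,
                     drop = TRUE)
  groups <- split(seq_len(nrow(trials)), key)
  n_failed <- 0L
  for (b in seq_len(B)) {
    rows <- unlist(lapply(groups, function(g)
      g[sample.int(length(g), length(g), replace = TRUE)]),
      use.names = FALSE)
    res <- tryCatch(
      fit_tva(trials[rows, , drop = FALSE], starts = list(fit$params),
              maxit = maxit),
      error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L
    else samples[b, ] <- unlist(res$params)
  }
  ok <- stats::complete.cases(samples)
  list(samples = samples,
       sd = apply(samples[ok, , drop = FALSE], 2, stats::sd),
       quantiles = apply(samples[ok, , drop = FALSE], 2, stats::quantile,
                         probs = c(0.025, 0.25, 0.5, 0.75, 0.975)),
       n_failed = n_failed)
}
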