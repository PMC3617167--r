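#' TVA parameter set for one observer
#'
#' Bundles the four parameters of the whole-report race model: visual
#' processing speed \code{C} (elements/second, shared equally among the
#' displayed elements), visual short-term memory capacity \code{K}
#' (elements, possibly fractional), perceptual threshold \code{t0}
#' (seconds; exposure below which nothing is encoded) and the iconic-memory
#' buffer \code{mu} (seconds of extra effective exposure on unmasked
#' trials).
#'
#' @param C Visual processing speed, elements per second. Must be > 0.
#' @param K VSTM storage capacity in elements; fractional values are
#'   interpreted as a Bernoulli mixture of the two adjacent integer
#'   capacities. Must be >= 0.
#' @param t0 Perceptual threshold in seconds. Must be >= 0.
#' @param mu Iconic-memory buffer in seconds. Must be >= 0.
#' @return An object of class \code{"tva_params"}.
#' @examples
#' tva_params(C = 24.6, K = 3.6, t0 = 0.004, mu = 0.184)
#' @export
tva_params <- function(C, K, t0 = 0, mu = 0) {
  stopifnot(is.numeric(C), length(C) == 1L, is.finite(C), C > 0,
            is.numeric(K), length(K) == 1L, is.finite(K), K >= 0,
            is.numeric(t0), length(t0) == 1L, is.finite(t0), t0 >= 0,
            is.numeric(mu), length(mu) == 1L, is.finite(mu), mu >= 0)
  structure(list(C = C, K = K, t0 = t0, mu = mu), class = "tva_params")
}

#' @export
print.tva_params <- function(x, ...) {
  cat(sprintf(
    "TVA parameters: C = %.2f el/s, K = %.2f el, t0 = %.1f ms, mu = %.1f ms\n",
    x$C, x$K, 1000 * x$t0, 1000 * x$mu))
  invisible(x)
}

#' Whole-report display condition
#'
#' @param n Display size (number of letters), a positive integer.
#' @param exposure Stimulus exposure duration in seconds (> 0).
#' @param masked Logical; was the display followed by a pattern mask?
#'   Unmasked displays gain prolonged effective exposure from visual
#'   persistence.
#' @return An object of class \code{"display_condition"}.
#' @examples
#' display_condition(n = 6, exposure = 0.2, masked = FALSE)
#' @export
display_condition <- function(n, exposure, masked) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == round(n),
            is.numeric(exposure), length(exposure) == 1L, exposure > 0,
            is.logical(masked), length(masked) == 1L, !is.na(masked))
  structure(list(n = as.integer(n), exposure = exposure, masked = masked),
            class = "display_condition")
}

#' Effective exposure duration
#'
#' Exposure above the perceptual threshold \code{t0}, extended by the
#' iconic-memory buffer \code{mu} on unmasked trials (the mask terminates
#' visual persistence, so masked trials get the physical exposure only).
#'
#' @param cond A \code{\link{display_condition}}.
#' @param params A \code{\link{tva_params}} object.
#' @return Effective exposure in seconds, never negative; exactly 0 when
#'   the exposure does not exceed \code{t0}.
#' @export
effective_exposure <- function(cond, params) {
  tau <- cond$exposure - params$t0
  if (tau <= 0) return(0)
  if (!cond$masked) tau <- tau + params$mu
  tau
}

#' Probability that one displayed element is encoded
#'
#' Each of the \code{n} displayed elements races at exponential rate
#' \code{C/n} (the total processing capacity is divided equally among
#' homogeneous letters); an element is encoded if its race finishes within
#' the effective exposure \code{tau}.
#'
#' @param n Display size (>= 1).
#' @param tau Effective exposure in seconds (>= 0).
#' @param params A \code{\link{tva_params}} object.
#' @return \code{1 - exp(-(C/n) * tau)}, in [0, 1).
#' @export
encoding_probability <- function(n, tau, params) {
  stopifnot(n >= 1, tau >= 0)
  -expm1(-(params$C / n) * tau)
}

# Distribution of the report score for a fixed integer VSTM cap k:
# F ~ Binomial(n, p) encodings; the first min(F, k) to finish are stored.
score_dist_integer_cap <- function(n, p, k) {
  probs <- stats::dbinom(0:n, n, p)
  if (k >= n) return(probs)
  out <- numeric(n + 1L)
  if (k > 0) out[seq_len(k)] <- probs[seq_len(k)]
  out[k + 1L] <- sum(probs[(k + 1L):(n + 1L)])
  out
}

#' Distribution of the whole-report score
#'
#' Probability of reporting 0..n letters correctly in one trial. Encoded
#' elements follow a Binomial(n, p) law with p from
#' \code{\link{encoding_probability}}; the VSTM store admits only the first
#' \code{K} finishers. A fractional capacity \code{K} is treated as a
#' per-trial mixture: capacity \code{ceiling(K)} with probability
#' \code{K - floor(K)}, else \code{floor(K)}.
#'
#' @inheritParams effective_exposure
#' @return Named numeric vector of probabilities for scores \code{0:n},
#'   summing to 1.
#' @examples
#' p <- tva_params(C = 30, K = 3, t0 = 0.010)
#' score_distribution(display_condition(6, 0.110, masked = TRUE), p)
#' @export
score_distribution <- function(cond, params) {
  n <- cond$n
  tau <- effective_exposure(cond, params)
  p <- encoding_probability(n, tau, params)
  k_lo <- floor(params$K)
  gamma <- params$K - k_lo
  probs <- score_dist_integer_cap(n, p, k_lo)
  if (gamma > 0) {
    probs <- (1 - gamma) * probs + gamma * score_dist_integer_cap(n, p, k_lo + 1)
  }
  names(probs) <- 0:n
  probs
}

#' Expected whole-report score
#'
#' Mean number of correctly reported letters for one condition: the
#' expectation of \code{\link{score_distribution}}. As exposure grows the
#' curve rises from 0 (at \code{t0}) with initial slope \code{C} towards
#' the asymptote \code{min(n, K)}; this exponential growth shape is what
#' the maximum-likelihood fit exploits.
#'
#' @inheritParams effective_exposure
#' @return Expected score (letters).
#' @export
expected_score <- function(cond, params) {
  probs <- score_distribution(cond, params)
  sum((0:cond$n) * probs)
}

#' Simulate whole-report trials by running the race
#'
#' Draws per-element exponential finishing times at rate \code{C/n};
#' elements finishing within the effective exposure occupy, in finishing
#' order, up to \code{cap} VSTM slots, where \code{cap} is drawn per trial
#' for fractional \code{K}. The reported score is the number of occupied
#' slots. This is the sampling counterpart of
#' \code{\link{score_distribution}} and is kept mechanistic (explicit race)
#' so it can serve as an independent check on the closed form.
#'
#' @inheritParams effective_exposure
#' @param n_trials Number of trials to simulate.
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of \code{n_trials} report scores.
#' @export
simulate_trials <- function(cond, params, n_trials, seed = NULL) {
  stopifnot(n_trials >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n_trials == 0) return(integer(0))
  n <- cond$n
  tau <- effective_exposure(cond, params)
  if (tau <= 0 || params$K == 0) return(integer(n_trials))
  # finishing times; only the count below tau matters for identity scoring,
  # the finishing order determines which letters are stored, not how many
  times <- matrix(stats::rexp(n_trials * n, rate = params$C / n),
                  nrow = n_trials)
  finished <- rowSums(times < tau)
  k_lo <- floor(params$K)
  gamma <- params$K - k_lo
  cap <- k_lo + if (gamma > 0) stats::rbinom(n_trials, 1L, gamma) else 0L
  as.integer(pmin(finished, cap))
}
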