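# shared fixtures: all built in code at test time

ref_cohort <- function(seed = 1, ...) {
  generate_cohort_moment_exact(reference_moments(), seed = seed, ...)
}

typical_params <- function() tva_params(C = 24.6, K = 3.6, t0 = 0.004,
                                        mu = 0.184)

# a small cohort with a known mediation structure x -> m -> y plus
# covariate, for constructed-case tests
chain_cohort <- function(n = 60, seed = 7, b_noise = 1, m_noise = 1) {
  set.seed(seed)
  age <- runif(n, 97, 119)
  x <- rnorm(n, 25, 7) + 0.1 * (age - 108)
  m <- 2 + 0.05 * x + m_noise * rnorm(n)
  y <- 10 + 8 * m + 0.3 * (age - 108) + b_noise * rnorm(n)
  data.frame(child_id = seq_len(n), age = age, x = x, m = m, y = y)
}
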