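# vaspan

Visual attention capacity, visual attention span and reading speed in
children: a complete, reproducible analysis pipeline.

## The problem

Eight-to-nine-year-old children differ widely in how fast they read.
One candidate bottleneck is visual: the number of letters that can be
processed in a single glance (the **visual attention span**, VA span —
mean letters reported from a five-consonant string flashed for 200 ms).
The Theory of Visual Attention (TVA) splits visual attention capacity
into two parameters estimated from a whole-report task: **visual
processing speed C** (elements/s) and **VSTM capacity K** (elements).
`vaspan` implements the whole chain that connects them to reading:

1. **Race model** (`score_distribution`, `expected_score`,
   `simulate_trials`): letters race in parallel at rate C/n; encoding is
   Binomial(n, 1 − e^(−(C/n)τ)) with effective exposure
   τ = max(0, D − t0) (+ µ if unmasked); the first K finishers are
   stored. Fractional K is a mixture of adjacent integer capacities.
2. **Maximum-likelihood fitting** (`fit_tva`) of (C, K, t0, µ) from
   trial-level report scores, with fit-quality screening (r > .75,
   Fisher-z averaging) and within-condition bootstrap reliability
   (`bootstrap_fit`).
3. **Synthetic cohorts** (`generate_cohort_structural`,
   `generate_cohort_moment_exact`): a structural generator that
   simulates every measured quantity through the race model, and a
   moment-exact generator whose sample means/SDs/correlations hit
   published targets to 1e-10 — so published summary tables reproduce
   published regressions exactly.
4. **Screening** (`zscore_outlier_screen`, `fit_quality_screen`): the
   |z| > 2.5 single-pass outlier rule on the four experimental measures.
5. **Association** (`correlation_matrix`, `partial_correlation`,
   `ols_fit`, `r2_from_correlations`): the three age-adjusted regression
   models.
6. **Mediation** (`causal_steps`, `bootstrap_mediated_effect`,
   `kappa_squared`): does VA span mediate the effect of C on reading
   speed? Causal steps, case-resampled bootstrap of a×b with 95% BCa
   intervals, and the κ² effect size (observed over maximum admissible
   indirect effect, age partialled).
7. **Pipeline** (`run_pipeline`, `read_trials`, `write_report`): CSV in
   (milliseconds on disk, seconds in memory), JSON + text report out,
   one seed, bit-reproducible. A thin CLI lives in
   `inst/scripts/vaspan-cli.R`.

## Worked example

Build the 47-child cohort that carries the reference summary moments
exactly, fit the VA-span model and run the mediation:

```r
library(vaspan)
cohort <- generate_cohort_moment_exact(reference_moments(), seed = 1)

ols_fit(cohort, "va_span", c("age", "C", "K"))
#> va_span ~ age + C + K  (n = 47)
#>         term estimate std_estimate       se      t         p
#>  (Intercept) 1.330000           NA 0.873500 1.5230 0.1351000
#>          age 0.004219      0.05625 0.007998 0.5275 0.6006000
#>            C 0.030160      0.41220 0.009102 3.3140 0.0018730
#>            K 0.436700      0.43670 0.116700 3.7430 0.0005346
#> R^2 = 0.586, F(3, 43) = 20.26, p = 2.5e-08

med <- mediation_analysis(cohort, "C", "va_span", "reading_speed",
                          covariates = "age", B = 1000, seed = 11)
med
#> Mediation of C on reading_speed through va_span (covariates: age )
#>     path estimate       se      t         p
#>        a  0.04772 0.008879 5.3750 2.772e-06
#>        b 15.70000 6.458000 2.4310 1.929e-02
#>        c  1.18700 0.401000 2.9610 4.928e-03
#>  c_prime  0.43810 0.489600 0.8949 3.758e-01
#> indirect effect a*b = 0.7493; causal-steps verdict: total
```

Reading the output: C and K together with age explain 59% of VA-span
variance (age itself contributes nothing once C and K are in the
model); an extra 10 elements/s of processing speed buys ~0.3 letters of
span, an extra memory slot ~0.44 letters. In the mediation, processing
speed predicts reading speed (path c, ~1.2 wpm per element/s), but once
VA span enters the model the direct path c′ collapses to
non-significance — total mediation, with indirect effect
a×b ≈ 0.75 wpm per element/s (95% BCa [0.21, 1.54]) and effect size
κ² ≈ 0.22 [0.07, 0.41].

Trial-level simulation and refitting:

```r
truth <- tva_params(C = 24.6, K = 3.6, t0 = 0.004, mu = 0.184)
trials <- simulate_study_trials(truth, trials_per_condition = 15, seed = 1)
fit_tva(trials)
#> TVA maximum-likelihood fit (150 trials, 10 conditions)
#> TVA parameters: C = 26.66 el/s, K = 3.56 el, t0 = 14.9 ms, mu = 189.7 ms
#> logLik = -146.814, fit quality r = 0.990
```

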