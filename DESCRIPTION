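Package: vaspan
Title: Visual Attention Capacity, Visual Attention Span and Reading Speed
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling whole-report letter identification with the
    Theory of Visual Attention (TVA): an exponential race model with visual
    processing speed C, visual short-term memory capacity K, perceptual
    threshold t0 and iconic-memory buffer mu; maximum-likelihood estimation
    of the four parameters from trial-level report scores with bootstrap
    reliability; visual attention span scoring; cohort screening;
    correlation, partial-correlation and regression analyses; and mediation
    analysis (causal steps, bootstrap BCa intervals for the indirect effect,
    and the kappa-squared effect size) linking visual processing speed to
    reading speed through the visual attention span. Includes a synthetic
    cohort generator, both structural (race-model trial simulation) and
    moment-exact (sample moments reproduced to machine precision), for
    studies of 8-9 year-old readers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
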