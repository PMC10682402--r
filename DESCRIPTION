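Package: rlsfit
Title: Weibull Fitting and Screening Statistics for Yeast Replicative
    Lifespan Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Censoring-aware analysis of single-cell replicative lifespan
    (RLS) experiments in budding yeast. Builds discrete product-limit
    survival curves from per-cell division counts with dead/alive end
    states, fits the Weibull survival law S(g) = exp(-(r*g)^alpha) by
    bounded least squares, and predicts full-distribution lifespan
    statistics (mean, SD, SEM) from the fitted parameters via the gamma
    function, so that fixed-duration (e.g. 72-hour) experiments yield
    complete lifespan estimates. Includes two-sample Z screening of
    deletion strains against wild-type, Pearson correlation for replicate
    concordance, hypergeometric gene-set enrichment with
    Benjamini-Hochberg FDR, exponential dose-response fitting, and a
    synthetic microfluidic aging-experiment generator (Weibull lifespans,
    age-dependent cell-cycle durations, fixed-duration right-censoring)
    for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    fgsea,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
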