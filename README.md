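# rlsfit

Censoring-aware Weibull analysis of single-cell replicative-lifespan
(RLS) experiments in budding yeast, plus the screening statistics built
on top of it.

Microfluidic trapping platforms count, cell by cell, how many daughters a
mother produces before dying. Because long-lived mothers can divide for
five days or more, screens run fixed-duration (typically 72-hour)
experiments instead, which right-censors every cell still dividing at the
end. `rlsfit` turns such truncated data into full-distribution lifespan
estimates and screen-level conclusions:

* **Survival curves** — discrete product-limit (Kaplan–Meier) estimates
  from per-cell division counts and dead/alive end states
  (`empirical_survival()`).
* **Weibull fitting** — bounded least squares of
  `S(g) = exp(-(r·g)^α)` on the survival scale, initialised from the
  exact log-log linearisation (`fit_weibull()`, `init_loglog()`).
* **Full-distribution prediction** — mean, SD and SEM of the complete
  lifespan distribution from the fitted parameters via the gamma
  function: mean `= Γ(1 + 1/α)/r`,
  SD `= sqrt(Γ(1 + 2/α) − Γ(1 + 1/α)²)/r`, SEM `= SD/√n`
  (`predict_full_stats()`, `full_summary()`).
* **Screening statistics** — two-sample Z tests (two-sided for replicate
  concordance, right-sided for "longer-lived than wild-type"), screen
  classification with fold-changes (`two_sample_z()`,
  `classify_screen()`), Pearson correlation (`pearson_cc()`),
  hypergeometric gene-set enrichment with Benjamini–Hochberg FDR
  (`hypergeom_enrichment()`), and exponential dose–response fitting
  (`fit_exp_decay()`).
* **A synthetic experiment generator** — Weibull lifespans, ~90-min
  age-dependent cell-cycle durations, fixed-duration censoring, two
  pooled replicates per strain (`simulate_experiment()`,
  `simulate_screen()`), so every stage is testable without microscope
  data.

## Worked example

Simulate one default 72-h experiment (200 cells, two replicates, true
`r = 0.04`, `α = 4`, i.e. a true full-distribution mean of 22.66
generations), fit it, and predict the full distribution:

```r
library(rlsfit)

cells <- simulate_experiment(
  aging_sim_params(weibull_params(r = 0.04, alpha = 4), seed = 42), "WT")
fit_strains(cells)
#>   strain n_cells n_censored          r    alpha mean_rls   sd_rls       sem
#> 1     WT     200          0 0.04085667 3.798125 22.12031 6.502981 0.4598302
#>           rss converged
#> 1 0.008905381      TRUE
```

The fitted scale is within 2.2% of the truth and the predicted mean
(22.12) is within 1.2 SEM of the true 22.66. Comparing a long-lived hit
against wild-type with the screen's right-sided Z test:

```r
two_sample_z(list(mean = 36, sd = 8, n = 200),
             list(mean = 23, sd = 6, n = 200), sided = "right")
#> Two-sample Z: z = 18.385, p(two-sided) = 1.74e-75, p(right) = 8.7e-76 [right-sided, significant]
```

## The analysis workflow

`analysis/` holds the numbered drivers that chain the package into the
full study, writing tab-separated outputs under `results/`:

| step | script | what it does |
|---|---|---|
| 1 | `01_simulate_screen.R` | simulate a 25-strain screen (8 truly long-lived) from `inst/extdata/screen_config.yaml` |
| 2 | `02_fit_strains.R` | per-strain curves, Weibull fits, full-distribution predictions |
| 3 | `03_classify_screen.R` | right-sided Z screen vs wild-type + replicate concordance |
| 4 | `04_duration_benchmark.R` | 48/72/120-h designs vs a 120-h benchmark over 50 strains |
| 5 | `05_enrichment.R` | hypergeometric GO-slim-style enrichment of the hits |
| 6 | `06_dose_response.R` | decaying-exponential fit of mean RLS vs protein level |

Run them in order with `Rscript analysis/01_simulate_screen.R` etc. (the
package must be installed). On the shipped configuration the screen step
prints

```
8 of 24 deletion strains live significantly longer than wild-type (right-sided p < 0.05)
replicate concordance: PCC = 0.981 over 25 strains
```

recovering exactly the 8 strains simulated as long-lived, and the
duration benchmark prints

```
 48 h: 26/50 strains not significantly different from benchmark; RMSE 2.61
 72 h: 46/50 strains not significantly different from benchmark; RMSE 0.58
120 h: 46/50 strains not significantly different from benchmark; RMSE 0.63
```

— 3-day experiments predict the same lifespans as the 5-day benchmark
(92% of strains indistinguishable, matching the nominal rate of the null
self-comparison in the last row), while 2-day experiments visibly
degrade.

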