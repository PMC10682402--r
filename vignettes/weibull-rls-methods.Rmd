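---
title: "Predicting full replicative-lifespan distributions from truncated single-cell experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting full replicative-lifespan distributions from truncated single-cell experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlsfit)
```

## The measurement problem

Replicative lifespan (RLS) in budding yeast is the number of divisions a
mother cell completes before it stops dividing and dies. Microfluidic
trapping devices measure it directly: newborn mother cells are caught in
traps at time zero, imaged every few minutes, and their daughter-production
events are counted until death. The practical obstacle is time. A typical
mother divides roughly 23 times with each division taking about 90 minutes,
but long-lived cells — exactly the interesting ones in an aging screen —
can keep dividing for five days or more. Running every experiment to
completion makes a multi-hundred-strain screen infeasible, while stopping
early right-censors the long-lived tail: a cell still dividing at the end
of the experiment has a lifespan that is only bounded below by its observed
division count.

`rlsfit` implements the parametric solution: run fixed-duration (72-hour)
experiments, fit the observed part of the survival curve to a Weibull
survival law, and recover the *full* distribution's statistics from the
fitted parameters.

## Model

The survival fraction at generation $g$ is modelled as

$$\frac{S}{S_0} = e^{-(r g)^\alpha},$$

with scale $r$ (units 1/generation) and dimensionless shape $\alpha$;
$\alpha > 1$ means an increasing hazard, i.e. aging. The full
distribution's mean and standard deviation follow in closed form through
the gamma function:

$$\bar x = \frac{\Gamma(1 + 1/\alpha)}{r}, \qquad
  \sigma = \frac{\sqrt{\Gamma(1 + 2/\alpha) - \Gamma(1 + 1/\alpha)^2}}{r},$$

with SEM $= \sigma/\sqrt{n}$ over the $n$ cells analysed. Both are
evaluated through `lgamma()` so extreme shapes (down to $\alpha = 0.1$)
do not overflow. In deletion-strain screens the fitted parameters fall
roughly in $r \in [0.025, 0.195]$, $\alpha \in [1.6, 7.3]$; the fitter's
box ($r \in [10^{-6}, 10]$, $\alpha \in [0.1, 50]$) brackets that range
with wide margins, and a fit that terminates on the box boundary is
reported as unconverged rather than trusted.

## From cell records to parameters

The input per cell is minimal: the number of divisions counted and the end
state, dead or alive, at experiment end. `empirical_survival()` converts a
table of such records into a discrete product-limit (Kaplan–Meier) curve.
The convention: a dead cell with $L$ divisions completed $L$ and failed
attempt $L+1$; a cell alive at the end with $C$ divisions is known alive
through generation $C$ and then leaves the risk set; at ties, deaths are
processed before censorings. With no censored cells this reduces exactly
to the naive fraction of cells with lifespan $\ge g$. The input format
names only generation counts and end states, so the censoring estimator is
a design choice of this package: the product-limit estimator is the
standard unbiased one, and a `method = "naive"` mode (censored cells
counted as survivors up to their observed count, curve truncated at the
smallest censored count) is kept behind a flag for sensitivity analysis.

`fit_weibull()` then minimises the unweighted residual sum of squares on
the survival scale, $\sum_g (\hat S(g) - e^{-(rg)^\alpha})^2$, over
generations $g \ge 1$ whose risk set holds at least 5 cells — tail points
estimated from fewer cells are noise-dominated and would otherwise
dominate an unweighted objective. Optimisation is Levenberg–Marquardt
within the parameter box (objective tolerance $10^{-10}$, at most 1000
iterations), started from the exact log-log linearisation
$\ln(-\ln \hat S) = \alpha \ln g + \alpha \ln r$ computed by ordinary
least squares over the points with $0 < \hat S < 1$. On noiseless curves
the linearisation alone recovers the parameters to machine-level accuracy,
so the nonlinear step only has to absorb sampling noise. Curves with fewer
than two distinct death generations or fewer than three fit points raise a
degeneracy error instead of a meaningless two-parameter fit.

```{r fit-example}
cells <- simulate_experiment(
  aging_sim_params(weibull_params(r = 0.04, alpha = 4), seed = 42), "WT")
fit_strains(cells)
```

A deliberate distinction: simulated integer lifespans are the floor of a
continuous Weibull variate, which makes the simulated survival function
equal the continuous law *exactly* at integer generations, while the
expected integer lifespan $E[L] = \sum_{g \ge 1} S(g)$ sits about half a
generation below the continuous mean $\bar x$. All reported statistics use
the continuous closed forms above — that is the quantity the fitting
procedure defines — and the discrete sum exists only as a testing oracle.

## The synthetic experiment generator

Because the raw screen data live in supplementary archives, every stage
here is validated against a generator that emulates the experiment's
statistical structure, with defaults set to the screen's design:

* integer lifespans from the Weibull law (inverse-CDF, floored);
* 200 cells per strain, split evenly over 2 biological replicates and
  pooled before curve construction (fitting the pooled curve is exactly
  fitting the concatenated records);
* cell-cycle durations of 90 min scaled by lognormal noise with unit
  median and CV 0.2 — positive by construction, with a simple CV
  parameterisation;
* senescent slowdown: the last 5 cycles before death are elongated by a
  linear ramp up to a factor $1 + \lambda$ ($\lambda = 1$ by default).
  This is a minimal mechanism, not a measured model; its role is to make
  short experiments censor harder than division counts alone imply, which
  is what gives the duration benchmark its bite;
* right-censoring at a fixed duration, 72 h by default; death is placed
  at the end of the failed division attempt, so with deterministic 90-min
  cycles a 72-h run censors exactly at 48 divisions;
* all cells enter at time zero (trap loading), no staggered entry; and
  optional rounding of division times up to a 10-min imaging frame,
  off by default since generation counting, not timing, drives the
  analysis.

Per-strain RNG streams are derived from the master seed plus a hash of the
strain label, so a strain's data never depend on which other strains are
simulated. What the generator does *not* emulate: trap loss and other
non-death exits, replicate-level batch effects, measurement error in
division counting, and any deviation of true lifespans from the Weibull
family. Tests passing on these simulations therefore show that the
pipeline recovers what it assumes — parameter recovery, calibration of the
test statistics, the benefit of longer durations — not that real lifespan
data are Weibull.

## Screening statistics

Strain-level comparisons use the plug-in two-sample Z statistic

$$Z = \frac{\bar x_1 - \bar x_2}{\sqrt{\sigma_1^2/n_1 + \sigma_2^2/n_2}},$$

with the hypothesised population difference zero: two-sided p-values
$2\Phi(-|Z|)$ for replicate concordance, right-sided $1 - \Phi(Z)$ for
"does this deletion live longer than wild-type". $\Phi$ is evaluated
through `pnorm()`'s tail routines (erfc-based), which resolve the
$|Z| \approx 13$ comparisons a strong screen hit produces
(p $\sim 10^{-39}$) without underflow. The default screen classification
flags raw $p < 0.05$ with no multiplicity correction — that is the
convention the per-strain significance calls follow — and a
Benjamini–Hochberg option is provided for users who want FDR control at
the screen level; BH can only shrink the significant set.

Enrichment of hit genes in annotation terms uses the upper-tail
hypergeometric probability $P(X \ge k)$, the enrichment score
$-\log_{10} p$, and BH FDR across terms, with raw $p < 0.05$ flagged
significant and FDR $< 0.05$ flagged strong. The universe defaults to
whatever gene list the caller supplies; passing the full genome
reproduces the GO-slim setting. Dose–response curves of mean RLS against
relative protein level are fitted as $y = a e^{-bx} + c$ with $b \ge 0$
enforced. The three-parameter form is fixed by this package: a "decaying
exponential" alone does not pin down the asymptote, and a positive $c$ is
biologically sensible since heavily over-expressing strains still divide.
The fit uses Levenberg–Marquardt from five fixed data-derived starts with
the best final objective winning (ties to the first start), making it
deterministic for a given table. `population_age_fraction()` documents the
companion demographic fact as the symmetric-budding approximation — the
fraction of cells aged $\ge a$ in an exponentially growing culture is
modelled as $2^{-a}$, so bulk assays probe almost exclusively young
cells; real age distributions deviate from exact halving, and the
function asserts only its own model.

## Validation designs and problem sizes

The package's own checks, all simulation-based and all run by the test
suite and `scripts/acceptance.R`, use these study sizes:

* **moment identity** — closed-form mean and SD against numerical
  integration of the survival law over a 20-point $(r, \alpha)$ grid;
* **parameter recovery** — 100 independent 72-h experiments at
  $(r = 0.04, \alpha = 4)$, $n = 200$: median relative error of $\hat r$
  and coverage of the true mean by prediction $\pm$ 2 SEM;
* **duration benchmark** — 50 strains with true means spanning 15–36
  generations, each run at 48/72/120 h against an independent 120-h
  benchmark with two-sided Z tests, plus per-duration RMSE of the
  predicted mean against the closed-form truth;
* **error rates** — 2000 null strain pairs for the right-sided test's
  type-I rate, and 200 repetitions of a 1.5× longer-lived strain for
  power;
* **combinatorial oracles** — hypergeometric upper tails against
  exhaustive enumeration for every universe of size $\le 12$, and BH
  against the literal step-up definition on random p-vectors.

These sizes give stable Monte-Carlo estimates (binomial SE on the type-I
rate at 2000 pairs is about 0.005) while keeping the whole suite fast.

## Known limitations

Least-squares on the survival scale is the procedure this pipeline
defines; it is not maximum likelihood for censored data, and no
alternative survival families (Gompertz, log-logistic) are offered. The
Z tests treat the fitted mean and SD as plug-in sample moments; the SEM
uses the Weibull-model SD rather than a fit-propagated standard error,
which simulation shows is close to the sampling SD of the predicted mean
at $n = 200$ under the default design, but is not guaranteed for heavily
censored designs. Strains whose curves are degenerate (e.g. every cell
dying at one generation, or all cells censored) are carried through
batch fits as unconverged rows rather than estimates.
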