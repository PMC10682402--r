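#' Censoring-aware empirical survival curve
#'
#' Discrete product-limit (Kaplan-Meier) estimate of the survival
#' fraction by generation, built from per-cell division counts and end
#' states. Convention: a dead cell with `divisions = L` completed L
#' divisions and failed division attempt L + 1; a cell censored at C
#' divisions is known alive through generation C and leaves the risk set
#' afterwards (deaths are processed before censorings at ties). With no
#' censored cells the estimate reduces exactly to the naive fraction of
#' cells with lifespan >= g.
#'
#' A `"naive"` mode is available for sensitivity analysis: censored cells
#' count as survivors up to their observed division count and the curve
#' is truncated at the smallest censored count, where the naive fraction
#' stops being interpretable.
#'
#' @param cells A `cell_table` data frame (columns `divisions`,
#'   `end_state`; see [simulate_experiment()] or [read_cell_table()]).
#'   All records should belong to one strain; replicates are pooled.
#' @param method `"km"` (product-limit, default) or `"naive"`.
#' @return An object of class `survival_curve`: list with integer vector
#'   `generations` (0, 1, ...), `s_hat`, `n_risk`, and counts `n_total`,
#'   `n_censored`.
#' @examples
#' cells <- data.frame(divisions = c(2L, 3L, 5L),
#'                     end_state = c("dead", "censored", "dead"))
#' as.data.frame(empirical_survival(cells))
#' @export
empirical_survival <- function(cells, method = c("km", "naive")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(cells),
            all(c("divisions", "end_state") %in% names(cells)))
  if (nrow(cells) == 0) stop("no cell records supplied", call. = FALSE)
  if (length(unique(cells$strain %||% "strain")) > 1) {
    stop("records from more than one strain; pool per strain", call. = FALSE)
  }
  bad <- !cells$end_state %in% c("dead", "censored")
  if (any(bad)) {
    stop("unknown end_state value(s): ",
         paste(unique(cells$end_state[bad]), collapse = ", "), call. = FALSE)
  }
  L <- as.integer(cells$divisions[cells$end_state == "dead"])
  C <- as.integer(cells$divisions[cells$end_state == "censored"])
  if (any(c(L, C) < 0)) stop("negative division counts", call. = FALSE)
  n_total <- length(L) + length(C)
  if (length(L) == 0) {
    stop("degenerate data: no death events (all cells censored)",
         call. = FALSE)
  }

  g_max <- max(L) + 1L
  gens <- 0:g_max
  # risk set at generation g: cells known alive at g
  n_risk <- vapply(gens, function(g) sum(L >= g) + sum(C >= g), 0L)

  if (method == "km") {
    # division attempt j kills cells with L = j - 1; at risk for attempt j
    # are dead cells with L >= j - 1 and censored cells with C >= j
    j <- seq_len(g_max)
    n_j <- vapply(j, function(jj) sum(L >= jj - 1L) + sum(C >= jj), 0L)
    d_j <- vapply(j, function(jj) sum(L == jj - 1L), 0L)
    s_hat <- c(1, cumprod(1 - d_j / n_j))
  } else {
    s_hat <- vapply(gens, function(g) (sum(L >= g) + sum(C >= g)) / n_total, 0)
    if (length(C)) {
      keep <- gens <= min(C)
      gens <- gens[keep]
      s_hat <- s_hat[keep]
      n_risk <- n_risk[keep]
    }
  }

  structure(list(generations = as.integer(gens), s_hat = as.numeric(s_hat),
                 n_risk = as.integer(n_risk), n_total = as.integer(n_total),
                 n_censored = length(C)),
            class = "survival_curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
as.data.frame.survival_curve <- function(x, ...) {
  data.frame(generation = x$generations, s_hat = x$s_hat, n_risk = x$n_risk)
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf(
    "Empirical survival curve: %d cells (%d censored), generations 0..%d\n",
    x$n_total, x$n_censored, max(x$generations)))
  invisible(x)
}

# synthetic curve straight from the law, for exact-recovery checks
curve_from_params <- function(params, g_max = 60, n_total = 1e6L) {
  params <- as_weibull_params(params)
  gens <- 0:g_max
  structure(list(generations = as.integer(gens),
                 s_hat = survival_weibull(params, gens),
                 n_risk = rep.int(as.integer(n_total), length(gens)),
                 n_total = as.integer(n_total), n_censored = 0L),
            class = "survival_curve")
}

#' Log-log initialisation for the Weibull least-squares fit
#'
#' The survival law linearises as \eqn{\ln(-\ln S) = \alpha \ln g +
#' \alpha \ln r}; ordinary least squares over the generations with
#' `0 < s_hat < 1` gives starting values for the nonlinear fit. Exact on
#' noiseless curves.
#'
#' @param curve A `survival_curve`.
#' @param bounds Parameter box used by the fitter, see [fit_weibull()].
#' @return A [weibull_params()] object, clipped to `bounds`.
#' @export
init_loglog <- function(curve, bounds = weibull_fit_bounds()) {
  stopifnot(inherits(curve, "survival_curve"))
  use <- curve$generations >= 1 & curve$s_hat > 0 & curve$s_hat < 1
  if (sum(use) < 2) {
    stop("fewer than 2 usable points (0 < s_hat < 1) for initialisation",
         call. = FALSE)
  }
  x <- log(curve$generations[use])
  y <- log(-log(curve$s_hat[use]))
  fit <- stats::lsfit(x, y)
  alpha <- unname(fit$coefficients[2])
  r <- exp(unname(fit$coefficients[1]) / alpha)
  weibull_params(clip(r, bounds$r), clip(alpha, bounds$alpha))
}

clip <- function(x, range) min(max(x, range[1]), range[2])

#' Parameter box for Weibull fitting
#'
#' Wide bounds bracketing the parameter ranges seen in deletion-strain
#' lifespan screens (r roughly 0.025-0.195 per generation, alpha roughly
#' 1.6-7.3) with generous margins.
#'
#' @return List with numeric ranges `r` and `alpha`.
#' @export
weibull_fit_bounds <- function() {
  list(r = c(1e-6, 10), alpha = c(0.1, 50))
}

#' Least-squares Weibull fit of a survival curve
#'
#' Bounded nonlinear least squares of \eqn{S(g) = \exp(-(r g)^\alpha)}
#' against the empirical survival fractions, unweighted on the survival
#' scale, over generations `g >= 1` whose risk set holds at least
#' `min_risk` cells (tail points estimated from fewer cells are
#' noise-dominated). Initialised by [init_loglog()], falling back to
#' `alpha = 2`, `r = 1/mean(observed divisions)` on degenerate
#' initialisations. Optimisation is Levenberg-Marquardt within the
#' parameter box, objective tolerance 1e-10, at most 1000 iterations;
#' the result is deterministic for a fixed curve.
#'
#' @param curve A `survival_curve` from [empirical_survival()].
#' @param min_risk Minimum risk-set size for a generation to enter the
#'   fit (default 5).
#' @param bounds Parameter box, see [weibull_fit_bounds()].
#' @return An object of class `weibull_fit`: list with `params`,
#'   `init_params`, `rss`, `n_points_fit`, `converged`, `at_bound`,
#'   `message`, `n_total`, `n_censored`.
#' @export
fit_weibull <- function(curve, min_risk = 5, bounds = weibull_fit_bounds()) {
  stopifnot(inherits(curve, "survival_curve"))
  dead_gens <- which(diff(curve$s_hat) < 0)  # generations where s_hat drops
  if (length(dead_gens) < 2) {
    stop("degenerate curve: fewer than 2 distinct death generations",
         call. = FALSE)
  }
  use <- curve$generations >= 1 & curve$n_risk >= min_risk
  g <- curve$generations[use]
  s <- curve$s_hat[use]
  if (length(g) < 3) {
    stop("degenerate curve: fewer than 3 generations available for fitting",
         call. = FALSE)
  }

  init <- tryCatch(init_loglog(curve, bounds), error = function(e) {
    obs_mean <- sum(-diff(curve$s_hat) * curve$generations[-1]) /
      max(1 - curve$s_hat[length(curve$s_hat)], .Machine$double.eps)
    weibull_params(clip(1 / max(obs_mean, 1), bounds$r), 2)
  })

  resid_fun <- function(p) s - exp(-(p[1] * g)^p[2])
  nls <- minpack.lm::nls.lm(
    par = c(init$r, init$alpha), fn = resid_fun,
    lower = c(bounds$r[1], bounds$alpha[1]),
    upper = c(bounds$r[2], bounds$alpha[2]),
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                         maxiter = 1000))
  converged <- nls$info %in% 1:4
  p <- nls$par
  at_bound <- p[1] <= bounds$r[1] * (1 + 1e-8) |
    p[1] >= bounds$r[2] * (1 - 1e-8) |
    p[2] <= bounds$alpha[1] * (1 + 1e-8) |
    p[2] >= bounds$alpha[2] * (1 - 1e-8)

  structure(list(params = weibull_params(p[1], p[2]),
                 init_params = init,
                 rss = sum(resid_fun(p)^2),
                 n_points_fit = length(g),
                 converged = converged && !at_bound,
                 at_bound = at_bound,
                 message = nls$message,
                 n_total = curve$n_total,
                 n_censored = curve$n_censored),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "Weibull LS fit: r = %.4f, alpha = %.3f (rss %.3g over %d points, %s)\n",
    x$params$r, x$params$alpha, x$rss, x$n_points_fit,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Predict full-lifespan statistics from a fitted truncated experiment
#'
#' The step that turns a fixed-duration (e.g. 72-h) experiment into
#' full-distribution lifespan estimates: the fitted `r` and `alpha` are
#' pushed through the closed-form gamma-function moments to give the
#' predicted mean RLS, SD, and SEM over the `n` cells analysed.
#'
#' @param fit A converged [fit_weibull()] result.
#' @param n Number of cells analysed; defaults to the number that entered
#'   the curve.
#' @param strain_id,scope Metadata carried on the summary (scope:
#'   `"pooled"` or a replicate label).
#' @return An object of class `lifespan_summary`: list with `strain_id`,
#'   `scope`, `fit`, and `moments` (an `rls_moments`).
#' @export
predict_full_stats <- function(fit, n = fit$n_total, strain_id = NA_character_,
                               scope = "pooled") {
  stopifnot(inherits(fit, "weibull_fit"))
  if (!isTRUE(fit$converged)) {
    stop("cannot predict full statistics from an unconverged fit",
         call. = FALSE)
  }
  structure(list(strain_id = strain_id, scope = scope, fit = fit,
                 moments = full_summary(fit$params, n)),
            class = "lifespan_summary")
}

#' @export
print.lifespan_summary <- function(x, ...) {
  cat(sprintf("%s [%s]: ", x$strain_id, x$scope))
  print(x$moments)
  invisible(x)
}

#' Fit every strain in a cell table
#'
#' Pools replicates per strain, builds the product-limit curve, fits the
#' Weibull law and predicts full-distribution statistics. Strains whose
#' data are degenerate or whose fit does not converge are retained with
#' `converged = FALSE` and `NA` estimates rather than aborting the batch.
#'
#' @param cells A `cell_table` covering one or more strains.
#' @param min_risk Passed to [fit_weibull()].
#' @return Data frame with one row per strain: `strain`, `n_cells`,
#'   `n_censored`, `r`, `alpha`, `mean_rls`, `sd_rls`, `sem`, `rss`,
#'   `converged`.
#' @examples
#' sim <- simulate_experiment(
#'   aging_sim_params(weibull_params(0.04, 4), n_cells = 200, seed = 3),
#'   strain_id = "WT")
#' fit_strains(sim)
#' @export
fit_strains <- function(cells, min_risk = 5) {
  stopifnot(is.data.frame(cells), "strain" %in% names(cells))
  strains <- unique(cells$strain)
  rows <- lapply(strains, function(s) {
    sub <- cells[cells$strain == s, , drop = FALSE]
    base <- data.frame(strain = s, n_cells = nrow(sub),
                       n_censored = sum(sub$end_state == "censored"),
                       r = NA_real_, alpha = NA_real_, mean_rls = NA_real_,
                       sd_rls = NA_real_, sem = NA_real_, rss = NA_real_,
                       converged = FALSE, stringsAsFactors = FALSE)
    res <- tryCatch({
      fit <- fit_weibull(empirical_survival(sub), min_risk = min_risk)
      if (isTRUE(fit$converged)) {
        sm <- predict_full_stats(fit, strain_id = s)
        base$r <- fit$params$r
        base$alpha <- fit$params$alpha
        base$mean_rls <- sm$moments$mean
        base$sd_rls <- sm$moments$sd
        base$sem <- sm$moments$sem
        base$rss <- fit$rss
        base$converged <- TRUE
      } else {
        base$r <- fit$params$r
        base$alpha <- fit$params$alpha
        base$rss <- fit$rss
      }
      base
    }, error = function(e) base)
    res
  })
  do.call(rbind, rows)
}

#' Experiment-duration benchmark
#'
#' Recreates the duration-validation design used to justify 3-day
#' experiments: for each strain, independent experiments are simulated at
#' each candidate duration and at the benchmark duration, each is fitted
#' and pushed to full-distribution predictions, and each duration's
#' prediction is compared to the benchmark's by a two-sided two-sample Z
#' test. The benchmark duration itself is compared against an independent
#' replicate of the benchmark design, giving a null self-comparison.
#' Per-duration root-mean-square error of the predicted mean against the
#' known closed-form mean is reported alongside.
#'
#' @param strain_specs Data frame `strain`, `r`, `alpha` (as in
#'   [simulate_screen()]).
#' @param shared An [aging_sim_params()] design shared by all runs (its
#'   `duration_h` is overridden per horizon).
#' @param horizons_h Candidate experiment durations in hours.
#' @param benchmark_h Benchmark duration; must be among `horizons_h`.
#' @param alpha_level Significance level for the comparisons.
#' @return List with `results` (per strain x horizon: fitted params,
#'   predicted mean/SEM, `z`, `p_two_sided`, `significant`, `true_mean`,
#'   `error`) and `rmse` (per horizon, over converged strains).
#' @export
duration_benchmark <- function(strain_specs, shared,
                               horizons_h = c(48, 72, 120),
                               benchmark_h = 120, alpha_level = 0.05) {
  stopifnot(inherits(shared, "aging_sim_params"))
  if (!benchmark_h %in% horizons_h) {
    stop("'horizons_h' must include the benchmark duration", call. = FALSE)
  }
  if (is.list(strain_specs) && !is.data.frame(strain_specs)) {
    strain_specs <- data.frame(
      strain = names(strain_specs),
      r = vapply(strain_specs, function(p) as_weibull_params(p)$r, 0),
      alpha = vapply(strain_specs, function(p) as_weibull_params(p)$alpha, 0),
      stringsAsFactors = FALSE)
  }

  one_run <- function(sp, dur, seed_shift) {
    pars <- shared
    pars$true_params <- weibull_params(sp$r, sp$alpha)
    pars$duration_h <- dur
    pars$seed <- as.integer((as.numeric(shared$seed) + label_hash(sp$strain) +
                               seed_shift) %% 2147483647)
    cells <- simulate_experiment(pars, strain_id = sp$strain)
    tryCatch({
      fit <- fit_weibull(empirical_survival(cells))
      if (!isTRUE(fit$converged)) return(NULL)
      predict_full_stats(fit, strain_id = sp$strain)
    }, error = function(e) NULL)
  }

  rows <- list()
  for (i in seq_len(nrow(strain_specs))) {
    sp <- strain_specs[i, ]
    true_mean <- mean_rls(weibull_params(sp$r, sp$alpha))
    ref <- one_run(sp, benchmark_h, seed_shift = 10585)  # independent reference
    for (h_i in seq_along(horizons_h)) {
      h <- horizons_h[h_i]
      run <- one_run(sp, h, seed_shift = 20000L + 7L * h_i)
      row <- data.frame(strain = sp$strain, horizon_h = h,
                        r = NA_real_, alpha = NA_real_, mean_rls = NA_real_,
                        sem = NA_real_, z = NA_real_, p_two_sided = NA_real_,
                        significant = NA, true_mean = true_mean,
                        error = NA_real_, converged = FALSE,
                        stringsAsFactors = FALSE)
      if (!is.null(run)) {
        row$r <- run$fit$params$r
        row$alpha <- run$fit$params$alpha
        row$mean_rls <- run$moments$mean
        row$sem <- run$moments$sem
        row$error <- run$moments$mean - true_mean
        row$converged <- TRUE
        if (!is.null(ref)) {
          cmp <- two_sample_z(run$moments, ref$moments, sided = "two",
                              alpha_level = alpha_level)
          row$z <- cmp$z
          row$p_two_sided <- cmp$p_two_sided
          row$significant <- cmp$significant
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  results <- do.call(rbind, rows)
  ok <- results$converged
  rmse <- do.call(rbind, lapply(horizons_h, function(h) {
    e <- results$error[ok & results$horizon_h == h]
    data.frame(horizon_h = h, rmse = sqrt(mean(e^2)), n_strains = length(e))
  }))
  list(results = results, rmse = rmse)
}
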