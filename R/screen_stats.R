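#' Two-sample Z test for lifespan summaries
#'
#' Compares two strain-level (or replicate-level) lifespan summaries with
#' the statistic \eqn{Z = (\bar x_1 - \bar x_2) / \sqrt{\sigma_1^2/n_1 +
#' \sigma_2^2/n_2}} (the hypothesised population difference is zero).
#' Two-sided p-values, \eqn{2\Phi(-|z|)}, are used for replicate
#' concordance; right-sided p-values, \eqn{1 - \Phi(z)}, test whether
#' sample 1 is longer-lived than sample 2 (strain vs wild-type). The
#' normal tail is evaluated on the log scale internally, so |z| in the
#' tens (p-values down to ~1e-300) is resolved.
#'
#' @param s1,s2 `rls_moments` objects (see [full_summary()]) or lists
#'   with `mean`, `sd`, `n`.
#' @param sided `"two"` or `"right"`; selects which p-value drives the
#'   `significant` flag.
#' @param alpha_level Significance level (default 0.05).
#' @return An object of class `strain_comparison`: `z`, `p_two_sided`,
#'   `p_one_sided_right`, `significant`, plus the inputs.
#' @examples
#' a <- full_summary(weibull_params(0.025, 4), n = 200)
#' b <- full_summary(weibull_params(0.040, 4), n = 200)
#' two_sample_z(a, b, sided = "right")
#' @export
two_sample_z <- function(s1, s2, sided = c("two", "right"),
                         alpha_level = 0.05) {
  sided <- match.arg(sided)
  chk <- function(s, who) {
    stopifnot(all(c("mean", "sd", "n") %in% names(s)))
    if (s$n < 2) stop("'", who, "' must summarise at least 2 cells",
                      call. = FALSE)
    if (s$sd < 0) stop("negative SD in '", who, "'", call. = FALSE)
    s
  }
  s1 <- chk(s1, "s1"); s2 <- chk(s2, "s2")
  se <- sqrt(s1$sd^2 / s1$n + s2$sd^2 / s2$n)
  diff <- s1$mean - s2$mean
  if (se == 0) {
    if (diff == 0) {
      stop("both SDs are zero with equal means: Z is undefined",
           call. = FALSE)
    }
    z <- sign(diff) * Inf
  } else {
    z <- diff / se
  }
  p_two <- 2 * stats::pnorm(-abs(z))
  p_right <- stats::pnorm(z, lower.tail = FALSE)
  p_sel <- if (sided == "two") p_two else p_right
  structure(list(mean1 = s1$mean, mean2 = s2$mean, sd1 = s1$sd, sd2 = s2$sd,
                 n1 = s1$n, n2 = s2$n, z = z, p_two_sided = p_two,
                 p_one_sided_right = p_right, sided = sided,
                 alpha_level = alpha_level, significant = p_sel < alpha_level),
            class = "strain_comparison")
}

#' @export
print.strain_comparison <- function(x, ...) {
  cat(sprintf(
    "Two-sample Z: z = %.3f, p(two-sided) = %.3g, p(right) = %.3g [%s-sided%s]\n",
    x$z, x$p_two_sided, x$p_one_sided_right, x$sided,
    if (x$significant) ", significant" else ""))
  invisible(x)
}

#' Classify a deletion screen against wild-type
#'
#' For each strain, computes the fold-change of its predicted mean RLS
#' over the wild-type's and a right-sided Z test of the strain being
#' longer-lived, flagging significance at `alpha_level` on the raw
#' p-value by default (Benjamini-Hochberg adjustment available as an
#' option). These (fold-change, |z|) pairs are the standard screen
#' scatter.
#'
#' @param fits Data frame as returned by [fit_strains()] (columns
#'   `strain`, `mean_rls`, `sd_rls`, `n_cells`, `converged`).
#' @param wildtype_id Strain label of the wild-type reference.
#' @param alpha_level Significance level (default 0.05).
#' @param correction `"none"` (default) or `"BH"`.
#' @return The input with columns `fold_change_vs_wt`, `z_vs_wt`,
#'   `p_right` (BH-adjusted when requested), `significant` appended. The
#'   wild-type row has fold-change 1 and `significant = FALSE`.
#' @export
classify_screen <- function(fits, wildtype_id, alpha_level = 0.05,
                            correction = c("none", "BH")) {
  correction <- match.arg(correction)
  stopifnot(is.data.frame(fits),
            all(c("strain", "mean_rls", "sd_rls", "n_cells", "converged")
                %in% names(fits)))
  wt <- fits[fits$strain == wildtype_id, , drop = FALSE]
  if (nrow(wt) != 1) {
    stop("wild-type strain '", wildtype_id,
         "' absent (or duplicated) in the fit table", call. = FALSE)
  }
  if (!isTRUE(wt$converged)) {
    stop("wild-type fit did not converge; screen cannot be classified",
         call. = FALSE)
  }
  wt_sum <- list(mean = wt$mean_rls, sd = wt$sd_rls, n = wt$n_cells)

  out <- fits
  out$fold_change_vs_wt <- out$mean_rls / wt$mean_rls
  out$z_vs_wt <- NA_real_
  out$p_right <- NA_real_
  for (i in seq_len(nrow(out))) {
    if (!isTRUE(out$converged[i])) next
    cmp <- two_sample_z(list(mean = out$mean_rls[i], sd = out$sd_rls[i],
                             n = out$n_cells[i]),
                        wt_sum, sided = "right", alpha_level = alpha_level)
    out$z_vs_wt[i] <- cmp$z
    out$p_right[i] <- cmp$p_one_sided_right
  }
  if (correction == "BH") {
    has_p <- !is.na(out$p_right)
    out$p_right[has_p] <- bh_fdr(out$p_right[has_p])
  }
  out$significant <- !is.na(out$p_right) & out$p_right < alpha_level
  out$significant[out$strain == wildtype_id] <- FALSE
  out
}

#' Pearson correlation coefficient
#'
#' Plain Pearson product-moment correlation of two equal-length vectors,
#' used for replicate concordance and cross-platform comparisons of mean
#' RLS values. Errors on constant input, where the coefficient is
#' undefined.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return List with `pcc` and `n` (class `correlation_result`).
#' @examples
#' pearson_cc(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
pearson_cc <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("'x' and 'y' differ in length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 paired points", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  structure(list(pcc = stats::cor(x, y, method = "pearson"), n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation: PCC = %.4f (n = %d)\n", x$pcc, x$n))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted values \eqn{q_i = \min_{j: p_{(j)} \ge p_{(i)}}
#' (p_{(j)} m / j)} capped at 1, returned in input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(is.numeric(pvals))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1] with no missing values", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Hypergeometric gene-set enrichment
#'
#' Tests each annotation term for over-representation in a hit list
#' (e.g. genes whose deletion significantly extends lifespan) against a
#' gene universe: upper-tail hypergeometric probability
#' \eqn{p = P(X \ge k)} of drawing `k` or more term genes when `n` hits
#' are drawn from `N` universe genes of which `K` carry the term. The
#' enrichment score is \eqn{-\log_{10} p}; FDR is Benjamini-Hochberg
#' across terms. Terms with raw p < `alpha_level` are flagged
#' `significant`, those with FDR < `alpha_level` additionally `strong`.
#'
#' @param hits Character vector of hit genes; must be a subset of
#'   `universe`.
#' @param annotations Named list mapping term id to character vector of
#'   genes (e.g. from [read_gmt()]). Genes outside the universe are
#'   ignored.
#' @param universe Character vector: all genes that could have been hits.
#' @param alpha_level Significance level (default 0.05).
#' @return Data frame sorted by p: `term`, `k`, `K`, `n`, `N`, `p`,
#'   `enrichment_score`, `fdr`, `significant`, `strong`.
#' @examples
#' genes <- paste0("g", 1:10)
#' hypergeom_enrichment(hits = genes[1:4],
#'                      annotations = list(term_a = genes[c(1:4, 9)]),
#'                      universe = genes)
#' @export
hypergeom_enrichment <- function(hits, annotations, universe,
                                 alpha_level = 0.05) {
  stopifnot(is.character(hits), is.list(annotations), is.character(universe))
  if (length(hits) == 0) stop("empty hit list", call. = FALSE)
  universe <- unique(universe)
  hits <- unique(hits)
  outside <- setdiff(hits, universe)
  if (length(outside)) {
    stop("hit genes absent from the universe: ",
         paste(outside, collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n <- length(hits)
  rows <- lapply(names(annotations), function(term) {
    term_genes <- intersect(unique(annotations[[term]]), universe)
    K <- length(term_genes)
    k <- length(intersect(term_genes, hits))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               enrichment_score = -log10(p) + 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$significant <- out$p < alpha_level
  out$strong <- out$fdr < alpha_level
  out[order(out$p), , drop = FALSE]
}

#' Exponential dose-response fit
#'
#' Fits mean RLS against relative protein dose with the decaying
#' exponential \eqn{y = a e^{-b x} + c}, `b >= 0` enforced, by
#' Levenberg-Marquardt least squares from five fixed data-derived
#' starting points (best final objective wins; ties resolved by the first
#' start), so the result is deterministic for a given table. A positive
#' asymptote `c` reflects that even heavily over-expressing strains keep
#' dividing.
#'
#' @param levels Relative protein levels (nonnegative), length >= 4.
#' @param means Mean RLS at each level, generations.
#' @return Object of class `dose_response_fit`: `a`, `b`, `c`,
#'   `r_squared`, `converged`, `fitted` values.
#' @examples
#' x <- seq(0, 2, by = 0.25)
#' fit_exp_decay(x, 30 * exp(-1.5 * x) + 6)
#' @export
fit_exp_decay <- function(levels, means) {
  stopifnot(is.numeric(levels), is.numeric(means))
  if (length(levels) != length(means)) {
    stop("'levels' and 'means' differ in length", call. = FALSE)
  }
  if (length(levels) < 4) {
    stop("need at least 4 dose points for a 3-parameter fit", call. = FALSE)
  }
  if (any(levels < 0)) stop("'levels' must be nonnegative", call. = FALSE)
  sstot <- sum((means - mean(means))^2)
  if (sstot == 0) {
    stop("constant response: R-squared undefined", call. = FALSE)
  }

  rng <- diff(range(means))
  xspan <- max(levels) - min(levels)
  starts <- list(
    c(a = rng, b = 1 / max(xspan, 1e-6), c = min(means)),
    c(a = rng, b = 2 / max(xspan, 1e-6), c = min(means)),
    c(a = max(means), b = 1, c = 0),
    c(a = rng / 2, b = 0.5, c = mean(means)),
    c(a = rng * 2, b = 4 / max(xspan, 1e-6), c = min(means) / 2)
  )
  resid_fun <- function(p) means - (p[1] * exp(-p[2] * levels) + p[3])
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fun,
                         lower = c(-Inf, 0, -Inf),
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-12, ptol = 1e-12, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid_fun(fit$par)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(par = fit$par, rss = rss, info = fit$info)
    }
  }
  if (is.null(best)) stop("dose-response fit failed from every start",
                          call. = FALSE)
  p <- best$par
  structure(list(a = unname(p[1]), b = unname(p[2]), c = unname(p[3]),
                 r_squared = 1 - best$rss / sstot,
                 converged = best$info %in% 1:4,
                 fitted = p[1] * exp(-p[2] * levels) + p[3]),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("Dose-response fit: y = %.3f * exp(-%.3f x) + %.3f, R^2 = %.4f\n",
              x$a, x$b, x$c, x$r_squared))
  invisible(x)
}

#' Fraction of old cells in a freely growing population
#'
#' In an exponentially growing budding-yeast culture, cell ages follow
#' (approximately) a geometric distribution: each division produces one
#' newborn, so half the population is age 0, a quarter age 1, and the
#' fraction of cells with replicative age at least `a` is modelled as
#' \eqn{2^{-a}}. Explains why bulk assays on growing cultures probe
#' almost exclusively young cells.
#'
#' @param a Integer replicative age(s), >= 0.
#' @return Fraction(s) of the population at least that old.
#' @examples
#' population_age_fraction(5)  # ~3% of cells are 5 generations or older
#' @export
population_age_fraction <- function(a) {
  stopifnot(is.numeric(a))
  if (any(a < 0) || any(a != floor(a))) {
    stop("'a' must be a nonnegative integer age", call. = FALSE)
  }
  2^(-a)
}
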