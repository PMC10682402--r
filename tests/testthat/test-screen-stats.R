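test_that("two-sample Z matches the hand-worked comparison", {
  long <- list(mean = 36, sd = 8, n = 200)
  wt <- list(mean = 23, sd = 6, n = 200)
  cmp <- two_sample_z(long, wt, sided = "right")
  expect_equal(cmp$z, 13 / sqrt(0.5), tolerance = 1e-12)
  expect_lt(cmp$p_one_sided_right, 1e-30)
  expect_true(cmp$significant)

  same <- two_sample_z(wt, wt, sided = "two")
  expect_equal(same$z, 0)
  expect_equal(same$p_two_sided, 1)
  expect_equal(same$p_one_sided_right, 0.5)
  expect_false(same$significant)

  # antisymmetry: swapping samples negates z, keeps the two-sided p
  swapped <- two_sample_z(wt, long, sided = "right")
  expect_equal(swapped$z, -cmp$z)
  expect_equal(swapped$p_two_sided, cmp$p_two_sided)
  expect_equal(swapped$p_one_sided_right, 1 - cmp$p_one_sided_right,
               tolerance = 1e-12)
})

test_that("two-sided p equals the folded one-sided p across the z range", {
  set.seed(61)
  for (i in 1:50) {
    m1 <- runif(1, 15, 40); m2 <- runif(1, 15, 40)
    cmp <- two_sample_z(list(mean = m1, sd = runif(1, 2, 9), n = 200),
                        list(mean = m2, sd = runif(1, 2, 9), n = 150))
    folded <- 2 * min(cmp$p_one_sided_right, 1 - cmp$p_one_sided_right)
    expect_lt(abs(cmp$p_two_sided - folded), 1e-12)
  }
  expect_error(two_sample_z(list(mean = 20, sd = 0, n = 10),
                            list(mean = 20, sd = 0, n = 10)),
               "undefined")
  expect_error(two_sample_z(list(mean = 20, sd = 5, n = 1),
                            list(mean = 20, sd = 5, n = 10)),
               "at least 2")
})

test_that("deep normal tails are resolved for the z values screens produce", {
  # |z| ~ 13 must give p ~ 1e-39, not underflow to an unusable zero
  long <- list(mean = 32.2, sd = 8, n = 200)
  wt <- list(mean = 23, sd = 6, n = 200)
  cmp <- two_sample_z(long, wt, sided = "right")
  expect_gt(cmp$z, 12)
  expect_lt(cmp$p_one_sided_right, 1e-30)
  expect_gt(cmp$p_one_sided_right, 0)
  expect_lt(cmp$p_two_sided, 1e-30)
  expect_gt(cmp$p_two_sided, 0)
})

test_that("screen classification reproduces hand-computed significance calls", {
  fits <- data.frame(
    strain = c("WT", "long", "null", "short"),
    n_cells = 200L, n_censored = 0L,
    r = NA_real_, alpha = NA_real_,
    mean_rls = c(23, 27, 23.2, 19),
    sd_rls = c(6, 7, 6, 5),
    sem = NA_real_, rss = NA_real_, converged = TRUE,
    stringsAsFactors = FALSE)
  scr <- classify_screen(fits, "WT")
  expect_equal(scr$fold_change_vs_wt[1], 1)
  expect_false(scr$significant[1])
  # hand evaluation: z_long = 4/sqrt(85/200) = 6.139, p ~ 4e-10
  expect_equal(scr$z_vs_wt[2], 4 / sqrt(85 / 200), tolerance = 1e-12)
  expect_true(scr$significant[2])
  expect_false(scr$significant[3])  # z = 0.33, p = 0.37
  expect_false(scr$significant[4])  # shorter-lived never flags right-sided
  expect_equal(sum(scr$significant), 1)

  # BH correction can only shrink the significant set
  scr_bh <- classify_screen(fits, "WT", correction = "BH")
  expect_true(all(scr_bh$significant <= scr$significant))
  expect_error(classify_screen(fits, "missing"), "absent")
})

test_that("Pearson correlation matches its definition and bounds", {
  expect_equal(pearson_cc(1:10, 2 * (1:10))$pcc, 1)
  expect_equal(pearson_cc(1:10, -(1:10))$pcc, -1)
  expect_equal(pearson_cc(c(1, 2, 3, 4), c(1, 3, 2, 4))$pcc, 0.8)
  expect_error(pearson_cc(1:4, rep(2, 4)), "constant")
  expect_error(pearson_cc(1:4, 1:5), "length")
  set.seed(71)
  for (i in 1:200) {
    x <- rnorm(sample(3:20, 1))
    y <- rnorm(length(x))
    expect_lte(abs(pearson_cc(x, y)$pcc), 1)
    expect_equal(pearson_cc(x, x)$pcc, 1)
  }
})

test_that("hypergeometric enrichment equals exhaustive enumeration for small universes", {
  for (N in c(4, 7, 9, 12)) {
    genes <- paste0("g", seq_len(N))
    for (K in 1:N) {
      for (n in 1:N) {
        hits <- genes[seq_len(n)]
        res <- hypergeom_enrichment(hits,
                                    list(t = genes[seq_len(K)]),
                                    universe = genes)
        expect_equal(res$p, enum_hyper_upper(N, K, n, res$k),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("enrichment worked example and edge cases", {
  genes <- paste0("g", 1:10)
  res <- hypergeom_enrichment(genes[1:4], list(t = genes[c(1:4, 9)]), genes)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
  expect_equal(res$enrichment_score, -log10(5 / 210))

  # a term covering the whole universe can never be enriched
  all_term <- hypergeom_enrichment(genes[1:4], list(all = genes), genes)
  expect_equal(all_term$p, 1)
  expect_equal(all_term$enrichment_score, 0)

  expect_error(hypergeom_enrichment(c("g1", "zz"), list(t = genes), genes),
               "zz")
  expect_error(hypergeom_enrichment(character(), list(t = genes), genes),
               "empty")
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(81)
  for (i in 1:100) {
    p <- runif(sample(1:25, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, brute_bh(p), tolerance = 1e-12)
    expect_true(all(q <= 1))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-12))
  }
})

test_that("exponential dose-response fit recovers exact curves and is structural", {
  x <- seq(0, 2, by = 0.25)
  y <- 30 * exp(-1.5 * x) + 6
  fit <- fit_exp_decay(x, y)
  expect_equal(fit$a, 30, tolerance = 1e-6)
  expect_equal(fit$b, 1.5, tolerance = 1e-6)
  expect_equal(fit$c, 6, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  shifted <- fit_exp_decay(x, y + 10)
  expect_equal(shifted$a, fit$a, tolerance = 1e-5)
  expect_equal(shifted$b, fit$b, tolerance = 1e-5)
  expect_equal(shifted$c, fit$c + 10, tolerance = 1e-5)

  expect_error(fit_exp_decay(x, rep(20, length(x))), "constant")
  expect_error(fit_exp_decay(x[1:3], y[1:3]), "at least 4")
  expect_error(fit_exp_decay(-x, y), "nonnegative")
})

test_that("noisy dose series stays monotone decreasing with high R-squared", {
  set.seed(91)
  levels <- c(0, 0.4, 1, 2, 5, 9)
  means <- 23 * exp(-0.9 * levels) + 13 + rnorm(6, sd = 0.5)
  fit <- fit_exp_decay(levels, means)
  expect_gt(fit$r_squared, 0.9)
  expect_gte(fit$b, 0)
  grid <- fit$a * exp(-fit$b * seq(0, 9, by = 0.5)) + fit$c
  expect_true(all(diff(grid) <= 0))
})

test_that("population age fractions follow the geometric halving model", {
  expect_equal(population_age_fraction(0), 1)
  expect_equal(population_age_fraction(1), 0.5)
  expect_equal(population_age_fraction(5), 0.03125)
  expect_error(population_age_fraction(-1), "nonnegative")
})
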