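test_that("product-limit curve matches hand-computed examples", {
  all_dead <- data.frame(divisions = c(2L, 3L, 3L, 5L), end_state = "dead")
  cv <- empirical_survival(all_dead)
  expect_equal(cv$generations, 0:6)
  expect_equal(cv$s_hat, c(1, 1, 1, 0.75, 0.25, 0.25, 0))
  expect_equal(cv$n_total, 4L)
  expect_equal(cv$n_censored, 0L)

  mixed <- data.frame(divisions = c(2L, 3L, 5L),
                      end_state = c("dead", "censored", "dead"))
  cvm <- empirical_survival(mixed)
  expect_equal(cvm$s_hat, c(1, 1, 1, 2/3, 2/3, 2/3, 0))

  single <- data.frame(divisions = 4L, end_state = "dead")
  expect_equal(empirical_survival(single)$s_hat, c(1, 1, 1, 1, 1, 0))
})

test_that("without censoring the curve equals the naive survival fraction", {
  set.seed(11)
  L <- sample_lifespan(weibull_params(0.05, 3), runif(80))
  cells <- data.frame(divisions = L, end_state = "dead")
  cv <- empirical_survival(cells)
  naive <- vapply(cv$generations, function(g) mean(L >= g), 0)
  expect_equal(cv$s_hat, naive)
  # survival counts are integers over n_total
  expect_equal(cv$s_hat * cv$n_total, round(cv$s_hat * cv$n_total))
  expect_true(all(diff(cv$s_hat) <= 0))
  expect_identical(cv$s_hat[1], 1)
})

test_that("degenerate inputs raise typed errors", {
  expect_error(empirical_survival(data.frame(divisions = integer(),
                                             end_state = character())),
               "no cell records")
  expect_error(empirical_survival(data.frame(divisions = c(3L, 8L),
                                             end_state = "censored")),
               "no death events")
  expect_error(empirical_survival(data.frame(divisions = 3L,
                                             end_state = "lost")),
               "end_state")
})

test_that("naive mode truncates at the smallest censored count", {
  cells <- data.frame(divisions = c(2L, 3L, 5L),
                      end_state = c("dead", "censored", "dead"))
  cv <- empirical_survival(cells, method = "naive")
  expect_equal(max(cv$generations), 3L)
  expect_equal(cv$s_hat, c(1, 1, 1, 2/3))
})

test_that("log-log initialisation is exact on noiseless curves", {
  cv <- rlsfit:::curve_from_params(weibull_params(0.05, 3), g_max = 60)
  init <- init_loglog(cv)
  expect_equal(init$r, 0.05, tolerance = 1e-6)
  expect_equal(init$alpha, 3, tolerance = 1e-6)

  flat <- rlsfit:::curve_from_params(weibull_params(0.05, 3), g_max = 60)
  flat$s_hat <- as.numeric(flat$s_hat >= 0.5)  # degenerate 0/1 curve
  expect_error(init_loglog(flat), "usable points")
})

test_that("least squares recovers exact parameters from noiseless data", {
  cv <- rlsfit:::curve_from_params(weibull_params(0.05, 3), g_max = 60)
  fit <- fit_weibull(cv)
  expect_true(fit$converged)
  expect_equal(fit$params$r, 0.05, tolerance = 1e-6)
  expect_equal(fit$params$alpha, 3, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("degenerate curves are rejected rather than fitted", {
  one_gen <- data.frame(divisions = rep(20L, 30), end_state = "dead")
  expect_error(fit_weibull(empirical_survival(one_gen)), "degenerate")
})

test_that("fitted objective beats random parameter draws (local optimality)", {
  set.seed(21)
  L <- sample_lifespan(weibull_params(0.06, 3), runif(20))
  cv <- empirical_survival(data.frame(divisions = L, end_state = "dead"))
  fit <- fit_weibull(cv, min_risk = 1)
  use <- cv$generations >= 1
  obj <- function(r, a) sum((cv$s_hat[use] -
                               exp(-(r * cv$generations[use])^a))^2)
  best <- obj(fit$params$r, fit$params$alpha)
  rr <- runif(200, 1e-3, 0.5)
  aa <- runif(200, 0.5, 10)
  rand <- mapply(obj, rr, aa)
  expect_true(all(best <= rand + 1e-12))
})

test_that("pooling replicates before curve construction equals concatenating records", {
  sim <- simulate_experiment(
    aging_sim_params(weibull_params(0.04, 4), seed = 31), "WT")
  pooled <- fit_weibull(empirical_survival(sim))
  reordered <- sim[order(sim$replicate, decreasing = TRUE), ]
  refit <- fit_weibull(empirical_survival(reordered))
  expect_identical(pooled$params, refit$params)
})

test_that("full-statistics prediction is the closed-form image of the fit", {
  cv <- rlsfit:::curve_from_params(weibull_params(0.05, 1), g_max = 120)
  fit <- fit_weibull(cv)
  fit$n_total <- 200L
  sm <- predict_full_stats(fit, strain_id = "WT")
  expect_equal(sm$moments$mean, 20, tolerance = 1e-5)
  expect_equal(sm$moments$sd, 20, tolerance = 1e-5)
  expect_equal(sm$moments$sem, sqrt(2), tolerance = 1e-5)
  ref <- full_summary(fit$params, 200)
  expect_identical(sm$moments, ref)

  bad <- fit
  bad$converged <- FALSE
  expect_error(predict_full_stats(bad), "unconverged")
})

test_that("fit_strains retains unconverged strains instead of aborting", {
  good <- simulate_experiment(
    aging_sim_params(weibull_params(0.04, 4), n_cells = 100, seed = 41), "ok")
  deg <- data.frame(strain = "deg", replicate = "rep1",
                    cell_id = sprintf("deg_c%02d", 1:10),
                    divisions = rep(15L, 10), end_state = "dead",
                    stringsAsFactors = FALSE)
  deg$division_times <- replicate(10, numeric(0), simplify = FALSE)
  both <- rbind(as.data.frame(good), deg)
  fits <- fit_strains(both)
  expect_equal(nrow(fits), 2)
  expect_true(fits$converged[fits$strain == "ok"])
  expect_false(fits$converged[fits$strain == "deg"])
  expect_true(is.na(fits$mean_rls[fits$strain == "deg"]))
})

test_that("duration benchmark validates horizons and reports per-horizon error", {
  specs <- benchmark_specs(4)
  shared <- aging_sim_params(weibull_params(0.04, 4), n_cells = 100, seed = 51)
  expect_error(duration_benchmark(specs, shared, horizons_h = c(48, 72),
                                  benchmark_h = 120), "benchmark")
  bm <- duration_benchmark(specs, shared, horizons_h = c(72, 120),
                           benchmark_h = 120)
  expect_equal(nrow(bm$results), 8)
  expect_equal(bm$rmse$horizon_h, c(72, 120))
  expect_true(all(is.finite(bm$rmse$rmse)))
  r72 <- bm$results[bm$results$horizon_h == 72, ]
  expect_true(all(abs(r72$error) < 5))
})
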