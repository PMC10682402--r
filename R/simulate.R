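#' Parameters of a synthetic microfluidic aging experiment
#'
#' Describes one simulated single-cell replicative-lifespan experiment on
#' a trapping microfluidic device: newborn mother cells are loaded at time
#' zero, each divides until its Weibull-distributed lifespan is exhausted,
#' and the experiment is stopped after a fixed duration, right-censoring
#' every cell still alive. Cell-cycle durations are about 90 minutes with
#' multiplicative lognormal noise, and the final few cycles before death
#' are elongated (senescent slowdown), so shorter experiment durations
#' censor more aggressively than the division count alone would suggest.
#'
#' @param true_params [weibull_params()] governing lifespans.
#' @param n_cells Total mother cells tracked (default 200).
#' @param n_replicates Biological replicates the cells are split across,
#'   as evenly as possible (default 2).
#' @param duration_h Experiment duration in hours (default 72, the 3-day
#'   design).
#' @param base_cycle_min Baseline cell-cycle duration, minutes (default 90).
#' @param cycle_cv Coefficient of variation of the multiplicative
#'   lognormal cycle-duration noise; 0 gives deterministic cycles
#'   (default 0.2).
#' @param elongation_factor Senescent elongation strength lambda: the last
#'   cycle before death takes `(1 + lambda)` times the baseline
#'   (default 1).
#' @param elongation_window Number of final cycles over which the
#'   elongation ramps up linearly (default 5).
#' @param imaging_interval_min Imaging frame interval in minutes; when
#'   positive, recorded division times are rounded up to the next frame.
#'   Default 0 (continuous timing).
#' @param seed Integer seed; mandatory so simulated datasets are exactly
#'   reproducible.
#' @return An object of class `aging_sim_params`.
#' @examples
#' aging_sim_params(weibull_params(0.04, 4), seed = 1)
#' @export
aging_sim_params <- function(true_params, n_cells = 200, n_replicates = 2,
                             duration_h = 72, base_cycle_min = 90,
                             cycle_cv = 0.2, elongation_factor = 1,
                             elongation_window = 5,
                             imaging_interval_min = 0, seed) {
  true_params <- as_weibull_params(true_params)
  if (missing(seed) || is.null(seed)) {
    stop("'seed' is mandatory: simulated experiments must be reproducible",
         call. = FALSE)
  }
  stopifnot(n_cells >= 1, n_cells == floor(n_cells),
            n_replicates >= 1, n_replicates == floor(n_replicates),
            duration_h >= 0, base_cycle_min > 0, cycle_cv >= 0,
            elongation_factor >= 0,
            elongation_window >= 0, elongation_window == floor(elongation_window),
            imaging_interval_min >= 0,
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(true_params = true_params,
                 n_cells = as.integer(n_cells),
                 n_replicates = as.integer(n_replicates),
                 duration_h = as.numeric(duration_h),
                 base_cycle_min = as.numeric(base_cycle_min),
                 cycle_cv = as.numeric(cycle_cv),
                 elongation_factor = as.numeric(elongation_factor),
                 elongation_window = as.integer(elongation_window),
                 imaging_interval_min = as.numeric(imaging_interval_min),
                 seed = as.integer(seed)),
            class = "aging_sim_params")
}

# Run code under a private RNG stream without disturbing the caller's.
with_sim_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit hash of a label, for deriving per-strain seeds.
label_hash <- function(label) {
  codes <- utf8ToInt(as.character(label))
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 2147483647
  as.integer(h)
}

#' Simulate one microfluidic aging experiment
#'
#' Generates per-cell division-tracking records for one strain under the
#' design in [aging_sim_params()]. Each cell's integer lifespan L is drawn
#' by inverse-CDF sampling from the Weibull law; cycle durations are
#' `base_cycle_min * f_age(i) * eps_i` with lognormal noise `eps_i` of
#' unit median and CV `cycle_cv`, and `f_age(i) = 1 + lambda *
#' max(0, (i - (L - k)) / k)` ramping over the final `k =
#' elongation_window` cycles. Death occurs at the end of the failed
#' `(L+1)`-th division attempt; a cell whose death falls beyond the
#' experiment duration is recorded alive (censored) with the divisions it
#' completed in time.
#'
#' @param params An [aging_sim_params()] object.
#' @param strain_id Strain label recorded on every row.
#' @return A `cell_table` data frame with columns `strain`, `replicate`,
#'   `cell_id`, `divisions`, `end_state` (`"dead"`/`"censored"`) and a
#'   `division_times` list column of completed-division times in minutes.
#'   The generating parameters are attached as attribute `true_params`.
#' @examples
#' cells <- simulate_experiment(
#'   aging_sim_params(weibull_params(0.04, 4), n_cells = 20, seed = 7))
#' table(cells$end_state)
#' @export
simulate_experiment <- function(params, strain_id = "strain") {
  stopifnot(inherits(params, "aging_sim_params"))
  with_sim_seed(params$seed,
                simulate_experiment_impl(params, strain_id))
}

simulate_experiment_impl <- function(params, strain_id) {
  n <- params$n_cells
  k <- params$elongation_window
  lambda <- params$elongation_factor
  dur_min <- params$duration_h * 60

  u <- stats::runif(n)
  # runif() can in principle return 0; reflect into the open interval
  u[u <= 0] <- .Machine$double.eps
  L <- sample_lifespan(params$true_params, u)

  m <- L + 1L                      # completed cycles + the failed attempt
  idx <- rep.int(seq_len(n), m)
  i_within <- sequence(m)
  ramp <- if (k > 0) {
    1 + lambda * pmax(0, (i_within - (L[idx] - k)) / k)
  } else {
    1 + lambda * as.numeric(i_within > L[idx])  # k = 0: only the failed attempt
  }
  eps <- if (params$cycle_cv > 0) {
    sigma <- sqrt(log1p(params$cycle_cv^2))
    exp(stats::rnorm(sum(m), mean = 0, sd = sigma))
  } else {
    rep.int(1, sum(m))
  }
  cyc <- params$base_cycle_min * ramp * eps
  cs <- cumsum(cyc)
  last_pos <- cumsum(m)
  offset <- rep.int(c(0, cs[last_pos[-n]]), m)
  t_div <- cs - offset             # per-cell cumulative event times

  if (params$imaging_interval_min > 0) {
    iv <- params$imaging_interval_min
    t_div <- iv * ceiling(t_div / iv)
  }

  death_time <- t_div[last_pos]
  dead <- death_time <= dur_min
  completed <- i_within <= L[idx]           # true division events
  observed <- completed & t_div <= dur_min  # seen before experiment end
  n_obs <- tabulate(idx[observed], nbins = n)
  divisions <- ifelse(dead, L, n_obs)

  times <- split(t_div[observed], factor(idx[observed], levels = seq_len(n)))
  names(times) <- NULL

  rep_id <- sort(rep_len(seq_len(params$n_replicates), n))
  out <- data.frame(
    strain = rep.int(strain_id, n),
    replicate = paste0("rep", rep_id),
    cell_id = sprintf("%s_c%04d", strain_id, seq_len(n)),
    divisions = as.integer(divisions),
    end_state = ifelse(dead, "dead", "censored"),
    stringsAsFactors = FALSE
  )
  out$division_times <- times
  attr(out, "true_params") <- params$true_params
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Simulate a multi-strain lifespan screen
#'
#' Runs one simulated aging experiment per strain under a common design,
#' deriving each strain's RNG stream deterministically from the master
#' seed and the strain label so that adding or reordering strains never
#' changes another strain's data.
#'
#' @param strain_specs Data frame with columns `strain`, `r`, `alpha`
#'   (one row per strain), or a named list of [weibull_params()].
#' @param shared An [aging_sim_params()] object; its `true_params` are
#'   ignored in favour of each strain's own, its `seed` is the master
#'   seed.
#' @param wildtype_id Label of the strain playing the wild-type reference
#'   (default the first strain). Must be present.
#' @return List with `cells` (row-bound `cell_table` across strains) and
#'   `truth` (per-strain `r`, `alpha`, the closed-form full-distribution
#'   `true_mean` and `true_sd`, and `is_wildtype`).
#' @examples
#' specs <- data.frame(strain = c("WT", "longlived"),
#'                     r = c(0.043, 0.030), alpha = c(3.5, 3.5))
#' sim <- simulate_screen(specs,
#'   aging_sim_params(weibull_params(0.04, 4), n_cells = 50, seed = 11))
#' sim$truth
#' @export
simulate_screen <- function(strain_specs, shared, wildtype_id = NULL) {
  stopifnot(inherits(shared, "aging_sim_params"))
  if (is.list(strain_specs) && !is.data.frame(strain_specs)) {
    strain_specs <- data.frame(
      strain = names(strain_specs),
      r = vapply(strain_specs, function(p) as_weibull_params(p)$r, 0),
      alpha = vapply(strain_specs, function(p) as_weibull_params(p)$alpha, 0),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(strain_specs),
            all(c("strain", "r", "alpha") %in% names(strain_specs)),
            nrow(strain_specs) >= 1)
  if (anyDuplicated(strain_specs$strain)) {
    stop("duplicate strain ids: ",
         paste(unique(strain_specs$strain[duplicated(strain_specs$strain)]),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(wildtype_id)) wildtype_id <- strain_specs$strain[1]
  if (!wildtype_id %in% strain_specs$strain) {
    stop("wild-type strain '", wildtype_id, "' not among strain_specs",
         call. = FALSE)
  }

  per_strain <- lapply(seq_len(nrow(strain_specs)), function(i) {
    sp <- strain_specs[i, ]
    pars <- shared
    pars$true_params <- weibull_params(sp$r, sp$alpha)
    pars$seed <- as.integer((as.numeric(shared$seed) + label_hash(sp$strain)) %%
                              2147483647)
    simulate_experiment(pars, strain_id = sp$strain)
  })
  cells <- do.call(rbind, lapply(per_strain, function(x) {
    class(x) <- "data.frame"
    x
  }))
  class(cells) <- c("cell_table", "data.frame")

  truth <- data.frame(
    strain = strain_specs$strain,
    r = strain_specs$r,
    alpha = strain_specs$alpha,
    true_mean = vapply(seq_len(nrow(strain_specs)), function(i)
      mean_rls(weibull_params(strain_specs$r[i], strain_specs$alpha[i])), 0),
    true_sd = vapply(seq_len(nrow(strain_specs)), function(i)
      sd_rls(weibull_params(strain_specs$r[i], strain_specs$alpha[i])), 0),
    is_wildtype = strain_specs$strain == wildtype_id,
    stringsAsFactors = FALSE
  )
  list(cells = cells, truth = truth)
}

#' Simulate a single tracked mother cell
#'
#' Returns the record of one cell from the deterministic experiment
#' defined by `params`: the same seed and cell index always give the same
#' record, regardless of how many other cells are inspected.
#'
#' @inheritParams simulate_experiment
#' @param cell_index Index of the cell within the experiment, in
#'   `1:params$n_cells`.
#' @return A one-row `cell_table` (see [simulate_experiment()]).
#' @export
simulate_cell <- function(params, cell_index = 1L, strain_id = "strain") {
  stopifnot(inherits(params, "aging_sim_params"),
            cell_index >= 1, cell_index <= params$n_cells)
  cells <- simulate_experiment(params, strain_id = strain_id)
  out <- cells[cell_index, , drop = FALSE]
  rownames(out) <- NULL
  out
}
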