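# Stochastic execution of state-chart models: fixed-step tau-leaping with
# rates frozen at the start of each step, in-step kill-message delivery and
# reproducible seeded ensembles.

#' Configuration of the agent-based engine
#'
#' @param dt step size in days (0 < dt <= 1).  The default 0.02 keeps every
#'   per-step firing probability small for the case-study rate scales (the
#'   largest per-agent rates are around 10 per day) and passes the
#'   step-halving convergence check; see the methods vignette.
#' @param n_runs number of ensemble runs.
#' @param base_seed integer; run `i` (zero-based) uses seed `base_seed + i`.
#' @param mode `"count_based"` (one binomial/multinomial draw per species and
#'   step) or `"per_agent"` (an independent competing-exponential outcome per
#'   agent).  The two are distributionally identical; `per_agent` is only
#'   practical for small populations.
#' @param record_every recording interval in days (must be a multiple of
#'   `dt`).
#' @param rate_mode transition-rate convention passed to the state-chart
#'   builders, `"as_printed"` or `"ode_faithful"`.
#' @return An object of class `abm_config`.
#' @export
abm_config <- function(dt = 0.02, n_runs = 50, base_seed = 1L,
                       mode = c("count_based", "per_agent"),
                       record_every = 1,
                       rate_mode = c("as_printed", "ode_faithful")) {
  mode <- match.arg(mode)
  rate_mode <- match.arg(rate_mode)
  dt <- .check_scalar(dt, "dt", positive = TRUE)
  if (dt > 1) stop("'dt' must not exceed 1 day", call. = FALSE)
  record_every <- .check_scalar(record_every, "record_every", positive = TRUE)
  steps <- record_every / dt
  if (abs(steps - round(steps)) > 1e-9) {
    stop("'record_every' must be a whole multiple of 'dt'", call. = FALSE)
  }
  n_runs <- .check_scalar(n_runs, "n_runs", positive = TRUE)
  if (n_runs != round(n_runs)) stop("'n_runs' must be an integer", call. = FALSE)
  if (!is.numeric(base_seed) || length(base_seed) != 1L ||
      !is.finite(base_seed)) {
    stop("'base_seed' must be a single integer", call. = FALSE)
  }
  structure(
    list(dt = dt, n_runs = as.integer(n_runs),
         base_seed = as.integer(base_seed), mode = mode,
         record_every = record_every, rate_mode = rate_mode),
    class = "abm_config"
  )
}

.COUNT_CAP <- 1e9

#' Advance a state-chart population by one time step
#'
#' Rates are frozen at the step's start.  For each species with competing
#' rate transitions of per-agent rates `r_i` (total `R`) and `N` agents, the
#' number of firing agents is `Binomial(N, 1 - exp(-R dt))`, split
#' multinomially with weights `r_i / R` (`count_based` mode) or drawn as one
#' independent categorical outcome per agent (`per_agent` mode; the same
#' distribution).  Spawn actions add agents, branch firings add or remove the
#' firing agent according to the sign of the frozen signed rate, kill
#' messages are collected and applied after all rate draws in sender order
#' effector before tumour, each removing one uniformly chosen (exchangeable)
#' agent of the target species, surplus messages being dropped.  Global
#' events fire `Poisson(rate dt)` times.
#'
#' @param counts named non-negative integer vector over the chart's species.
#' @param chart a [statechart()] object.
#' @param dt step size in days.
#' @param mode `"count_based"` or `"per_agent"`.
#' @return The updated named integer count vector.
#' @export
abm_step <- function(counts, chart, dt, mode = c("count_based", "per_agent")) {
  if (length(mode) > 1L) mode <- mode[[1L]]
  if (!mode %in% c("count_based", "per_agent")) {
    stop("mode must be \"count_based\" or \"per_agent\"", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  species <- chart$species
  if (!identical(names(counts), species)) counts <- counts[species]
  n0 <- counts
  params <- chart$params
  by_species <- chart$by_species
  kills <- NULL   # sender species -> named vector of message counts
  for (sp in species) {
    N <- n0[[sp]]
    info <- by_species[[sp]]
    n_tr <- info$n
    if (N == 0 || n_tr == 0L) next
    fns <- info$rate_fns
    signed <- numeric(n_tr)
    for (k in seq_len(n_tr)) signed[k] <- fns[[k]](n0, params)
    if (any(!is.finite(signed))) {
      stop(sprintf("non-finite transition rate for species '%s'", sp),
           call. = FALSE)
    }
    is_branch <- info$is_branch
    rates <- signed
    rates[rates < 0] <- 0
    if (any(is_branch)) rates[is_branch] <- abs(signed[is_branch])
    R <- sum(rates)
    if (R <= 0) next
    p_fire <- -expm1(-R * dt)
    if (mode == "count_based") {
      nf <- stats::rbinom(1L, N, p_fire)
      fires <- if (nf > 0L) drop(stats::rmultinom(1L, nf, rates))
               else numeric(n_tr)
    } else {
      draw <- sample.int(n_tr + 1L, size = N, replace = TRUE,
                         prob = c(1 - p_fire, p_fire * rates / R))
      fires <- tabulate(draw, nbins = n_tr + 1L)[-1L]
    }
    action <- info$action
    target <- info$target
    for (k in seq_len(n_tr)) {
      if (fires[k] == 0) next
      act <- action[[k]]
      if (act == "branch") {
        counts[sp] <- counts[sp] + sign(signed[k]) * fires[k]
      } else if (act == "die") {
        counts[sp] <- counts[sp] - fires[k]
      } else if (act == "spawn") {
        counts[target[[k]]] <- counts[target[[k]]] + fires[k]
      } else { # kill: collect a message per firing
        prev <- kills[[sp]]
        if (is.null(prev)) prev <- numeric(0)
        prev[target[[k]]] <- sum(prev[target[[k]]], fires[k], na.rm = TRUE)
        if (is.null(kills)) kills <- list()
        kills[[sp]] <- prev
      }
    }
  }
  for (ev in chart$events) {
    if (ev$rate > 0) {
      counts[ev$spawn] <- counts[ev$spawn] + stats::rpois(1L, ev$rate * dt)
    }
  }
  if (!is.null(kills)) {
    # deliver kill messages, senders in fixed order (effectors first)
    for (sender in chart$sender_order) {
      msg <- kills[[sender]]
      if (is.null(msg)) next
      for (target in names(msg)) {
        counts[target] <- max(0, counts[target] - msg[[target]])
      }
    }
  }
  counts[counts < 0] <- 0
  if (any(counts > .COUNT_CAP)) {
    stop(sprintf("population overflow: species '%s' exceeded %g agents",
                 names(counts)[which.max(counts)], .COUNT_CAP), call. = FALSE)
  }
  counts
}

# run fn under a seeded, restored RNG state
.with_run_rng <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  force(expr)
}

#' Execute one agent-based run of a scenario
#'
#' Counts are recorded every `record_every` days from day 0 to the horizon.
#' Runs are reproducible: the RNG (L'Ecuyer-CMRG) is seeded with
#' `base_seed + run_index`, so the same seed yields a bit-identical
#' trajectory.  The caller's RNG state is left untouched.
#'
#' @param scenario a [scenario_spec()] object.
#' @param config an [abm_config()] object.
#' @param run_index zero-based run index within the ensemble.
#' @param chart optional pre-built [statechart()]; defaults to
#'   `build_statechart(scenario, config$rate_mode)`.
#' @return A [trajectory()] with `run_kind = "abm"` and integer counts.
#' @export
abm_run <- function(scenario, config = abm_config(), run_index = 0L,
                    chart = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"),
            inherits(config, "abm_config"))
  if (is.null(chart)) chart <- build_statechart(scenario, config$rate_mode)
  init <- scenario$initial_state
  if (any(init != floor(init))) {
    stop("agent-based runs need integer initial counts", call. = FALSE)
  }
  steps_per_rec <- as.integer(round(config$record_every / config$dt))
  n_rec <- as.integer(floor(scenario$horizon_days / config$record_every))
  rec_times <- seq(0, by = config$record_every, length.out = n_rec + 1L)
  seed <- config$base_seed + as.integer(run_index)
  values <- matrix(0, nrow = n_rec + 1L, ncol = length(chart$species),
                   dimnames = list(NULL, chart$species))
  .with_run_rng(seed, tryCatch({
    counts <- init[chart$species]
    values[1L, ] <- counts
    for (r in seq_len(n_rec)) {
      for (k in seq_len(steps_per_rec)) {
        counts <- abm_step(counts, chart, config$dt, config$mode)
      }
      values[r + 1L, ] <- counts
    }
  }, error = function(e) stop(sprintf("run %d failed: %s", run_index,
                                      conditionMessage(e)), call. = FALSE)))
  trajectory(rec_times, values, scenario$model_id, run_kind = "abm",
             run_seed = seed, run_index = as.integer(run_index))
}

#' Run a seeded ensemble of agent-based simulations
#'
#' Runs `config$n_runs` independent trajectories with seeds
#' `base_seed, ..., base_seed + n_runs - 1` and computes the per-day mean and
#' variance of every species.
#'
#' @param scenario a [scenario_spec()] object.
#' @param config an [abm_config()] object.
#' @return An object of class `abm_ensemble` with elements `runs` (list of
#'   trajectories), `time_days`, `mean` and `variance` (matrices over
#'   species), `n_runs`, `config` and `scenario_label`.
#' @export
run_ensemble <- function(scenario, config = abm_config()) {
  stopifnot(inherits(scenario, "scenario_spec"),
            inherits(config, "abm_config"))
  chart <- build_statechart(scenario, config$rate_mode)
  runs <- lapply(seq_len(config$n_runs) - 1L, function(i)
    abm_run(scenario, config, run_index = i, chart = chart))
  cube <- vapply(runs, function(r) r$values,
                 matrix(0, nrow(runs[[1]]$values), ncol(runs[[1]]$values)))
  mean_mat <- apply(cube, c(1, 2), mean)
  var_mat <- if (config$n_runs > 1) apply(cube, c(1, 2), stats::var)
             else mean_mat * 0
  dimnames(mean_mat) <- dimnames(var_mat) <-
    list(NULL, colnames(runs[[1]]$values))
  structure(
    list(runs = runs, time_days = runs[[1]]$time_days, mean = mean_mat,
         variance = var_mat, n_runs = config$n_runs, config = config,
         model_id = scenario$model_id, scenario_label = scenario$label),
    class = "abm_ensemble"
  )
}

#' @export
print.abm_ensemble <- function(x, ...) {
  cat(sprintf("<abm ensemble> scenario '%s', %d runs, %d samples, dt = %g\n",
              x$scenario_label, x$n_runs, length(x$time_days), x$config$dt))
  invisible(x)
}

#' Ensemble mean as a trajectory
#'
#' @param ensemble an `abm_ensemble`.
#' @return A [trajectory()] holding the per-day ensemble means (real-valued).
#' @export
ensemble_mean_trajectory <- function(ensemble) {
  stopifnot(inherits(ensemble, "abm_ensemble"))
  trajectory(ensemble$time_days, ensemble$mean, ensemble$model_id,
             run_kind = "abm", run_seed = ensemble$config$base_seed)
}
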