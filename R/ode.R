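# Deterministic integration of the model ODEs.

#' Integrate a scenario's ODE model
#'
#' Uses an adaptive stiff-capable solver (`deSolve`'s `lsoda`, which switches
#' between Adams and BDF methods); the TGF-beta model mixes per-day rates
#' spanning twelve orders of magnitude and is moderately stiff.  Output is
#' sampled on the requested grid (daily by default) through the solver's
#' dense output.  Tiny negative undershoot (above `-1e-9`) is clamped to
#' zero; anything more negative, and any non-finite state, raises an error
#' naming the failure time.
#'
#' @param scenario a [scenario_spec()] object.
#' @param times output time grid in days; defaults to `0:horizon_days`.
#' @param rtol,atol relative/absolute integration tolerances.
#' @return A [trajectory()] with `run_kind = "ode"`.
#' @examples
#' traj <- integrate_scenario(load_scenario("case1-s2"))
#' @export
integrate_scenario <- function(scenario, times = NULL,
                               rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (is.null(times)) times <- seq(0, scenario$horizon_days, by = 1)
  if (times[1] != 0 || max(times) > scenario$horizon_days) {
    stop("time grid must start at 0 and stay within the horizon",
         call. = FALSE)
  }
  rhs <- model_rhs(scenario$model_id)
  species <- model_species(scenario$model_id)
  f <- function(t, y, parms) {
    y <- pmax(y, 0)  # guard the RHS against solver micro-undershoot
    names(y) <- species
    list(unname(rhs(y, parms)))
  }
  out <- deSolve::ode(
    y = scenario$initial_state, times = times, func = f,
    parms = scenario$params, method = "lsoda", rtol = rtol, atol = atol
  )
  vals <- unname(out[, -1, drop = FALSE])
  colnames(vals) <- species
  if (nrow(vals) < length(times) || any(!is.finite(vals))) {
    bad <- if (nrow(vals) < length(times)) times[nrow(vals)]
           else min(out[which(!is.finite(vals), arr.ind = TRUE)[, 1], 1])
    stop(sprintf("integration failed (non-finite state) near t = %g days",
                 bad), call. = FALSE)
  }
  if (any(vals < -1e-9)) {
    bad <- min(out[which(vals < -1e-9, arr.ind = TRUE)[, 1], 1])
    stop(sprintf("integration produced negative abundances near t = %g days",
                 bad), call. = FALSE)
  }
  vals[vals < 0] <- 0
  trajectory(times, vals, scenario$model_id, run_kind = "ode")
}

#' Resample a trajectory onto the whole-day grid
#'
#' Keeps exactly one sample per whole day.  The input grid must contain every
#' whole day of its span (as adaptive integrations with daily or finer output
#' do); no interpolation is performed.  Already-daily trajectories pass
#' through unchanged.
#'
#' @param traj a [trajectory()] object.
#' @return A [trajectory()] sampled at days `0, 1, ..., floor(max time)`.
#' @export
sample_daily <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  days <- seq(0, floor(max(traj$time_days) + 1e-9))
  idx <- vapply(days, function(d) {
    i <- which(abs(traj$time_days - d) < 1e-9)
    if (length(i) == 0) NA_integer_ else i[1]
  }, integer(1))
  if (anyNA(idx)) {
    stop(sprintf("trajectory grid does not cover day(s): %s",
                 paste(days[is.na(idx)][seq_len(min(3, sum(is.na(idx))))],
                       collapse = ", ")), call. = FALSE)
  }
  trajectory(days, traj$values[idx, , drop = FALSE], traj$model_id,
             run_kind = traj$run_kind, run_seed = traj$run_seed,
             run_index = traj$run_index)
}

#' Estimate a steady-state plateau from the tail of a trajectory
#'
#' Returns the mean of the species' values over the final `window_days` days
#' if the relative range within that window ((max - min) / mean) is below 1
#' percent, and `NA` otherwise.  A window that is constant at zero counts as
#' a plateau at zero.
#'
#' @param traj a [trajectory()] object.
#' @param species species name.
#' @param window_days length of the tail window in days (must be shorter
#'   than the trajectory span).
#' @return The plateau estimate, or `NA_real_` when no plateau is detected.
#' @export
steady_state_value <- function(traj, species, window_days) {
  stopifnot(inherits(traj, "trajectory"))
  series <- trajectory_series(traj, species)
  span <- max(traj$time_days) - min(traj$time_days)
  if (window_days >= span) {
    stop("'window_days' must be shorter than the trajectory span",
         call. = FALSE)
  }
  keep <- traj$time_days >= max(traj$time_days) - window_days
  w <- series[keep]
  m <- mean(w)
  if (m == 0) return(if (max(w) == min(w)) 0 else NA_real_)
  rel_range <- (max(w) - min(w)) / m
  if (rel_range < 0.01) m else NA_real_
}
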