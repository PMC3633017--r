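# Trajectory container shared by the ODE and agent-based engines.

#' Construct a trajectory
#'
#' @param time_days numeric vector of sampling times (days, monotone
#'   increasing, starting at 0).
#' @param values numeric matrix, one row per time point, one column per
#'   species (canonical order).
#' @param model_id model identifier.
#' @param run_kind `"ode"` or `"abm"`.
#' @param run_seed RNG seed of the run (`NA` for ODE runs).
#' @param run_index index of the run within an ensemble (`NA` for ODE runs).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(time_days, values, model_id,
                       run_kind = c("ode", "abm"), run_seed = NA_integer_,
                       run_index = NA_integer_) {
  run_kind <- match.arg(run_kind)
  values <- as.matrix(values)
  if (length(time_days) != nrow(values)) {
    stop("time grid and value rows must have equal length", call. = FALSE)
  }
  if (is.unsorted(time_days, strictly = TRUE)) {
    stop("time grid must be strictly increasing", call. = FALSE)
  }
  if (any(values < 0)) stop("abundances must be non-negative", call. = FALSE)
  structure(
    list(time_days = as.numeric(time_days), values = values,
         model_id = model_id, run_kind = run_kind,
         run_seed = run_seed, run_index = run_index),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<%s trajectory> model %s, %d samples over [%g, %g] days\n",
              x$run_kind, x$model_id, length(x$time_days),
              min(x$time_days), max(x$time_days)))
  cat("  species:", paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  df <- data.frame(time_days = x$time_days, x$values, check.names = FALSE)
  if (x$run_kind == "abm") {
    df$run_index <- x$run_index
    df$seed <- x$run_seed
  }
  df
}

#' Extract one species' series from a trajectory
#'
#' @param traj a [trajectory()] object.
#' @param species species name.
#' @return Numeric vector aligned with `traj$time_days`.
#' @export
trajectory_series <- function(traj, species) {
  stopifnot(inherits(traj, "trajectory"))
  if (!species %in% colnames(traj$values)) {
    stop(sprintf("unknown species '%s'; trajectory has: %s", species,
                 paste(colnames(traj$values), collapse = ", ")), call. = FALSE)
  }
  traj$values[, species]
}
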