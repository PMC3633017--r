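# Deterministic on-disk formats: trajectory CSV, ensemble summary CSV and
# comparison-report JSON.  All files are UTF-8 with LF line endings and fixed
# column order (time first, then species in canonical T, E, I, S order).

#' Write a trajectory to CSV
#'
#' Columns: `time_days`, then one column per species; agent-based runs add
#' `run_index` and `seed`.
#'
#' @param traj a [trajectory()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  df <- as.data.frame(traj)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path file path.
#' @param model_id model identifier to attach.
#' @return A [trajectory()] object.
#' @export
read_trajectory_csv <- function(path, model_id) {
  df <- utils::read.csv(path, check.names = FALSE)
  abm <- "run_index" %in% names(df)
  species <- setdiff(names(df), c("time_days", "run_index", "seed"))
  trajectory(df$time_days, as.matrix(df[species]), model_id,
             run_kind = if (abm) "abm" else "ode",
             run_seed = if (abm) df$seed[1] else NA_integer_,
             run_index = if (abm) df$run_index[1] else NA_integer_)
}

#' Write an ensemble summary to CSV
#'
#' Long format with columns `time_days`, `species`, `mean`, `variance`,
#' `n_runs`.
#'
#' @param ensemble an `abm_ensemble` from [run_ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "abm_ensemble"))
  if (ensemble$n_runs < 1 || length(ensemble$runs) == 0) {
    stop("refusing to write an empty ensemble", call. = FALSE)
  }
  species <- colnames(ensemble$mean)
  df <- do.call(rbind, lapply(species, function(sp) data.frame(
    time_days = ensemble$time_days, species = sp,
    mean = ensemble$mean[, sp], variance = ensemble$variance[, sp],
    n_runs = ensemble$n_runs
  )))
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Write a comparison report (or report table) to JSON
#'
#' @param report a `comparison_report` or `report_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  payload <- if (inherits(report, "report_table")) {
    lapply(report$reports, unclass)
  } else if (inherits(report, "comparison_report")) {
    unclass(report)
  } else {
    stop("expected a comparison_report or report_table", call. = FALSE)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a comparison report written by [write_report_json()]
#'
#' @param path file path of a single-report JSON file.
#' @return A `comparison_report` object equal to the one written.
#' @export
read_report_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  raw$alpha <- as.numeric(raw$alpha)
  raw$n_runs <- as.integer(raw$n_runs)
  raw$seed <- as.integer(raw$seed)
  raw$sample_size_days <- as.integer(raw$sample_size_days)
  raw$species <- lapply(raw$species, function(sp) {
    if (!is.null(sp$p_value)) sp$p_value <- as.numeric(sp$p_value)
    if (!is.null(sp$rejection_fraction)) {
      sp$rejection_fraction <- as.numeric(sp$rejection_fraction)
    }
    sp
  })
  structure(raw, class = "comparison_report")
}
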