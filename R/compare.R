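# Statistical comparison of ODE and agent-based trajectories with the
# two-sided Wilcoxon rank-sum (Mann-Whitney) test.

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Uses the exact null distribution when both samples have at most 10
#' observations and there are no ties, and the normal approximation with tie
#' and continuity corrections otherwise.  Two samples whose pooled values are
#' all identical are indistinguishable and get p = 1.
#'
#' @param x,y numeric samples (non-empty).
#' @return The two-sided p-value in `[0, 1]`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # 0.1, exact
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(c(x, y)))) stop("samples must be finite", call. = FALSE)
  pooled <- c(x, y)
  if (max(pooled) == min(pooled)) return(1)
  ties <- anyDuplicated(pooled) > 0
  exact <- length(x) <= 10 && length(y) <= 10 && !ties
  res <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", exact = exact, correct = TRUE
  ))
  unname(min(1, res$p.value))
}

#' Compare an ODE trajectory with an agent-based ensemble
#'
#' The published comparison protocol: per species, sample `x` is the ODE
#' daily series and sample `y` the ensemble-mean daily series, tested with
#' the two-sided rank-sum test at significance level `alpha`
#' (`mode = "ensemble_mean"`).  `mode = "per_run"` instead tests every run
#' against the ODE series and reports the fraction of runs rejected.
#'
#' @param ode a daily-sampled ODE [trajectory()].
#' @param ensemble an `abm_ensemble` from [run_ensemble()] on the same model,
#'   horizon and daily grid.
#' @param alpha significance level (default 0.05).
#' @param mode `"ensemble_mean"` (default) or `"per_run"`.
#' @return An object of class `comparison_report`: per-species `p_value`
#'   (ensemble-mean mode), `rejection_fraction` (per-run mode) and
#'   `decision` (`"reject"` / `"fail-to-reject"`), plus metadata.
#' @export
compare_trajectories <- function(ode, ensemble, alpha = 0.05,
                                 mode = c("ensemble_mean", "per_run")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ode, "trajectory"), inherits(ensemble, "abm_ensemble"))
  if (!identical(ode$model_id, ensemble$model_id)) {
    stop("ODE and ensemble must come from the same model", call. = FALSE)
  }
  if (length(ode$time_days) != length(ensemble$time_days) ||
      any(abs(ode$time_days - ensemble$time_days) > 1e-9)) {
    stop("ODE and ensemble must share the same sampling grid", call. = FALSE)
  }
  species <- colnames(ode$values)
  if (length(species) == 0) stop("trajectory has no species", call. = FALSE)
  entries <- lapply(species, function(sp) {
    x <- ode$values[, sp]
    if (mode == "ensemble_mean") {
      p <- wilcoxon_rank_sum(x, ensemble$mean[, sp])
      list(name = sp, p_value = p,
           decision = if (p < alpha) "reject" else "fail-to-reject")
    } else {
      ps <- vapply(ensemble$runs, function(r)
        wilcoxon_rank_sum(x, r$values[, sp]), numeric(1))
      frac <- mean(ps < alpha)
      list(name = sp, rejection_fraction = frac,
           decision = if (frac > 0.5) "reject" else "fail-to-reject")
    }
  })
  structure(
    list(scenario = ensemble$scenario_label, mode = mode, alpha = alpha,
         n_runs = ensemble$n_runs, seed = ensemble$config$base_seed,
         sample_size_days = length(ode$time_days), species = entries),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison> scenario '%s', mode %s, alpha %g, %d runs\n",
              x$scenario, x$mode, x$alpha, x$n_runs))
  for (sp in x$species) {
    if (x$mode == "ensemble_mean") {
      cat(sprintf("  %-2s p = %.4f  (%s)\n", sp$name, sp$p_value, sp$decision))
    } else {
      cat(sprintf("  %-2s rejected in %.0f%% of runs  (%s)\n",
                  sp$name, 100 * sp$rejection_fraction, sp$decision))
    }
  }
  invisible(x)
}

#' Assemble several comparison reports into a summary table
#'
#' @param reports non-empty list of `comparison_report` objects.
#' @return An object of class `report_table` wrapping a data frame with one
#'   row per scenario and one column per species statistic; print it for a
#'   plain-text table, or serialise with [write_report_json()].
#' @export
build_report <- function(reports) {
  if (!is.list(reports) || length(reports) == 0) {
    stop("need a non-empty list of comparison reports", call. = FALSE)
  }
  if (inherits(reports, "comparison_report")) reports <- list(reports)
  rows <- lapply(reports, function(rep) {
    stopifnot(inherits(rep, "comparison_report"))
    vals <- lapply(rep$species, function(sp)
      if (rep$mode == "ensemble_mean") sp$p_value else sp$rejection_fraction)
    names(vals) <- vapply(rep$species, `[[`, character(1), "name")
    dec <- vapply(rep$species, `[[`, character(1), "decision")
    names(dec) <- paste0(names(vals), "_decision")
    c(list(scenario = rep$scenario, mode = rep$mode, alpha = rep$alpha,
           n_runs = rep$n_runs), vals, as.list(dec))
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  df <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    as.data.frame(r[all_cols], stringsAsFactors = FALSE)
  }))
  structure(list(table = df, reports = reports), class = "report_table")
}

#' @export
print.report_table <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}
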