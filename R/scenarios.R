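# Scenario handling: a scenario bundles a model id, a parameter set, an
# initial population state and a horizon.  Built-in scenarios ship as YAML
# resources under inst/extdata/scenarios and carry the published study
# conditions.

.builtin_labels <- c("case1-s1", "case1-s2", "case1-s3", "case1-s4",
                     "case2", "case3")

.params_constructor <- function(model_id) {
  switch(model_id,
    case0 = generic_growth_params,
    case1 = case1_params,
    case2 = case2_params,
    case3 = case3_params,
    stop("unknown model: ", model_id, call. = FALSE)
  )
}

#' Construct a simulation scenario
#'
#' @param model_id one of `"case0"`, `"case1"`, `"case2"`, `"case3"`.
#' @param params matching parameter object (see [case1_params()] etc.).
#' @param initial_state named abundances for every species of the model.
#' @param horizon_days positive integer simulation horizon in days.
#' @param label free-text scenario name.
#' @param provenance free text recording where the parameter values come from
#'   (published table versus external defaults); echoed into every run log.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(model_id, params, initial_state, horizon_days,
                          label = "custom", provenance = "user supplied") {
  model_id <- match.arg(model_id, c("case0", "case1", "case2", "case3"))
  if (!inherits(params, .params_class(model_id))) {
    stop(sprintf("params must be a %s object", .params_class(model_id)),
         call. = FALSE)
  }
  horizon_days <- .check_scalar(horizon_days, "horizon_days", positive = TRUE)
  if (horizon_days != round(horizon_days)) {
    stop("'horizon_days' must be a whole number of days", call. = FALSE)
  }
  st <- do.call(population_state,
                c(as.list(initial_state), list(model_id = model_id)))
  structure(
    list(model_id = model_id, label = label, params = params,
         initial_state = st, horizon_days = as.integer(horizon_days),
         provenance = provenance),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario '%s'> model %s, horizon %d days\n",
              x$label, x$model_id, x$horizon_days))
  cat("  initial state:",
      paste(sprintf("%s=%g", names(x$initial_state), x$initial_state),
            collapse = ", "), "\n")
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' List the built-in scenario labels
#'
#' @return Character vector of labels accepted by [load_scenario()].
#' @export
list_scenarios <- function() .builtin_labels

#' Load a built-in scenario or a scenario configuration file
#'
#' Built-in labels are the four effector-tumour treatment scenarios
#' (`case1-s1` .. `case1-s4`, 100-day horizon, initial `T = 50`, `E = 5`),
#' the effector/tumour/IL-2 scenario (`case2`, 600 days, `E = 10`, `T = 50`,
#' `I = 0`) and the TGF-beta scenario (`case3`, 600 days, `E = 1`, `T = 1`,
#' `I = 10`, `S = 0`).  Any other value is interpreted as a path to a YAML
#' scenario file (see [read_scenario()]).
#'
#' @param label built-in label or file path.
#' @return A [scenario_spec()] object.
#' @examples
#' load_scenario("case1-s2")$params$b  # 0.004
#' @export
load_scenario <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  if (label %in% .builtin_labels) {
    path <- system.file("extdata", "scenarios", paste0(label, ".yaml"),
                        package = "oncoabm", mustWork = TRUE)
    return(read_scenario(path))
  }
  if (file.exists(label)) return(read_scenario(label))
  stop(sprintf(
    "unknown scenario '%s' (not a built-in label and no such file); available built-ins: %s",
    label, paste(.builtin_labels, collapse = ", ")), call. = FALSE)
}

#' Read a scenario from a YAML configuration file
#'
#' The file must contain the sections `model`, `params`, `initial_state` and
#' `horizon_days`; `label` and `provenance` are optional.  Unknown sections or
#' unknown parameter names are rejected.
#'
#' @param path file path.
#' @return A [scenario_spec()] object.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("no such scenario file: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop(sprintf("malformed scenario file '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  allowed <- c("model", "label", "params", "initial_state", "horizon_days",
               "provenance")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(c("model", "params", "initial_state", "horizon_days"),
                     names(raw))
  if (length(missing) > 0) {
    stop("scenario file misses required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  # YAML 1.1 treats bare y/n keys as booleans, so the case-1 parameter
  # `n` comes back named "FALSE"; undo that before validation.
  names(raw$params)[names(raw$params) == "FALSE"] <- "n"
  names(raw$params)[names(raw$params) == "TRUE"] <- "y"
  ctor <- .params_constructor(raw$model)
  bad <- setdiff(names(raw$params), names(formals(ctor)))
  if (length(bad) > 0) {
    stop(sprintf("unknown parameter(s) for model '%s': %s",
                 raw$model, paste(bad, collapse = ", ")), call. = FALSE)
  }
  params <- do.call(ctor, raw$params)
  scenario_spec(
    model_id = raw$model,
    params = params,
    initial_state = unlist(raw$initial_state),
    horizon_days = raw$horizon_days,
    label = if (is.null(raw$label)) basename(path) else raw$label,
    provenance = if (is.null(raw$provenance)) "user supplied" else raw$provenance
  )
}

#' Write a scenario to a YAML configuration file
#'
#' Scenarios round-trip: reading a written file reproduces the scenario.
#'
#' @param scenario a [scenario_spec()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario_spec"))
  out <- list(
    model = scenario$model_id,
    label = scenario$label,
    horizon_days = scenario$horizon_days,
    params = lapply(unclass(scenario$params), identity),
    initial_state = as.list(scenario$initial_state),
    provenance = scenario$provenance
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
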