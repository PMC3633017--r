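# Declarative state-chart models.  A state chart lists species, per-species
# transitions and global injection events.  Rate-triggered transitions fire as
# Poisson streams whose per-agent intensity may depend on the global
# population counts; message-triggered transitions fire when a kill message
# arrives from a sender species.

#' Declare a state-chart transition
#'
#' @param species species the transition belongs to.
#' @param name transition name.
#' @param type `"rate"` (Poisson stream per agent), `"branch"` (a single
#'   Poisson stream of intensity `|rate|` whose firing is a birth when the
#'   signed rate is positive and a death when it is negative), or
#'   `"message"` (fires on receipt of a kill message; the agent dies).
#' @param rate for `"rate"`/`"branch"`: a function `f(counts, params)`
#'   returning the per-agent intensity (signed for `"branch"`); ignored for
#'   `"message"`.
#' @param action for `"rate"` transitions: `"die"` (the firing agent is
#'   removed), `"spawn"` (one agent of `target` is created, the firing agent
#'   survives) or `"kill"` (a kill message is sent to one uniformly chosen
#'   agent of `target`, the firing agent survives).
#' @param target target species for `"spawn"`/`"kill"` actions.
#' @param message_from sender species for `"message"` transitions.
#' @return A transition description (list).
#' @export
sc_transition <- function(species, name,
                          type = c("rate", "branch", "message"),
                          rate = NULL,
                          action = c("die", "spawn", "kill"),
                          target = NULL, message_from = NULL) {
  type <- match.arg(type)
  if (type == "message") {
    if (is.null(message_from)) stop("message transition needs 'message_from'")
    return(structure(list(species = species, name = name, type = type,
                          message_from = message_from),
                     class = "sc_transition"))
  }
  if (!is.function(rate)) stop("rate/branch transition needs a rate function")
  if (type == "branch") {
    action <- "branch"
  } else {
    action <- match.arg(action)
    if (action %in% c("spawn", "kill") && is.null(target)) {
      stop(sprintf("'%s' action needs a target species", action))
    }
  }
  structure(list(species = species, name = name, type = type, rate = rate,
                 action = action, target = target),
            class = "sc_transition")
}

#' Declare a global injection event
#'
#' Global events model treatment: a Poisson stream of constant intensity that
#' spawns agents irrespective of current populations.
#'
#' @param name event name.
#' @param rate constant intensity (firings per day).
#' @param spawn species spawned by each firing.
#' @return An event description (list).
#' @export
sc_event <- function(name, rate, spawn) {
  structure(list(name = name, rate = .check_scalar(rate, "rate"),
                 spawn = spawn), class = "sc_event")
}

#' Assemble a state-chart model
#'
#' @param species character vector of species names in recording order.
#' @param transitions list of [sc_transition()] objects.
#' @param events list of [sc_event()] objects.
#' @param params parameter object passed to every rate function.
#' @param model_id free-text model identifier.
#' @param rate_mode annotation of the transition-rate convention in use
#'   (`"as_printed"` or `"ode_faithful"`).
#' @return An object of class `statechart`.
#' @export
statechart <- function(species, transitions, events = list(), params,
                       model_id = "custom", rate_mode = "as_printed") {
  stopifnot(is.character(species), length(species) >= 1L)
  for (tr in transitions) {
    if (!inherits(tr, "sc_transition")) stop("transitions must be sc_transition objects")
    if (!tr$species %in% species) {
      stop(sprintf("transition '%s' names unknown species '%s'",
                   tr$name, tr$species))
    }
    if (!is.null(tr$target) && !tr$target %in% species) {
      stop(sprintf("transition '%s' targets unknown species '%s'",
                   tr$name, tr$target))
    }
  }
  for (ev in events) {
    if (!inherits(ev, "sc_event")) stop("events must be sc_event objects")
    if (!ev$spawn %in% species) {
      stop(sprintf("event '%s' spawns unknown species '%s'", ev$name, ev$spawn))
    }
  }
  # every kill action must have a message-triggered receiver on its target
  receivers <- vapply(transitions, function(tr)
    if (tr$type == "message") tr$species else NA_character_, character(1))
  for (tr in transitions) {
    if (tr$type != "message" && identical(tr$action, "kill") &&
        !tr$target %in% receivers) {
      stop(sprintf("kill action '%s' has no message-triggered transition on '%s'",
                   tr$name, tr$target))
    }
  }
  by_species <- lapply(setNames(species, species), function(sp) {
    trs <- Filter(function(tr) tr$species == sp && tr$type != "message",
                  transitions)
    # flatten the per-species transition data for the simulation hot path
    list(
      transitions = trs,
      n = length(trs),
      rate_fns = lapply(trs, `[[`, "rate"),
      is_branch = vapply(trs, function(tr) tr$type == "branch", logical(1)),
      action = vapply(trs, `[[`, character(1), "action"),
      target = vapply(trs, function(tr)
        if (is.null(tr$target)) NA_character_ else tr$target, character(1))
    )
  })
  structure(
    list(species = species, transitions = transitions, events = events,
         params = params, model_id = model_id, rate_mode = rate_mode,
         by_species = by_species,
         sender_order = intersect(c("E", "T", "I", "S"), species)),
    class = "statechart"
  )
}

#' @export
print.statechart <- function(x, ...) {
  cat(sprintf("<statechart> model %s (%s rates), species: %s\n",
              x$model_id, x$rate_mode, paste(x$species, collapse = ", ")))
  for (tr in x$transitions) {
    cat(sprintf("  %s/%s [%s]%s\n", tr$species, tr$name, tr$type,
                if (!is.null(tr$target)) paste0(" -> ", tr$target) else ""))
  }
  for (ev in x$events) {
    cat(sprintf("  event %s: rate %g -> %s\n", ev$name, ev$rate, ev$spawn))
  }
  invisible(x)
}

#' Evaluate per-agent transition rates of a state chart
#'
#' Rates are evaluated at the supplied counts; `"branch"` transitions report
#' their signed rate, all others are clamped at zero from below.
#'
#' @param chart a [statechart()] object.
#' @param counts named count vector over the chart's species.
#' @return Data frame with columns `species`, `name`, `type`, `rate`.
#' @export
statechart_rates <- function(chart, counts) {
  stopifnot(inherits(chart, "statechart"))
  counts <- counts[chart$species]
  trs <- Filter(function(tr) tr$type != "message", chart$transitions)
  data.frame(
    species = vapply(trs, `[[`, character(1), "species"),
    name = vapply(trs, `[[`, character(1), "name"),
    type = vapply(trs, `[[`, character(1), "type"),
    rate = vapply(trs, function(tr) {
      r <- tr$rate(counts, chart$params)
      if (!is.finite(r)) stop(sprintf("rate of '%s' is not finite", tr$name))
      if (tr$type == "branch") r else max(0, r)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Mean-field drift of a state chart
#'
#' Expected instantaneous net flow per species implied by the transition
#' rates: each firing contributes its action's population change (branch:
#' plus or minus one on the own species, die: minus one, spawn: plus one on
#' the target, kill: minus one on the target), weighted by the per-agent rate
#' times the current count; global events add their constant rate.  For
#' charts built in `ode_faithful` mode this equals the ODE right-hand side.
#'
#' @param chart a [statechart()] object.
#' @param counts named count vector.
#' @return Named numeric drift vector over the chart's species.
#' @export
statechart_drift <- function(chart, counts) {
  counts <- counts[chart$species]
  drift <- setNames(numeric(length(chart$species)), chart$species)
  for (tr in chart$transitions) {
    if (tr$type == "message") next
    r <- tr$rate(counts, chart$params)
    n <- counts[[tr$species]]
    if (tr$type == "branch") {
      drift[tr$species] <- drift[tr$species] + n * r
    } else {
      flow <- n * max(0, r)
      drift <- switch(tr$action,
        die = { drift[tr$species] <- drift[tr$species] - flow; drift },
        spawn = { drift[tr$target] <- drift[tr$target] + flow; drift },
        kill = { drift[tr$target] <- drift[tr$target] - flow; drift }
      )
    }
  }
  for (ev in chart$events) drift[ev$spawn] <- drift[ev$spawn] + ev$rate
  drift
}

# ---- model-specific builders ------------------------------------------------

#' State chart of the generic tumour growth model
#'
#' Single tumour agent class with a proliferate/die branch of signed
#' per-agent rate `a T^alpha - b T^beta`.
#'
#' @param params a [generic_growth_params()] object.
#' @return A [statechart()] object.
#' @export
build_generic_statechart <- function(params) {
  stopifnot(inherits(params, "generic_growth_params"))
  statechart(
    species = "T",
    transitions = list(
      sc_transition("T", "proliferateOrDie", type = "branch",
        rate = function(n, p) {
          T <- n[["T"]]
          p$a * T^p$alpha - p$b * T^p$beta
        })
    ),
    params = params, model_id = "case0", rate_mode = "ode_faithful"
  )
}

#' State chart of the effector-tumour model
#'
#' Tumour agents proliferate or die through a branch of signed rate
#' `a - b T_total`, die under effector attack at rate `n E_total`, and damage
#' effectors (`causeEffectorDamage`), each firing sending a kill message to
#' one uniformly chosen effector.  Effector agents proliferate at rate
#' `p T_total / (g + T_total)`, die with age at rate `d` and die on a kill
#' message from a tumour agent.  Treatment is a global Poisson event of rate
#' `s` spawning effectors.
#'
#' In the published agent formulation (`rate_mode = "as_printed"`) the
#' per-tumour-agent damage rate is the bare constant `m`, which aggregates to
#' `m T` rather than the ODE term `m T E`, and the proliferate/die branch
#' uses the signed rate `a - b T` rather than the logistic factor
#' `a (1 - b T)`; `rate_mode = "ode_faithful"` uses `m E_total` and
#' `a (1 - b T_total)` instead, restoring the aggregate match.
#'
#' @param params a [case1_params()] object.
#' @param rate_mode `"as_printed"` (default) or `"ode_faithful"`.
#' @return A [statechart()] object.
#' @export
build_case1_statechart <- function(params,
                                   rate_mode = c("as_printed", "ode_faithful")) {
  stopifnot(inherits(params, "case1_params"))
  rate_mode <- match.arg(rate_mode)
  damage_rate <- if (rate_mode == "as_printed") {
    function(n, p) p$m
  } else {
    function(n, p) p$m * n[["E"]]
  }
  statechart(
    species = c("T", "E"),
    transitions = list(
      sc_transition("T", "proliferateOrDie", type = "branch",
        rate = if (rate_mode == "as_printed") {
          function(n, p) p$a - p$b * n[["T"]]
        } else {
          function(n, p) p$a * (1 - p$b * n[["T"]])
        }),
      sc_transition("T", "dieKilledByEffectorCells", rate = function(n, p)
        p$n * n[["E"]], action = "die"),
      sc_transition("T", "causeEffectorDamage", rate = damage_rate,
        action = "kill", target = "E"),
      sc_transition("E", "Proliferation", rate = function(n, p)
        p$p * n[["T"]] / (p$g + n[["T"]]), action = "spawn", target = "E"),
      sc_transition("E", "DieWithAge", rate = function(n, p) p$d,
        action = "die"),
      sc_transition("E", "DiePerApoptosis", type = "message",
        message_from = "T")
    ),
    events = list(sc_event("treatment", params$s, "E")),
    params = params, model_id = "case1", rate_mode = rate_mode
  )
}

#' State chart of the effector/tumour/IL-2 model
#'
#' The recruitment term `c T` is realised as a tumour-agent transition of
#' rate `c` that spawns one effector.  The tumour proliferate/die branch uses
#' the published signed rate `a - b T` in `"as_printed"` mode and the
#' logistic ODE form `a (1 - b T)` in `"ode_faithful"` mode (the two differ
#' by `(1 - a) b T`, negligible far below the carrying capacity); all other
#' rates aggregate exactly to their ODE flow terms in both modes.
#'
#' @param params a [case2_params()] object.
#' @param rate_mode `"as_printed"` (default) or `"ode_faithful"`.
#' @return A [statechart()] object.
#' @export
build_case2_statechart <- function(params,
                                   rate_mode = c("as_printed", "ode_faithful")) {
  stopifnot(inherits(params, "case2_params"))
  rate_mode <- match.arg(rate_mode)
  statechart(
    species = c("T", "E", "I"),
    transitions = list(
      sc_transition("E", "Reproduce", rate = function(n, p)
        p$p1 * n[["I"]] / (p$g1 + n[["I"]]), action = "spawn", target = "E"),
      sc_transition("E", "Die", rate = function(n, p) p$mu2, action = "die"),
      sc_transition("E", "killTumour", rate = function(n, p)
        p$aa * n[["T"]] / (p$g2 + n[["T"]]), action = "kill", target = "T"),
      sc_transition("E", "ProduceIL2", rate = function(n, p)
        p$p2 * n[["T"]] / (p$g3 + n[["T"]]), action = "spawn", target = "I"),
      sc_transition("T", "proliferateOrDie", type = "branch",
        rate = if (rate_mode == "as_printed") {
          function(n, p) p$a - p$b * n[["T"]]
        } else {
          function(n, p) p$a * (1 - p$b * n[["T"]])
        }),
      sc_transition("T", "DieKilledByEffector", type = "message",
        message_from = "E"),
      sc_transition("T", "InduceRecruitment", rate = function(n, p) p$c,
        action = "spawn", target = "E"),
      sc_transition("I", "Loss", rate = function(n, p) p$mu3, action = "die")
    ),
    events = list(sc_event("TreatmentS1", params$s1, "E"),
                  sc_event("TreatmentS2", params$s2, "I")),
    params = params, model_id = "case2", rate_mode = rate_mode
  )
}

#' State chart of the effector/tumour/IL-2/TGF-beta model
#'
#' Effector proliferation uses the published bracket
#' `[p1 I/(g1+I)] [p1 - q1 S/(q2+S)]`, clamped at zero from below (a Poisson
#' intensity cannot be negative).  In `ode_faithful` mode the clamped excess
#' is routed to an additional effector death transition so that the aggregate
#' drift still matches the ODE term.  TGF-beta driven tumour growth
#' (`StimulatesTumourGrowth`) uses the published per-TGF-agent rate
#' `p2 S/(g3+S)` in `"as_printed"` mode (aggregate `p2 S^2/(g3+S)`) and
#' `p2 T/(g3+S)` in `"ode_faithful"` mode (aggregate `p2 S T/(g3+S)`, the ODE
#' term).
#'
#' @param params a [case3_params()] object.
#' @param rate_mode `"as_printed"` (default) or `"ode_faithful"`.
#' @return A [statechart()] object.
#' @export
build_case3_statechart <- function(params,
                                   rate_mode = c("as_printed", "ode_faithful")) {
  stopifnot(inherits(params, "case3_params"))
  rate_mode <- match.arg(rate_mode)
  bracket <- function(n, p) p$p1 - p$q1 * n[["S"]] / (p$q2 + n[["S"]])
  il2_factor <- function(n, p) p$p1 * n[["I"]] / (p$g1 + n[["I"]])
  stim_rate <- if (rate_mode == "as_printed") {
    function(n, p) p$p2 * n[["S"]] / (p$g3 + n[["S"]])
  } else {
    function(n, p) p$p2 * n[["T"]] / (p$g3 + n[["S"]])
  }
  transitions <- list(
    sc_transition("E", "Reproduce", rate = function(n, p)
      max(0, il2_factor(n, p) * bracket(n, p)), action = "spawn",
      target = "E"),
    sc_transition("E", "Die", rate = function(n, p) p$mu1, action = "die"),
    sc_transition("E", "ProduceIL2", rate = function(n, p)
      p$p3 * n[["T"]] / ((p$g4 + n[["T"]]) * (1 + p$alpha * n[["S"]])),
      action = "spawn", target = "I"),
    sc_transition("E", "KillTumour", rate = function(n, p)
      p$aa * n[["T"]] / (p$g2 + n[["T"]]), action = "kill", target = "T"),
    sc_transition("T", "proliferateOrDie", type = "branch",
      rate = function(n, p) p$a * (1 - n[["T"]] / p$K)),
    sc_transition("T", "DieKilledByEffector", type = "message",
      message_from = "E"),
    sc_transition("T", "ProduceTGF", rate = function(n, p)
      p$p4 * n[["T"]] / (p$theta^2 + n[["T"]]^2), action = "spawn",
      target = "S"),
    sc_transition("T", "EffectorRecruitment", rate = function(n, p)
      p$c / (1 + p$gamma * n[["S"]]), action = "spawn", target = "E"),
    sc_transition("I", "Loss", rate = function(n, p) p$mu2, action = "die"),
    sc_transition("S", "Loss", rate = function(n, p) p$mu3, action = "die"),
    sc_transition("S", "StimulatesTumourGrowth", rate = stim_rate,
      action = "spawn", target = "T")
  )
  if (rate_mode == "ode_faithful") {
    transitions <- c(transitions, list(
      sc_transition("E", "InhibitionExcessDeath", rate = function(n, p)
        max(0, -il2_factor(n, p) * bracket(n, p)), action = "die")
    ))
  }
  statechart(
    species = c("T", "E", "I", "S"),
    transitions = transitions,
    params = params, model_id = "case3", rate_mode = rate_mode
  )
}

#' State chart for a scenario
#'
#' @param scenario a [scenario_spec()] object.
#' @param rate_mode `"as_printed"` or `"ode_faithful"`.
#' @return A [statechart()] object for the scenario's model and parameters.
#' @export
build_statechart <- function(scenario,
                             rate_mode = c("as_printed", "ode_faithful")) {
  stopifnot(inherits(scenario, "scenario_spec"))
  rate_mode <- match.arg(rate_mode)
  switch(scenario$model_id,
    case0 = build_generic_statechart(scenario$params),
    case1 = build_case1_statechart(scenario$params, rate_mode),
    case2 = build_case2_statechart(scenario$params, rate_mode),
    case3 = build_case3_statechart(scenario$params, rate_mode)
  )
}
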