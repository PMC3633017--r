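# ODE right-hand sides for the four models.  States are named numeric vectors
# in canonical species order (see model_species()).

.check_state <- function(state, species) {
  if (is.null(names(state)) || !setequal(names(state), species)) {
    stop(sprintf("state must name exactly: %s", paste(species, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!is.finite(state))) stop("state must be finite", call. = FALSE)
  if (any(state < 0)) stop("state abundances must be non-negative", call. = FALSE)
  state[species]
}

#' Growth rate of the generic single-population tumour model
#'
#' Evaluates `dT/dt = T (a T^alpha - b T^beta)`.
#'
#' @param T tumour abundance (non-negative scalar or vector).
#' @param params a [generic_growth_params()] object.
#' @return `dT/dt`, same length as `T`.
#' @examples
#' generic_growth_rhs(100, generic_growth_params(0.5, 0, 0.005, 1)) # 0
#' @export
generic_growth_rhs <- function(T, params) {
  stopifnot(inherits(params, "generic_growth_params"))
  if (any(!is.finite(T)) || any(T < 0)) {
    stop("tumour abundance must be finite and non-negative", call. = FALSE)
  }
  T * (params$a * T^params$alpha - params$b * T^params$beta)
}

#' Derivatives of the effector-tumour model
#'
#' @param state named numeric vector with components `T` and `E`.
#' @param params a [case1_params()] object.
#' @return Named derivative vector `c(T = dT/dt, E = dE/dt)`.
#' @examples
#' p <- case1_params(b = 0.002, d = 0.1908, s = 0.318)
#' case1_rhs(c(T = 50, E = 5), p)
#' @export
case1_rhs <- function(state, params) {
  stopifnot(inherits(params, "case1_params"))
  st <- .check_state(state, c("T", "E"))
  T <- st[["T"]]; E <- st[["E"]]
  c(
    T = params$a * T * (1 - params$b * T) - params$n * T * E,
    E = params$p * T * E / (params$g + T) - params$m * T * E -
      params$d * E + params$s
  )
}

#' Derivatives of the effector/tumour/IL-2 model
#'
#' The tumour equation uses logistic growth `a T (1 - b T)` by default
#' (the form consistent with the agent transition rates); `growth =
#' "no_leading_T"` selects the variant `a (1 - b T)` in which the leading
#' tumour factor is dropped, for sensitivity checks.
#'
#' @param state named numeric vector with components `T`, `E` and `I`.
#' @param params a [case2_params()] object.
#' @param growth tumour growth form, `"logistic"` (default) or
#'   `"no_leading_T"`.
#' @return Named derivative vector over `T`, `E`, `I`.
#' @examples
#' case2_rhs(c(T = 50, E = 10, I = 0), case2_params())
#' @export
case2_rhs <- function(state, params, growth = c("logistic", "no_leading_T")) {
  stopifnot(inherits(params, "case2_params"))
  growth <- match.arg(growth)
  st <- .check_state(state, c("T", "E", "I"))
  T <- st[["T"]]; E <- st[["E"]]; I <- st[["I"]]
  grow <- if (growth == "logistic") params$a * T * (1 - params$b * T)
          else params$a * (1 - params$b * T)
  c(
    T = grow - params$aa * E * T / (params$g2 + T),
    E = params$c * T - params$mu2 * E +
      params$p1 * E * I / (params$g1 + I) + params$s1,
    I = params$p2 * E * T / (params$g3 + T) - params$mu3 * I + params$s2
  )
}

#' Derivatives of the effector/tumour/IL-2/TGF-beta model
#'
#' @param state named numeric vector with components `T`, `E`, `I`, `S`.
#' @param params a [case3_params()] object.
#' @return Named derivative vector over `T`, `E`, `I`, `S`.
#' @examples
#' case3_rhs(c(T = 1, E = 1, I = 10, S = 0), case3_params())
#' @export
case3_rhs <- function(state, params) {
  stopifnot(inherits(params, "case3_params"))
  st <- .check_state(state, c("T", "E", "I", "S"))
  T <- st[["T"]]; E <- st[["E"]]; I <- st[["I"]]; S <- st[["S"]]
  c(
    T = params$a * T * (1 - T / params$K) -
      params$aa * E * T / (params$g2 + T) +
      params$p2 * S * T / (params$g3 + S),
    E = params$c * T / (1 + params$gamma * S) - params$mu1 * E +
      (params$p1 * E * I / (params$g1 + I)) *
        (params$p1 - params$q1 * S / (params$q2 + S)),
    I = params$p3 * E * T / ((params$g4 + T) * (1 + params$alpha * S)) -
      params$mu2 * I,
    S = params$p4 * T^2 / (params$theta^2 + T^2) - params$mu3 * S
  )
}

#' Right-hand side function for a model identifier
#'
#' @param model_id one of `"case0"`, `"case1"`, `"case2"`, `"case3"`.
#' @return A function `f(state, params)` returning the named derivative
#'   vector (for `"case0"` the state is the single-element vector `c(T = .)`).
#' @export
model_rhs <- function(model_id) {
  switch(match.arg(model_id, c("case0", "case1", "case2", "case3")),
    case0 = function(state, params) {
      st <- .check_state(state, "T")
      c(T = generic_growth_rhs(st[["T"]], params))
    },
    case1 = case1_rhs,
    case2 = function(state, params) case2_rhs(state, params),
    case3 = case3_rhs
  )
}
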