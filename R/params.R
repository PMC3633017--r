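# ---- validation helpers -----------------------------------------------------

.check_scalar <- function(x, name, nonneg = TRUE, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("parameter '%s' must be a single finite number", name),
         call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("parameter '%s' must be > 0", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("parameter '%s' must be >= 0", name), call. = FALSE)
  }
  as.numeric(x)
}

.new_params <- function(fields, class) {
  structure(fields, class = c(class, "oncoabm_params"))
}

#' Parameters of the generic single-population tumour growth model
#'
#' The generic model is `dT/dt = T (p(T) - d(T))` with power-law proliferation
#' `p(T) = a T^alpha` and death `d(T) = b T^beta`.  Setting `alpha = 0`,
#' `beta = 1` recovers logistic growth with rate `a` and carrying capacity
#' `a / b`.
#'
#' @param a proliferation coefficient (per day).
#' @param alpha proliferation power exponent (dimensionless, may be any
#'   finite value).
#' @param b death coefficient (per day).
#' @param beta death power exponent (dimensionless).
#' @return An object of class `generic_growth_params`.
#' @examples
#' generic_growth_params(a = 0.5, alpha = 0, b = 0.005, beta = 1)
#' @export
generic_growth_params <- function(a, alpha, b, beta) {
  if (!is.numeric(alpha) || !is.finite(alpha)) stop("'alpha' must be finite")
  if (!is.numeric(beta) || !is.finite(beta)) stop("'beta' must be finite")
  .new_params(list(
    a = .check_scalar(a, "a"),
    alpha = as.numeric(alpha),
    b = .check_scalar(b, "b"),
    beta = as.numeric(beta)
  ), "generic_growth_params")
}

#' Parameters of the effector-tumour model (Kuznetsov type)
#'
#' Two-population model of tumour cells `T` attacked by generic immune
#' effector cells `E`:
#' \deqn{dT/dt = a T (1 - b T) - n T E}
#' \deqn{dE/dt = p T E / (g + T) - m T E - d E + s}
#'
#' The published study scenarios only vary `b` (tumour crowding), `d`
#' (effector apoptosis) and `s` (treatment influx of effector cells);
#' the remaining constants default to the dimensionless parameterisation of
#' Kuznetsov et al. (1994), from which the scenario values are drawn.
#'
#' @param a tumour intrinsic growth rate (per day).
#' @param b tumour density-death (inverse carrying capacity) coefficient
#'   (per cell).
#' @param n effector kill-rate coefficient (per cell per day).
#' @param p maximum effector proliferation rate (per day).
#' @param g half-saturation tumour load for effector proliferation (cells).
#' @param m effector damage coefficient from fighting tumour cells
#'   (per cell per day).
#' @param d effector apoptosis rate (per day).
#' @param s treatment influx of effector cells (cells per day).
#' @return An object of class `case1_params`.
#' @references Kuznetsov VA, Makalkin IA, Taylor MA, Perelson AS (1994).
#'   Nonlinear dynamics of immunogenic tumors. Bull Math Biol 56:295-321.
#' @export
case1_params <- function(b, d, s, a = 1.636, n = 1, p = 1.131,
                         g = 20.19, m = 0.00311) {
  .new_params(list(
    a = .check_scalar(a, "a"),
    b = .check_scalar(b, "b"),
    n = .check_scalar(n, "n"),
    p = .check_scalar(p, "p"),
    g = .check_scalar(g, "g", positive = TRUE),
    m = .check_scalar(m, "m"),
    d = .check_scalar(d, "d"),
    s = .check_scalar(s, "s")
  ), "case1_params")
}

#' Parameters of the effector/tumour/IL-2 model (Kirschner-Panetta type)
#'
#' Three-population model coupling effector cells `E`, tumour cells `T` and
#' the stimulatory cytokine IL-2 (`I`):
#' \deqn{dE/dt = c T - \mu_2 E + p_1 E I / (g_1 + I) + s_1}
#' \deqn{dT/dt = a T (1 - b T) - a_a E T / (g_2 + T)}
#' \deqn{dI/dt = p_2 E T / (g_3 + T) - \mu_3 I + s_2}
#'
#' Defaults are the published parameterisation of the untreated
#' high-antigenicity regime (`s1 = s2 = 0`).
#'
#' @param c antigenicity: recruitment of effectors per tumour cell (per day).
#' @param mu2 effector death rate (per day).
#' @param p1 IL-2 driven effector proliferation rate (per day).
#' @param g1 IL-2 half-saturation for proliferation (molecules).
#' @param s1 treatment influx of effector cells (cells per day).
#' @param a tumour intrinsic growth rate (per day).
#' @param b inverse tumour carrying capacity (per cell).
#' @param aa strength of the immune kill response (per day).
#' @param g2 tumour half-saturation of the kill term (cells).
#' @param p2 IL-2 production rate (per day).
#' @param g3 tumour half-saturation of IL-2 production (cells).
#' @param mu3 IL-2 loss rate (per day).
#' @param s2 treatment influx of IL-2 (molecules per day).
#' @return An object of class `case2_params`.
#' @references Kirschner D, Panetta JC (1998). Modeling immunotherapy of the
#'   tumor-immune interaction. J Math Biol 37:235-252.
#' @export
case2_params <- function(c = 0.05, mu2 = 0.03, p1 = 0.1245, g1 = 2e7,
                         s1 = 0, a = 0.18, b = 1e-9, aa = 1, g2 = 1e5,
                         p2 = 5, g3 = 1000, mu3 = 10, s2 = 0) {
  .new_params(list(
    c = .check_scalar(c, "c"),
    mu2 = .check_scalar(mu2, "mu2"),
    p1 = .check_scalar(p1, "p1"),
    g1 = .check_scalar(g1, "g1", positive = TRUE),
    s1 = .check_scalar(s1, "s1"),
    a = .check_scalar(a, "a"),
    b = .check_scalar(b, "b"),
    aa = .check_scalar(aa, "aa"),
    g2 = .check_scalar(g2, "g2", positive = TRUE),
    p2 = .check_scalar(p2, "p2"),
    g3 = .check_scalar(g3, "g3", positive = TRUE),
    mu3 = .check_scalar(mu3, "mu3"),
    s2 = .check_scalar(s2, "s2")
  ), "case2_params")
}

#' Parameters of the effector/tumour/IL-2/TGF-beta model (Arciero type)
#'
#' Four-population model adding the immunosuppressive cytokine TGF-beta (`S`)
#' which inhibits effector recruitment, proliferation and IL-2 production
#' while stimulating tumour growth:
#' \deqn{dE/dt = c T / (1 + \gamma S) - \mu_1 E +
#'   [p_1 E I / (g_1 + I)] [p_1 - q_1 S / (q_2 + S)]}
#' \deqn{dT/dt = a T (1 - T/K) - a_a E T / (g_2 + T) + p_2 S T / (g_3 + S)}
#' \deqn{dI/dt = p_3 E T / ((g_4 + T)(1 + \alpha S)) - \mu_2 I}
#' \deqn{dS/dt = p_4 T^2 / (\theta^2 + T^2) - \mu_3 S}
#'
#' TGF-beta production switches on around the critical tumour size `theta`
#' (oxygen starvation proxy).  The proliferation bracket is implemented
#' exactly in the published form, including the leading `p1` inside the
#' bracket product.
#'
#' @param c antigenicity (per day).
#' @param gamma TGF-beta inhibition of effector recruitment (per molecule).
#' @param mu1 effector death rate (per day).
#' @param p1 maximum effector proliferation rate without TGF-beta (per day).
#' @param g1 IL-2 half-saturation for proliferation (molecules).
#' @param q1 maximum anti-proliferative effect of TGF-beta (per day).
#' @param q2 TGF-beta half-saturation of the anti-proliferative effect
#'   (molecules).
#' @param a tumour intrinsic growth rate (per day).
#' @param K tumour carrying capacity (cells).
#' @param aa strength of the immune kill response (per day).
#' @param g2 tumour half-saturation of the kill term (cells).
#' @param p2 maximum TGF-beta driven extra tumour growth (per day).
#' @param g3 TGF-beta half-saturation of the growth stimulation (molecules).
#' @param p3 maximum IL-2 production rate (per day).
#' @param g4 tumour half-saturation of IL-2 production (cells).
#' @param alpha TGF-beta inhibition of IL-2 production (per molecule).
#' @param mu2 IL-2 loss rate (per day).
#' @param p4 maximum TGF-beta production rate (molecules per day).
#' @param theta critical tumour size of the TGF-beta production switch (cells).
#' @param mu3 TGF-beta decay rate (per day).
#' @return An object of class `case3_params`.
#' @references Arciero JC, Jackson TL, Kirschner DE (2004). A mathematical
#'   model of tumor-immune evasion and siRNA treatment. Discrete Contin Dyn
#'   Syst B 4:39-58.
#' @export
case3_params <- function(c = 0.035, gamma = 10, mu1 = 0.03, p1 = 0.1245,
                         g1 = 2e7, q1 = 10, q2 = 0.1121, a = 0.18, K = 1e10,
                         aa = 1, g2 = 1e5, p2 = 0.27, g3 = 2e7, p3 = 5,
                         g4 = 1000, alpha = 0.001, mu2 = 10, p4 = 2.84,
                         theta = 1e6, mu3 = 10) {
  .new_params(list(
    c = .check_scalar(c, "c"),
    gamma = .check_scalar(gamma, "gamma"),
    mu1 = .check_scalar(mu1, "mu1"),
    p1 = .check_scalar(p1, "p1"),
    g1 = .check_scalar(g1, "g1", positive = TRUE),
    q1 = .check_scalar(q1, "q1"),
    q2 = .check_scalar(q2, "q2", positive = TRUE),
    a = .check_scalar(a, "a"),
    K = .check_scalar(K, "K", positive = TRUE),
    aa = .check_scalar(aa, "aa"),
    g2 = .check_scalar(g2, "g2", positive = TRUE),
    p2 = .check_scalar(p2, "p2"),
    g3 = .check_scalar(g3, "g3", positive = TRUE),
    p3 = .check_scalar(p3, "p3"),
    g4 = .check_scalar(g4, "g4", positive = TRUE),
    alpha = .check_scalar(alpha, "alpha"),
    mu2 = .check_scalar(mu2, "mu2"),
    p4 = .check_scalar(p4, "p4"),
    theta = .check_scalar(theta, "theta", positive = TRUE),
    mu3 = .check_scalar(mu3, "mu3")
  ), "case3_params")
}

# ---- model metadata ---------------------------------------------------------

#' Species tracked by each model
#'
#' Population vectors follow a fixed canonical order: tumour cells `T`,
#' effector cells `E`, IL-2 molecules `I`, TGF-beta molecules `S`.
#'
#' @param model_id one of `"case0"` (generic growth), `"case1"`, `"case2"`,
#'   `"case3"`.
#' @return Character vector of species names in canonical order.
#' @export
model_species <- function(model_id) {
  switch(match.arg(model_id, c("case0", "case1", "case2", "case3")),
    case0 = "T",
    case1 = c("T", "E"),
    case2 = c("T", "E", "I"),
    case3 = c("T", "E", "I", "S")
  )
}

.params_class <- function(model_id) {
  switch(model_id,
    case0 = "generic_growth_params",
    case1 = "case1_params",
    case2 = "case2_params",
    case3 = "case3_params",
    stop("unknown model_id: ", model_id)
  )
}

#' Construct a per-species population state vector
#'
#' @param ... named abundances (subset of `T`, `E`, `I`, `S`), each a single
#'   non-negative number.
#' @param model_id model the state belongs to; the species set must match.
#' @return Named numeric vector in canonical species order.
#' @examples
#' population_state(T = 50, E = 5, model_id = "case1")
#' @export
population_state <- function(..., model_id) {
  vals <- c(...)
  species <- model_species(model_id)
  if (!setequal(names(vals), species)) {
    stop(sprintf("state for model '%s' must name exactly: %s",
                 model_id, paste(species, collapse = ", ")), call. = FALSE)
  }
  vals <- vals[species]
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("population abundances must be finite and non-negative",
         call. = FALSE)
  }
  vals
}
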