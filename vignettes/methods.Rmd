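---
title: "Methods: dual-paradigm tumour–immune simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-paradigm tumour–immune simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`oncoabm` simulates the same biological system twice — once as a system of
ordinary differential equations (ODEs) and once as a stochastic agent-based
model (ABM) — and compares the two statistically. This vignette documents the
model equations, the agent semantics, the numerical methods, and the
limitations a user should know about.

## 1. The ODE models

All populations are dimensionless counts; time is in days. `T` is the tumour
cell count, `E` effector (immune) cells, `I` IL-2 molecules, `S` TGF-β
molecules. The canonical species order everywhere in the package (CSV columns,
state vectors) is `T, E, I, S`.

**Case 1 (effector–tumour, Kuznetsov type).**

$$
\frac{dT}{dt} = aT(1-bT) - nTE, \qquad
\frac{dE}{dt} = \frac{pTE}{g+T} - mTE - dE + s .
$$

The scenario tables for this family only vary $b$, $d$ and $s$; the remaining
constants default to the dimensionless values of the original
Kuznetsov et al. (1994) model ($a=1.636$, $n=1$, $p=1.131$, $g=20.19$,
$m=0.00311$) and are user-overridable via `case1_params()`. Four built-in
scenarios (`case1-s1` … `case1-s4`) cover tumour clearance under therapy,
uncontrolled growth, predator–prey oscillation, and therapy withdrawal.

**Case 2 (effector–tumour–IL-2, Kirschner–Panetta type).**

$$
\frac{dE}{dt} = cT - \mu_2 E + \frac{p_1 E I}{g_1 + I} + s_1,\quad
\frac{dT}{dt} = aT(1-bT) - \frac{a_a E T}{g_2 + T},\quad
\frac{dI}{dt} = \frac{p_2 E T}{g_3 + T} - \mu_3 I + s_2 .
$$

**Case 3 (adds TGF-β, Arciero type).**

$$
\begin{aligned}
\frac{dE}{dt} &= \frac{cT}{1+\gamma S} - \mu_1 E
  + \frac{p_1 E I}{g_1+I}\Big(p_1 - \frac{q_1 S}{q_2+S}\Big), &
\frac{dT}{dt} &= aT\Big(1-\frac{T}{K}\Big) - \frac{a_a E T}{g_2+T}
  + \frac{p_2 S T}{g_3+S},\\
\frac{dI}{dt} &= \frac{p_3 E T}{(g_4+T)(1+\alpha S)} - \mu_2 I, &
\frac{dS}{dt} &= \frac{p_4 T^2}{\theta^2+T^2} - \mu_3 S .
\end{aligned}
$$

TGF-β production switches on only once the tumour approaches the switching
scale $\theta = 10^6$ cells; in the built-in scenario the tumour never gets
there, so $S$ stays far below one "molecule" — which is precisely what makes
the agent-based rendering of this model interesting (see §5).

Integration uses `deSolve::ode` (LSODA) with `rtol = atol = 1e-8`, sampled on
the daily grid $t = 0, 1, \dots,$ `horizon_days`. Tiny negative undershoots
(within $10^{-9}$) are clamped to zero; anything larger is treated as an
integration failure and raised as an error naming the failure time.
`steady_state_value()` reports a plateau when the trajectory's relative range
over a trailing window is below 1%.

## 2. State-chart agent models

Each ODE term is re-read as a transition of an agent state chart:

* **Rate transitions** fire as Poisson streams per agent; the intensity may
  depend on global counts (e.g. an effector kills a tumour cell at rate
  $a_a T/(g_2+T)$).
* **Branch transitions** model "proliferate or die": a single Poisson stream
  with intensity $|a - bT|$ whose action is a birth when the signed rate is
  positive and a death when it is negative.
* **Message transitions** deliver kills: a firing `kill` transition posts a
  message to the target species; messages are applied after all rate draws,
  in sender order (effectors before tumour cells), and surplus messages —
  kills with no one left to kill — are dropped.
* **Global events** (therapy) inject agents as a population-level Poisson
  stream, e.g. effector influx at rate $s$ per day.

Two **rate modes** are provided because published transition tables for this
model family occasionally differ from the ODE they were derived from.
`"as_printed"` (default) uses the published per-agent rates verbatim;
`"ode_faithful"` substitutes rates whose aggregate drift equals the ODE
exactly. The differences are: the case-1 effector-damage rate ($m$ per tumour
agent vs $mE$), the case-3 TGF-driven tumour growth rate
($p_2 S/(g_3+S)$ per TGF agent vs $p_2 T/(g_3+S)$), and the case-3 effector
proliferation bracket, which can go negative and is clamped at zero
(`ode_faithful` routes the clamped excess to an explicit death transition).
`statechart_drift()` exposes the aggregate drift so the
`ode_faithful` equivalence is testable: for 100 random states the drift equals
the RHS to machine precision.

## 3. The tau-leap step

Time advances in fixed steps of `dt` days. For each species with $N$ agents
and total per-agent intensity $R$ (the sum of its transition rates), the
number of agents that fire during the step is drawn as

$$ F \sim \mathrm{Binomial}\!\left(N,\; 1-e^{-R\,dt}\right), $$

and $F$ is split across the species' transitions multinomially with weights
$r_i/R$. The `per_agent` mode draws one categorical outcome per agent instead;
the two modes are distributionally identical (and tested to be). Counts are
integers, never negative, and an ensemble run is reproducible bit-for-bit: run
$i$ uses an L'Ecuyer-CMRG stream seeded with `base_seed + i`, and the caller's
RNG state is saved and restored.

**Known bias.** Capping each agent at one firing per step deflates realised
rates by the factor $(1-e^{-R\,dt})/(R\,dt)$. This is negligible when
$R\,dt \ll 1$ but matters for fast channels: IL-2 decays at $\mu_3 = 10$/day,
so at $dt = 0.1$ that channel is deflated by ~39% and the case-2 ensemble
drifts visibly above the ODE. The package therefore defaults to
`abm_config(dt = 0.02)` (worst-case deflation ~9% on the fastest channel) and
leaves `dt` as an explicit knob. If your model has per-agent rates above a few
per day, check convergence by halving `dt`; residual inflation of fast species
is expected and documented rather than silently corrected, because the
fixed-step semantics *is* the modelling primitive here.

```{r}
library(oncoabm)
sc <- load_scenario("case2")
ode <- integrate_scenario(sc)
ens <- run_ensemble(sc, abm_config(dt = 0.02, n_runs = 50, base_seed = 1))
compare_trajectories(ode, ens)
```

## 4. Comparing the paradigms

`compare_trajectories()` aligns the ODE daily series with the ensemble-mean
daily series (grids must match exactly) and runs a two-sided Wilcoxon rank-sum
test per species; `mode = "per_run"` instead tests every run and reports the
rejection fraction. The rank-sum wrapper uses the exact distribution when both
samples have at most 10 values and no ties, and the tie-corrected normal
approximation otherwise; identical pooled samples return $p = 1$. Note the
usual caveat: daily samples of a trajectory are autocorrelated, so the test is
a similarity *score* in trajectory space rather than a calibrated hypothesis
test — with 600 daily samples it will flag even a ~2% systematic offset.

## 5. What the comparison shows

With large populations (case 2) the ensembles track the ODE to within a few
percent, with residual inflation of IL-2 from the step bias above. With small
populations the paradigms genuinely disagree, in two instructive ways:

* **Extinction (case 1, therapy scenarios).** The stochastic tumour hits
  exactly zero and stays there; the ODE only decays asymptotically. Run the
  README example to see the tumour series rejected while the effector series
  is not.
* **Discreteness (case 3).** The ODE's TGF-β stays at ~10⁻³ "molecules" —
  a fraction that the ODE happily feeds back into tumour growth. The agent
  model can only hold 0, 1, 2 … molecules: production fires as rare discrete
  events and each molecule decays within hours, so the sampled TGF-β count is
  almost always zero and its suppressive feedback is essentially absent.

## 6. Problem sizes and runtime

ODE integration of any built-in scenario takes well under a second. Agent
ensembles scale with (population × horizon / dt): a 50-run case-2 ensemble
(populations up to ~6×10⁴, 600 days, dt = 0.02) takes a few minutes on one
CPU; the case-1 scenarios (populations ≤ 500, 100 days) take seconds. Counts
are capped at 10⁹ agents; exceeding the cap is an explicit overflow error.

## 7. Limitations

* No spatial structure: perfectly mixed populations only.
* Fixed-step tau-leaping, not exact Gillespie simulation; see the bias note.
* The rank-sum comparison ignores autocorrelation (by design, to mirror the
  established methodology for this model family).
* Cytokines are treated as agent "molecules" at the model's own dimensionless
  scale, not physical molecule counts.
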