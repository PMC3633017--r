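Package: oncoabm
Title: Dual-Paradigm Simulation of Early-Stage Tumour-Immune Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates three classical ordinary-differential-equation (ODE)
    models of interactions between early-stage tumours and the immune system
    (an effector-tumour model of Kuznetsov type, a three-population
    effector/tumour/IL-2 model of Kirschner-Panetta type, and a four-population
    model with the suppressive cytokine TGF-beta of Arciero type), together
    with their agent-based re-conceptualisations as stochastic state-chart
    models with Poisson rate-triggered and message-triggered transitions.
    Provides deterministic integration with plateau detection, a fixed-step
    tau-leap agent-based engine with reproducible ensembles, and a Wilcoxon
    rank-sum harness that statistically compares trajectories produced by the
    two paradigms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
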