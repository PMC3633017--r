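# Model right-hand sides, parameter handling and scenario loading.

test_that("generic growth rate handles fixed points and exponential growth", {
  p_exp <- generic_growth_params(a = 1, alpha = 0, b = 0, beta = 0)
  expect_equal(generic_growth_rhs(0, p_exp), 0)
  expect_equal(generic_growth_rhs(10, p_exp), 10)
  # logistic fixed point at T = a/b when alpha = 0, beta = 1
  p_log <- generic_growth_params(a = 0.5, alpha = 0, b = 0.005, beta = 1)
  expect_equal(generic_growth_rhs(100, p_log), 0)
  expect_equal(generic_growth_rhs(0, p_log), 0)
  expect_error(generic_growth_rhs(-1, p_exp), "non-negative")
})

test_that("effector-tumour derivatives match hand substitution", {
  p <- case1_params(b = 0.01, d = 0.1, s = 0, a = 1, n = 1, p = 1,
                    g = 10, m = 0.01)
  d <- case1_rhs(c(T = 50, E = 5), p)
  expect_equal(d[["T"]], 50 * 0.5 - 250)            # -225
  expect_equal(d[["E"]], 250 / 60 - 2.5 - 0.5)      # 1.1667
  # pure treatment influx when no effectors are present
  p_s <- case1_params(b = 0.01, d = 0.1, s = 0.318, a = 1, n = 1, p = 1,
                      g = 10, m = 0.01)
  expect_equal(case1_rhs(c(T = 50, E = 0), p_s)[["E"]], 0.318)
  # origin is a fixed point without treatment
  expect_equal(unname(case1_rhs(c(T = 0, E = 0), p)), c(0, 0))
  expect_error(case1_rhs(c(T = -1, E = 0), p), "non-negative")
})

test_that("effector/tumour/IL-2 derivatives match hand substitution", {
  p <- case2_params()
  d <- case2_rhs(c(T = 50, E = 10, I = 0), p)
  expect_equal(d[["E"]], 0.05 * 50 - 0.03 * 10)                 # 2.2
  expect_equal(d[["T"]], 0.18 * 50 * (1 - 5e-8) - 500 / 100050, tolerance = 1e-12)
  expect_equal(d[["I"]], 2500 / 1050, tolerance = 1e-12)
  expect_equal(unname(case2_rhs(c(T = 0, E = 0, I = 0), p)), c(0, 0, 0))
  # the no-leading-T growth variant drops the tumour factor
  d2 <- case2_rhs(c(T = 50, E = 0, I = 0), p, growth = "no_leading_T")
  expect_equal(d2[["T"]], 0.18 * (1 - 5e-8))
})

test_that("TGF-beta model derivatives match hand substitution", {
  p <- case3_params()
  st <- c(T = 1, E = 1, I = 10, S = 0)
  d <- case3_rhs(st, p)
  expect_equal(d[["S"]], 2.84 / (1e12 + 1), tolerance = 1e-12)
  expect_equal(d[["I"]], 5 / 1001 - 100, tolerance = 1e-12)
  expect_equal(d[["E"]],
               0.035 - 0.03 + (0.1245 * 10 / (2e7 + 10)) * 0.1245,
               tolerance = 1e-12)
  expect_equal(unname(case3_rhs(c(T = 0, E = 0, I = 0, S = 0), p)),
               c(0, 0, 0, 0))
})

test_that("every RHS vanishes at the origin when influx terms are zero", {
  cases <- list(
    list(id = "case1", p = case1_params(b = 0.002, d = 0.3743, s = 0)),
    list(id = "case2", p = case2_params(s1 = 0, s2 = 0)),
    list(id = "case3", p = case3_params())
  )
  for (cs in cases) {
    species <- model_species(cs$id)
    origin <- setNames(numeric(length(species)), species)
    expect_equal(unname(model_rhs(cs$id)(origin, cs$p)),
                 numeric(length(species)), info = cs$id)
  }
})

test_that("built-in scenarios carry the published study conditions", {
  s2 <- load_scenario("case1-s2")
  expect_equal(s2$params$b, 0.004)
  expect_equal(s2$params$d, 2)
  expect_equal(s2$params$s, 0.318)
  expect_equal(s2$horizon_days, 100L)
  expect_equal(s2$initial_state, c(T = 50, E = 5))

  c2 <- load_scenario("case2")
  expect_equal(c2$initial_state, c(T = 50, E = 10, I = 0))
  expect_equal(c2$horizon_days, 600L)
  expect_equal(c2$params$s1, 0)
  expect_equal(c2$params$s2, 0)

  c3 <- load_scenario("case3")
  expect_equal(c3$params$theta, 1e6)
  expect_equal(c3$params$p4, 2.84)
  expect_equal(c3$params$mu3, 10)
  expect_equal(c3$params$K, 1e10)
  expect_equal(c3$initial_state, c(T = 1, E = 1, I = 10, S = 0))

  expect_error(load_scenario("no-such-model"), "unknown scenario")
  expect_error(load_scenario("no-such-model"), "case1-s1")  # lists built-ins
})

test_that("scenarios round-trip through YAML serialisation unchanged", {
  for (label in list_scenarios()) {
    sc <- load_scenario(label)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_scenario(sc, path)
    expect_equal(read_scenario(path), sc, info = label)
  }
  # regression: the bare YAML key `n` (a YAML 1.1 boolean) must survive
  sc1 <- load_scenario("case1-s1")
  expect_equal(sc1$params$n, 1)
})

test_that("scenario files with unknown keys or bad values are rejected", {
  sc <- load_scenario("case1-s1")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  txt <- readLines(path)
  writeLines(c(txt, "space: true"), path)
  expect_error(read_scenario(path), "unknown scenario key")
  writeLines(c("model: case1", "horizon_days: 100",
               "params: {b: 0.002, d: 0.19, s: 0.3, zz: 1}",
               "initial_state: {T: 50, E: 5}"), path)
  expect_error(read_scenario(path), "unknown parameter")
  expect_error(scenario_spec("case1", case1_params(b = 1, d = 1, s = 1),
                             c(T = -5, E = 5), 100), "non-negative")
  expect_error(case2_params(g1 = 0), "must be > 0")
})

test_that("state-chart rates reproduce the published transition formulas", {
  p1 <- load_scenario("case1-s1")$params
  ch1 <- build_case1_statechart(p1)  # as_printed
  # scenario 1 at T = 50, E = 5: hand-evaluated transition-rate expressions
  r <- statechart_rates(ch1, c(T = 50, E = 5))
  rate_of <- function(df, nm) df$rate[df$name == nm]
  expect_equal(rate_of(r, "proliferateOrDie"), 1.636 - 0.002 * 50)
  expect_equal(rate_of(r, "dieKilledByEffectorCells"), 5)     # n * E
  expect_equal(rate_of(r, "causeEffectorDamage"), 0.00311)    # bare m
  expect_equal(rate_of(r, "Proliferation"), 1.131 * 50 / (20.19 + 50))
  expect_equal(rate_of(r, "DieWithAge"), 0.1908)
  # branch boundary: zero signed rate when a = b T
  r0 <- statechart_rates(ch1, c(T = 1.636 / 0.002, E = 0))
  expect_equal(rate_of(r0, "proliferateOrDie"), 0)
  expect_equal(rate_of(r0, "dieKilledByEffectorCells"), 0)    # no effectors

  p2 <- load_scenario("case2")$params
  ch2 <- build_case2_statechart(p2)
  r2 <- statechart_rates(ch2, c(T = 50, E = 10, I = 0))
  expect_equal(rate_of(r2, "killTumour"), 50 / 100050, tolerance = 1e-12)
  expect_equal(rate_of(r2, "Reproduce"), 0)                   # no IL-2
  expect_equal(rate_of(r2, "InduceRecruitment"), 0.05)

  p3 <- load_scenario("case3")$params
  ch3 <- build_case3_statechart(p3)
  r3 <- statechart_rates(ch3, c(T = 0, E = 1, I = 10, S = 0))
  expect_equal(rate_of(r3, "Reproduce"),
               0.1245 * 10 / (2e7 + 10) * 0.1245, tolerance = 1e-12)
  expect_equal(rate_of(r3, "ProduceTGF"), 0)
  expect_equal(rate_of(r3, "KillTumour"), 0)
  expect_equal(rate_of(r3, "ProduceIL2"), 0)
  # TGF-beta production switch at its half-maximum: total rate p4 / 2
  r3b <- statechart_rates(ch3, c(T = 1e6, E = 0, I = 0, S = 0))
  expect_equal(1e6 * rate_of(r3b, "ProduceTGF"), 2.84 / 2)
})

test_that("aggregate state-chart drift matches the ODE flow (faithful mode)", {
  set.seed(7)
  specs <- list(
    list(id = "case1", params = load_scenario("case1-s3")$params,
         build = build_case1_statechart),
    list(id = "case2", params = load_scenario("case2")$params,
         build = build_case2_statechart),
    list(id = "case3", params = load_scenario("case3")$params,
         build = build_case3_statechart)
  )
  for (sp in specs) {
    chart <- sp$build(sp$params, rate_mode = "ode_faithful")
    rhs <- model_rhs(sp$id)
    species <- model_species(sp$id)
    for (k in seq_len(100)) {
      state <- setNames(
        round(runif(length(species), 0, c(1e5, 1e4, 1e4, 50))[seq_along(species)]),
        species)
      expect_equal(statechart_drift(chart, state), rhs(state, sp$params),
                   tolerance = 1e-10,
                   info = sprintf("%s state %s", sp$id,
                                  paste(state, collapse = ",")))
    }
  }
})

test_that("as-printed rates diverge from the ODE exactly as published", {
  p1 <- load_scenario("case1-s1")$params
  ch <- build_case1_statechart(p1, rate_mode = "as_printed")
  r <- statechart_rates(ch, c(T = 120, E = 37))
  expect_equal(r$rate[r$name == "causeEffectorDamage"], p1$m)  # not m * E
  p2 <- load_scenario("case2")$params
  ch2 <- build_case2_statechart(p2, rate_mode = "as_printed")
  r2 <- statechart_rates(ch2, c(T = 56168, E = 0, I = 0))
  expect_equal(r2$rate[r2$name == "proliferateOrDie"],
               p2$a - p2$b * 56168)                             # a - bT
  p3 <- load_scenario("case3")$params
  ch3 <- build_case3_statechart(p3, rate_mode = "as_printed")
  r3 <- statechart_rates(ch3, c(T = 10, E = 0, I = 0, S = 40))
  expect_equal(r3$rate[r3$name == "StimulatesTumourGrowth"],
               p3$p2 * 40 / (p3$g3 + 40))                      # p2 S/(g3+S)
})
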