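# Stochastic state-chart engine: step semantics, reproducibility, ensembles.

test_that("an empty population is absorbing", {
  chart <- build_case1_statechart(load_scenario("case1-s4")$params)  # s = 0
  set.seed(1)
  out <- abm_step(c(T = 0, E = 0), chart, dt = 0.1)
  expect_equal(out, c(T = 0, E = 0))
})

test_that("counts stay non-negative integers through random stepping", {
  chart <- build_case2_statechart(load_scenario("case2")$params)
  set.seed(11)
  counts <- c(T = 50, E = 10, I = 0)
  for (k in 1:300) {
    counts <- abm_step(counts, chart, dt = 0.1)
    expect_true(all(counts >= 0))
    expect_true(all(counts == floor(counts)))
  }
  expect_error(abm_step(c(T = -1, E = 0, I = 0), chart, 0.1),
               "non-negative integers")
  expect_error(abm_step(c(T = 1.5, E = 0, I = 0), chart, 0.1),
               "non-negative integers")
})

test_that("pure-death step matches the closed-form survival expectation", {
  chart <- statechart(
    species = "T",
    transitions = list(sc_transition("T", "death",
      rate = function(n, p) p$r, action = "die")),
    params = list(r = 0.03), model_id = "case0"
  )
  n_rep <- 10000L
  set.seed(2024)
  survivors <- vapply(seq_len(n_rep), function(i)
    abm_step(c(T = 1000), chart, dt = 1)[["T"]], numeric(1))
  p_die <- 1 - exp(-0.03)
  expected <- 1000 * exp(-0.03)              # 970.45
  se <- sqrt(1000 * p_die * (1 - p_die) / n_rep)
  expect_lt(abs(mean(survivors) - expected), 3 * se)
})

test_that("treatment events inject a Poisson stream of the configured rate", {
  # event-only model: s = 0.318/day over 100 days => mean total 31.8
  chart <- statechart(
    species = "T", transitions = list(),
    events = list(sc_event("treatment", 0.318, "T")),
    params = list(), model_id = "case0"
  )
  sc <- constant_scenario(0, 100)
  n_runs <- 200L
  totals <- vapply(seq_len(n_runs) - 1L, function(i) {
    r <- abm_run(sc, abm_config(dt = 0.1, n_runs = 1, base_seed = 500L),
                 run_index = i, chart = chart)
    r$values[101, "T"]
  }, numeric(1))
  se <- sqrt(31.8 / n_runs)
  expect_lt(abs(mean(totals) - 31.8), 3 * se)
})

test_that("identical seeds give bit-identical trajectories", {
  sc <- load_scenario("case1-s1")
  cfg <- abm_config(dt = 0.1, n_runs = 1, base_seed = 42L)
  a <- abm_run(sc, cfg, run_index = 3L)
  b <- abm_run(sc, cfg, run_index = 3L)
  expect_identical(a$values, b$values)
  expect_equal(a$run_seed, 45L)
  c <- abm_run(sc, cfg, run_index = 4L)
  expect_false(identical(b$values, c$values))
})

test_that("runs leave the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(abm_run(constant_scenario(5, 3), abm_config(dt = 0.5, n_runs = 1)))
  expect_identical(.Random.seed, before)
})

test_that("per-agent and count-based modes are distributionally equivalent", {
  chart <- toy_birth_death_chart(birth = 0.3, death = 0.1)
  sc <- constant_scenario(50, 10)
  day10 <- function(mode, base_seed) {
    cfg <- abm_config(dt = 0.25, n_runs = 1, base_seed = base_seed,
                      mode = mode)
    vapply(seq_len(2000) - 1L, function(i)
      abm_run(sc, cfg, run_index = i, chart = chart)$values[11, "T"],
      numeric(1))
  }
  x <- day10("count_based", 1000L)
  y <- day10("per_agent", 9000L)
  expect_gt(wilcoxon_rank_sum(x, y), 0.01)
  # sanity: both concentrate around the step-exact expectation, which carries
  # the documented one-firing-per-step deflation of the net rate
  per_step <- 1 + -expm1(-0.4 * 0.25) * (0.3 - 0.1) / 0.4
  expected <- 50 * per_step^40
  expect_lt(abs(mean(x) - expected) / expected, 0.03)
  expect_lt(abs(mean(y) - expected) / expected, 0.03)
})

test_that("kill messages are dropped when no target remains", {
  # one tumour cell fires damage at huge rate but there are no effectors
  p <- case1_params(b = 0, d = 0, s = 0, a = 0, n = 0, p = 0, g = 1, m = 50)
  chart <- build_case1_statechart(p)
  set.seed(5)
  out <- abm_step(c(T = 10, E = 0), chart, dt = 1)
  expect_equal(out[["E"]], 0)
  expect_equal(out[["T"]], 10)
})

test_that("population overflow raises an error", {
  chart <- statechart(
    species = "T", transitions = list(),
    events = list(sc_event("flood", 2e9, "T")),
    params = list(), model_id = "case0"
  )
  set.seed(8)
  expect_error(abm_step(c(T = 0), chart, dt = 1), "overflow")
})

test_that("ensembles aggregate runs with consistent mean and variance", {
  sc <- load_scenario("case1-s4")
  cfg <- abm_config(dt = 0.1, n_runs = 5, base_seed = 7L)
  ens <- run_ensemble(sc, cfg)
  expect_equal(ens$n_runs, 5L)
  expect_length(ens$runs, 5L)
  cube <- sapply(ens$runs, function(r) r$values[51, "T"])
  expect_equal(unname(ens$mean[51, "T"]), mean(cube))
  expect_equal(unname(ens$variance[51, "T"]), var(cube))
  # single-run ensemble mean equals the run itself
  one <- run_ensemble(sc, abm_config(dt = 0.1, n_runs = 1, base_seed = 7L))
  expect_equal(one$mean, one$runs[[1]]$values * 1)
})
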