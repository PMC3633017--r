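# Independent brute-force oracle for the two-sided rank-sum p-value:
# enumerate every assignment of the pooled values to the x-positions and
# compare the Mann-Whitney U statistic with its observed value.
rank_sum_perm_oracle <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  stopifnot(n <= 12, !anyDuplicated(pooled))
  u_stat <- function(xs, ys) sum(outer(xs, ys, ">"))
  u_obs <- u_stat(x, y)
  splits <- utils::combn(n, nx)
  us <- apply(splits, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# Toy one-species chart: competing per-agent birth and death streams.
toy_birth_death_chart <- function(birth, death) {
  statechart(
    species = "T",
    transitions = list(
      sc_transition("T", "birth", rate = function(n, p) p$birth,
                    action = "spawn", target = "T"),
      sc_transition("T", "death", rate = function(n, p) p$death,
                    action = "die")
    ),
    params = list(birth = birth, death = death),
    model_id = "case0"
  )
}

# Constant-population scenario on the generic growth model (all rates zero).
constant_scenario <- function(T0, horizon) {
  scenario_spec("case0", generic_growth_params(0, 0, 0, 0),
                c(T = T0), horizon, label = "constant")
}
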