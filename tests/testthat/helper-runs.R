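# Shared fixtures: full scenario runs are expensive, so they are computed
# once per session and cached for every test file that needs them.

.run_cache <- new.env(parent = emptyenv())

scenario_run <- function(name) {
  if (is.null(.run_cache[[name]])) {
    .run_cache[[name]] <- run_scenario(name)
  }
  .run_cache[[name]]
}

# A small, fast configuration: same chain geometry, shorter contraction
# period (2 s), used wherever the test only needs a converged pumping run.
toy_config <- function(...) {
  lymph_config(
    "WT",
    activation = list(frequency_per_min = 30, period_s = 2),
    run = list(min_cycles = 3L, max_cycles = 8L),
    ...
  )
}

toy_run <- function() {
  if (is.null(.run_cache[["toy"]])) {
    .run_cache[["toy"]] <- simulate_chain(toy_config())
  }
  .run_cache[["toy"]]
}

# Passive near-rigid tube with negligible valve resistance: the setting in
# which the steady solution has the Hagen-Poiseuille closed form.
rigid_poiseuille_config <- function(pin = 4, pout = 3.5) {
  lymph_config(
    "passive",
    boundary = list(pin_cmh2o = pin, pout_cmh2o = pout),
    wall = list(pre_floor_frac = 0.999, pre_ceiling_frac = 1.0001, peak_floor_frac = 0.4),
    valve = list(rv_min = 1e-3, rv_max = 1e-3, s_o = 1),
    run = list(min_cycles = 3L, max_cycles = 8L)
  )
}
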