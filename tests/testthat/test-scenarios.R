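test_that("presets carry the measured contractility metrics exactly", {
  wt <- scenario_preset("WT")
  expect_identical(wt$conduction_speed_cm_s, 0.98)
  expect_identical(wt$sites_per_cm, 10)
  expect_identical(wt$frequency_per_min, 8.3)
  expect_identical(wt$period_s, 7.23)
  expect_identical(wt$pattern, "antegrade")

  for (nm in c("KO1", "KO2", "KO3")) {
    ko <- scenario_preset(nm)
    expect_identical(ko$conduction_speed_cm_s, 0.063)
    expect_identical(ko$sites_per_cm, 11)
    expect_identical(ko$frequency_per_min, 15.8)
    expect_identical(ko$period_s, 3.80)
  }
  expect_identical(scenario_preset("KO2")$pattern, "alternating")
  expect_identical(scenario_preset("KO3")$pattern, "retrograde")
  expect_error(scenario_preset("WT2"), class = "lymphchain_invalid_parameter")

  # reference geometry and boundary conditions
  cfg <- lymph_config("WT")
  expect_identical(cfg$chain$n_lymphangions, 3L)
  expect_identical(cfg$chain$lymphangion_length_cm, 0.1)
  expect_identical(cfg$chain$dz_cm, 0.005)
  expect_identical(cfg$boundary$pin_cmh2o, 3.5)
  expect_identical(cfg$boundary$pout_cmh2o, 4)
  expect_identical(cfg$wall$d0_um, 255)
  expect_identical(cfg$run$dt_ms, 5)
  expect_identical(cfg$fluid$viscosity, 1e-5)
  expect_identical(cfg$fluid$density, 1070e-6)
  expect_identical(cfg$fluid$zeta, 2)
})

test_that("configuration validation rejects bad input and fills defaults", {
  expect_error(lymph_config("WT", run = list(dt_ms = -5)),
    class = "lymphchain_config_error"
  )
  expect_error(lymph_config("WT", nonsense = list(a = 1)),
    class = "lymphchain_config_error"
  )
  expect_error(lymph_config("WT", valve = list(rv_bogus = 2)),
    class = "lymphchain_config_error"
  )
  expect_error(lymph_config("WT", run = list(min_cycles = 5, max_cycles = 2)),
    class = "lymphchain_config_error"
  )

  # empty file -> full WT defaults
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", f)
  cfg <- load_config(f)
  expect_identical(cfg$scenario, "WT")
  expect_identical(cfg$valve$rv_min, 600)

  expect_error(load_config(tempfile()), class = "lymphchain_config_error")
})

test_that("configurations round-trip through YAML", {
  cfg <- lymph_config("KO2", valve = list(rv_max = 123456), run = list(max_cycles = 7L))
  f <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg, f)
  back <- load_config(f)
  expect_identical(back$scenario, "KO2")
  expect_equal(back$valve$rv_max, 123456)
  expect_equal(back$run$max_cycles, 7)
  expect_equal(back$activation$pattern, "alternating")
  expect_equal(back$chain$dz_cm, cfg$chain$dz_cm)
  expect_equal(back$wall$peak_fraction, cfg$wall$peak_fraction)
})

test_that("scenario runs are deterministic and persist complete outputs", {
  cfg <- toy_config()
  s1 <- simulate_chain(cfg)
  s2 <- simulate_chain(cfg)
  expect_identical(s1$P, s2$P)
  expect_identical(s1$Qv, s2$Qv)
  expect_identical(s1$Rv, s2$Rv)

  out <- withr::local_tempdir()
  run <- run_scenario(cfg, out_dir = out)
  expect_true(all(file.exists(file.path(
    out, c("nodes.csv", "valves.csv", "metrics.json", "config.yaml")
  ))))
  mj <- jsonlite::read_json(file.path(out, "metrics.json"), simplifyVector = TRUE)
  expect_equal(mj$mean_flow_ulh, run$metrics$mean_flow_ulh, tolerance = 1e-12)
  expect_match(
    paste(readLines(file.path(out, "config.yaml")), collapse = "\n"),
    "config_hash"
  )

  # bit-identical rerun of the persisted tables
  out2 <- withr::local_tempdir()
  run_scenario(cfg, out_dir = out2)
  expect_identical(
    readLines(file.path(out, "nodes.csv")),
    readLines(file.path(out2, "nodes.csv"))
  )
})

test_that("a single-point sweep reproduces the direct run and failures are caught", {
  cfg <- toy_config()
  direct <- run_scenario(cfg)
  sw <- sensitivity_sweep(cfg,
    frequencies = cfg$activation$frequency_per_min,
    sites_per_cm = cfg$activation$sites_per_cm
  )
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$mean_flow_ulh, direct$metrics$mean_flow_ulh)
  expect_equal(sw$ef, direct$metrics$ef)

  sw2 <- sensitivity_sweep(cfg, frequencies = 30, sites_per_cm = c(-1, 10))
  expect_equal(nrow(sw2), 2L)
  expect_true(is.na(sw2$mean_flow_ulh[sw2$sites_per_cm == -1]))
  expect_false(is.na(sw2$mean_flow_ulh[sw2$sites_per_cm == 10]))
})

test_that("simulation tidiers expose the full state history", {
  sim <- toy_run()
  nodes <- tidy(sim, "nodes")
  expect_true(all(c("time", "node", "z", "lymphangion", "pressure", "flow", "diameter", "compliance", "activation") %in% names(nodes)))
  expect_equal(nrow(nodes), sim$geometry$n_nodes * ncol(sim$P))
  valves <- tidy(sim, "valves")
  expect_equal(nrow(valves), 4L * ncol(sim$Qv))
  cycles <- tidy(sim, "cycles")
  expect_equal(nrow(cycles), sim$cycles_run)
  g <- glance(sim)
  expect_equal(nrow(g), 1L)
  expect_true(g$converged)

  for (type in c("activation", "pressure", "flow", "wss", "pd_loop", "cd_loop", "valves")) {
    expect_s3_class(autoplot(sim, type = type), "ggplot")
  }
})
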