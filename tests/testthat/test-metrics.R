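test_that("ejection fraction handles vectors, matrices and degenerate cases", {
  expect_identical(ejection_fraction(c(1, 1, 1)), 0)
  expect_identical(ejection_fraction(c(1, 0, 1)), 1)
  expect_equal(ejection_fraction(c(2, 1, 1.5)), 0.5)
  # matrix input: chain average first (weighted)
  m <- rbind(c(2, 1), c(4, 3))
  expect_equal(ejection_fraction(m), 1 / 3) # means 3, 2
  expect_equal(ejection_fraction(m, weights = c(1, 0)), 0.5)
  expect_error(ejection_fraction(c(0, 0)), class = "lymphchain_invalid_parameter")
})

test_that("fractional pump function is frequency times EF", {
  expect_identical(fractional_pump_function(0, 10), 0)
  expect_equal(fractional_pump_function(0.78, 8.3), 6.474)
  expect_equal(fractional_pump_function(0.25, 15.8), 3.95)
  expect_error(fractional_pump_function(1.2, 8), class = "lymphchain_invalid_parameter")
  expect_error(fractional_pump_function(0.5, 0), class = "lymphchain_invalid_parameter")
})

test_that("wall shear stress reduces to the Hagen-Poiseuille formula at zeta = 2", {
  fl <- fluid_params()
  expect_identical(wall_shear_stress(0, 0.02, fl), 0)
  q <- 3e-5
  d <- 0.0255
  expect_equal(
    wall_shear_stress(q, d, fl),
    -32 * fl$mu * q / (pi * d^3) * 980.665
  )
  # negative during forward flow, positive during reverse
  expect_lt(wall_shear_stress(1e-5, d, fl), 0)
  expect_gt(wall_shear_stress(-1e-5, d, fl), 0)
  expect_error(wall_shear_stress(1, 0, fl), class = "lymphchain_invalid_parameter")
})

test_that("WSS signal-to-noise ratio matches the brute-force definition", {
  # x = [1,-1,1,-1], window 2: trailing filter gives [1,0,0,0],
  # MSE = sqrt(3/4), MSE0 = 1, SNR = log(4/3)
  expect_equal(wss_snr(c(1, -1, 1, -1), 2), log(4 / 3))
  # constant series with window 1: filtered equals original
  expect_identical(wss_snr(c(2, 2, 2), 1), Inf)
  expect_error(wss_snr(c(0, 0, 0), 2), class = "lymphchain_invalid_parameter")
  expect_error(wss_snr(c(1, 2), 5), class = "lymphchain_invalid_parameter")

  # scale invariance: both RMS terms scale identically
  set.seed(42)
  x <- stats::rnorm(200)
  expect_equal(wss_snr(x, 5), wss_snr(7.3 * x, 5))
  expect_equal(wss_snr(x, 5), wss_snr(-x, 5))
})

test_that("radial velocity differentiates the radius exactly on linear data", {
  expect_equal(radial_velocity(rep(0.02, 10), 0.005), rep(0, 10))
  # r(t) = r0 + a t: central differences are exact
  a <- 3e-4
  tt <- seq(0, 1, by = 0.005)
  d <- 2 * (0.01 + a * tt)
  expect_equal(radial_velocity(d, 0.005), rep(a, length(tt)))
  expect_error(radial_velocity(c(1, 2), 0.005), class = "lymphchain_invalid_parameter")
})

test_that("valvular energy loss combines pressure and dynamic heads", {
  expect_identical(valve_energy_loss(4, 0.1, 4, 0.1), 0)
  expect_equal(valve_energy_loss(4, 0, 3.5, 0), 0.5)
  rho <- 1070e-6
  expect_equal(
    valve_energy_loss(4, 2, 3, 1, rho),
    1 + 0.5 * rho * (4 - 1)
  )
})

test_that("activation integration uses the per-mille duty convention", {
  expect_identical(as.numeric(activation_integration(matrix(0, 3, 4))), 0)
  expect_identical(as.numeric(activation_integration(matrix(1, 5, 7))), 1000)
  ai <- activation_integration(matrix(0.5, 2, 2))
  expect_equal(as.numeric(ai), 500)
  expect_match(attr(ai, "convention"), "normalized")
})

test_that("bottleneck tracking finds the constructed argmax pattern", {
  # 1 lymphangion, 4 nodes, 10 steps: argmax at node 2 for 7 steps, node 4 for 3
  q <- matrix(0.1, nrow = 4, ncol = 10)
  q[2, 1:7] <- 1
  q[4, 8:10] <- -2 # magnitude decides
  bt <- bottleneck_trace(q, rep(1L, 4))
  expect_equal(bt$trace$node, c(rep(2L, 7), rep(4L, 3)))
  expect_equal(bt$stationarity$modal_node, 2L)
  expect_equal(bt$stationarity$score, 0.7)

  # uniform flow: ties break towards the upstream node, score 1
  bt0 <- bottleneck_trace(matrix(1, 3, 5), rep(1L, 3))
  expect_true(all(bt0$trace$node == 1L))
  expect_identical(bt0$stationarity$score, 1)
})

test_that("the metrics report is complete and self-consistent on a pumping run", {
  sim <- toy_run()
  m <- lymph_metrics(sim)
  # FPF identity holds exactly
  expect_identical(m$fpf_per_min, m$frequency_per_min * m$ef)
  expect_gte(m$ef, 0)
  expect_lte(m$ef, 1)
  expect_equal(m$area_reduction, m$ef) # same extremes of the same series
  expect_length(m$ef_per_lymphangion, 3L)
  expect_length(m$mean_pressure_per_lymphangion, 3L)
  # cycle/space mean pressures lie between the boundary pressures
  expect_true(all(m$mean_pressure_per_lymphangion >= 3.5 & m$mean_pressure_per_lymphangion <= 4))
  expect_equal(nrow(m$energy_loss), 4L)
  expect_true(m$mass_residual < 1e-2)
  expect_gt(m$peak_flow_ulh, m$mean_flow_ulh)
  expect_gt(m$contraction_velocity_peak_ums, 0)

  td <- tidy(m)
  expect_true(all(c("metric", "value", "unit") %in% names(td)))
  expect_true("mean_pressure_L2" %in% td$metric)
  g1 <- glance(m)
  expect_equal(nrow(g1), 1L)
  expect_equal(g1$ef, m$ef)
})

test_that("energy loss across a near-ideal open valve vanishes with its resistance", {
  # same passive rigid setup with decreasing open resistance
  losses <- vapply(c(10, 1, 0.01), function(rv) {
    cfg <- lymph_config("passive",
      boundary = list(pin_cmh2o = 4, pout_cmh2o = 3.5),
      wall = list(pre_floor_frac = 0.999, pre_ceiling_frac = 1.0001, peak_floor_frac = 0.4),
      valve = list(rv_min = rv, rv_max = rv, s_o = 1),
      run = list(min_cycles = 3L, max_cycles = 8L)
    )
    m <- lymph_metrics(simulate_chain(cfg))
    m$energy_loss$loss_magnitude[2]
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_lt(losses[3], 1e-4)
})
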