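test_that("activation parameters follow the decay rules", {
  wt <- activation_params(10, 0.98, 8.3, 7.23)
  expect_equal(wt$sigma_z, 0.0125)
  expect_equal(wt$sigma_t, 1.8075)
  expect_equal(wt$rho, 0.0125 / (0.98 * 1.8075))

  ko <- activation_params(11, 0.063, 15.8, 3.80)
  expect_equal(ko$sigma_z, 1 / 88)
  expect_equal(ko$sigma_t, 0.95)
  expect_equal(ko$rho, (1 / 88) / (0.063 * 0.95))

  # very fast conduction gives an unskewed pulse
  fast <- activation_params(10, 1e9, 8.3, 7.23)
  expect_lt(fast$rho, 1e-9)

  # slow conduction is clipped at rho_max
  slow <- activation_params(10, 1e-6, 8.3, 7.23, rho_max = 0.9)
  expect_equal(slow$rho, 0.9)

  expect_error(activation_params(0, 1, 8, 7), class = "lymphchain_invalid_parameter")
  expect_error(activation_params(10, -1, 8, 7), class = "lymphchain_invalid_parameter")
})

test_that("pacemakers are evenly spaced, centred, with per-scenario directions", {
  wt <- place_pacemakers(0.3, 10, "antegrade", period = 7.23)
  expect_equal(nrow(wt), 3L)
  expect_equal(wt$position_z, c(0.05, 0.15, 0.25))
  expect_true(all(wt$direction == "antegrade"))
  expect_true(all(wt$mu_t == 7.23 / 2))

  ko <- place_pacemakers(0.3, 11, "alternating", period = 3.8)
  expect_equal(nrow(ko), 3L)
  expect_equal(diff(ko$position_z), rep(1 / 11, 2))
  expect_equal(ko$direction, c("antegrade", "retrograde", "antegrade"))
  expect_equal(mean(ko$position_z), 0.15) # centred

  retro <- place_pacemakers(0.3, 10, "retrograde", period = 7.23)
  expect_true(all(retro$direction == "retrograde"))

  expect_error(place_pacemakers(0.3, 0, "antegrade", 7.23),
    class = "lymphchain_invalid_parameter"
  )
  expect_warning(
    single <- place_pacemakers(0.3, 2, "antegrade", 7.23),
    "single midpoint"
  )
  expect_equal(single$position_z, 0.15)
})

test_that("bivariate Gaussian has the textbook peak, symmetry and domain checks", {
  sz <- 0.0125
  st <- 1.8075
  expect_equal(
    bivariate_gaussian(0.1, 2, 0.1, 2, sz, st, 0),
    1 / (2 * pi * sz * st)
  )
  # frozen arithmetic: the WT peak density
  expect_equal(bivariate_gaussian(0, 0, 0, 0, sz, st, 0), 7.0442, tolerance = 1e-4)

  # unskewed density is symmetric in z about mu_z
  for (delta in c(0.001, 0.01, 0.05)) {
    expect_equal(
      bivariate_gaussian(0.1 + delta, 1.5, 0.1, 2, sz, st, 0),
      bivariate_gaussian(0.1 - delta, 1.5, 0.1, 2, sz, st, 0)
    )
  }
  expect_error(bivariate_gaussian(0, 0, 0, 0, sz, st, 1),
    class = "lymphchain_invalid_parameter"
  )
  expect_error(bivariate_gaussian(0, 0, 0, 0, -1, st, 0),
    class = "lymphchain_invalid_parameter"
  )
})

test_that("activation field is normalized, non-negative and periodic", {
  p <- activation_params(10, 0.98, 8.3, 7.23)
  s <- place_pacemakers(0.3, 10, "antegrade", p$period)
  f <- build_activation_field(s, p, seq(0, 0.3, 0.005), seq(0, 7.225, 0.005))

  expect_identical(max(f$values), 1)
  expect_true(all(f$values >= 0))

  # periodic extension: identical values one period apart, to machine precision
  for (t0 in c(0.3, 1.7, 5.11)) {
    expect_identical(eval_activation(f, t0), eval_activation(f, t0 + p$period))
    expect_identical(eval_activation(f, t0), eval_activation(f, t0 + 3 * p$period))
  }

  expect_error(build_activation_field(s[0, ], p, 0:1, 0:1),
    class = "lymphchain_invalid_parameter"
  )
  expect_error(build_activation_field(s, p, numeric(0), 0:1),
    class = "lymphchain_invalid_parameter"
  )
})

test_that("summation and normalization behave under coincident and separated sites", {
  p <- activation_params(10, 0.98, 8.3, 7.23)
  z <- seq(0, 0.3, 0.0025)
  tg <- seq(0, 7.225, 0.05)

  one <- tibble::tibble(site = 1L, position_z = 0.15, mu_t = p$period / 2, direction = "antegrade")
  two <- dplyr::bind_rows(one, one)
  f1 <- build_activation_field(one, p, z, tg)
  f2 <- build_activation_field(two, p, z, tg)
  # doubling every signal cancels in the normalization
  expect_equal(f2$values, f1$values, tolerance = 1e-12)
  expect_equal(f2$gamma, 2 * f1$gamma, tolerance = 1e-12)

  # single site: field value 1 exactly at (mu_z, mu_t)
  iz <- which(z == 0.15)
  it <- which.min(abs(tg - p$period / 2))
  expect_equal(f1$values[iz, it], max(f1$values))

  # well-separated sites each produce a local maximum near 1
  s3 <- place_pacemakers(0.3, 10, "antegrade", p$period)
  f3 <- build_activation_field(s3, p, z, tg)
  for (pos in s3$position_z) {
    expect_gt(f3$values[which.min(abs(z - pos)), it], 0.99)
  }
})

test_that("skew direction and ridge speed recover the conduction velocity", {
  # slow-conduction parameters so the tilt is resolvable on the grid
  p <- activation_params(11, 0.063, 15.8, 3.80)
  z <- seq(0, 0.3, 0.0025)
  tg <- seq(0, 3.7975, 0.0025)
  fa <- build_activation_field(
    place_pacemakers(0.3, 11, "antegrade", p$period), p, z, tg
  )
  fr <- build_activation_field(
    place_pacemakers(0.3, 11, "retrograde", p$period), p, z, tg
  )

  i0 <- which.min(abs(z - 0.15)) # middle pacemaker
  t_at <- function(f, i) tg[which.max(f$values[i, ])]
  # antegrade: downstream of the site peaks later; retrograde mirrored
  expect_gt(t_at(fa, i0 + 4), t_at(fa, i0))
  expect_lt(t_at(fa, i0 - 4), t_at(fa, i0))
  expect_lt(t_at(fr, i0 + 4), t_at(fr, i0))

  # ridge slope dt/dz near the site equals 1/c within grid resolution
  di <- 1:4
  slope <- stats::coef(stats::lm(
    vapply(i0 + di, function(i) t_at(fa, i), numeric(1)) ~ z[i0 + di]
  ))[2]
  expect_equal(unname(slope), 1 / 0.063, tolerance = 0.15)

  # WT field is near-synchronous; KO shows a measurably larger ridge delay
  pw <- activation_params(10, 0.98, 8.3, 7.23)
  zw <- seq(0, 0.3, 0.0025)
  tw <- seq(0, 7.2275, 0.0025)
  fw <- build_activation_field(
    place_pacemakers(0.3, 10, "antegrade", pw$period), pw, zw, tw
  )
  iw <- which.min(abs(zw - 0.15))
  delay_wt <- abs(tw[which.max(fw$values[iw + 4, ])] - tw[which.max(fw$values[iw, ])])
  delay_ko <- abs(t_at(fa, i0 + 4) - t_at(fa, i0))
  expect_lt(delay_wt, delay_ko)
})

test_that("activation field tidies to a long tibble and plots", {
  p <- activation_params(10, 0.98, 8.3, 7.23)
  s <- place_pacemakers(0.3, 10, "antegrade", p$period)
  f <- build_activation_field(s, p, seq(0, 0.3, 0.01), seq(0, 7, 0.5))
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("z", "t", "activation"))
  expect_equal(nrow(td), length(f$z) * length(f$t))
  expect_s3_class(autoplot(f), "ggplot")
})
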