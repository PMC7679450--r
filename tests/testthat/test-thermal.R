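# Forward solver: analytic oracles, conservation, scheme agreement,
# boundary handling.

test_that("uniform profile at ambient temperature is a fixed point", {
  u <- depth_profile(seq(0, 34, 0.1), rep(25, 341))
  tr <- forward_simulate(u, thermal_properties(), solver_config(duration = 30))
  expect_lt(max(abs(tr$T - 25)), 1e-9)
})

test_that("surface cooling matches the semi-infinite convective closed form", {
  # emissivity 0, deep insulated domain, uniform 40 degC start:
  # T_s(t) = T_inf + (T_i - T_inf) exp(Bi^2) erfc(Bi), Bi = h sqrt(alpha t)/k
  props <- thermal_properties(emissivity = 0, T_air = 25, T_env = 25)
  cfg <- solver_config(depth = 80, duration = 120, bottom_bc = "insulated")
  u <- depth_profile(seq(0, 80, 0.1), rep(40, 801))
  tr <- forward_simulate(u, props, cfg)
  alpha <- props$k / (props$rho * props$cp)
  Bi <- props$h_nc * sqrt(alpha * tr$t) / props$k
  erfc <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)
  T_exact <- 25 + 15 * exp(Bi^2) * erfc(Bi)
  expect_lt(max(abs(tr$T - T_exact)), 0.05)
})

test_that("adiabatic boundaries conserve the spatial mean", {
  props <- thermal_properties(emissivity = 0, h_nc = 0)
  cfg <- solver_config(bottom_bc = "insulated", duration = 60)
  z <- seq(0, 34, 0.1)
  init <- depth_profile(z, 25 + 10 * exp(-(z - 17)^2 / 8))
  snaps <- simulate_field(init, props, cfg, c(0, 20, 40, 60))
  m0 <- mean(snaps[[1L]]$T)
  for (s in snaps) expect_lt(abs(mean(s$T) - m0) / m0, 1e-6)
})

test_that("interior diffusion matches the free-space Gaussian solution", {
  props <- thermal_properties(emissivity = 0, h_nc = 0)
  cfg <- solver_config(bottom_bc = "insulated", duration = 60)
  z <- seq(0, 34, 0.1)
  s0 <- 2
  init <- depth_profile(z, 25 + 10 * exp(-(z - 17)^2 / (2 * s0^2)))
  snaps <- simulate_field(init, props, cfg, 60)
  alpha_mm <- props$k / (props$rho * props$cp) * 1e6  # mm^2/s
  s2 <- s0^2 + 2 * alpha_mm * 60
  T_exact <- 25 + 10 * sqrt(s0^2 / s2) * exp(-(z - 17)^2 / (2 * s2))
  expect_lt(max(abs(snaps[[1L]]$T - T_exact)), 0.02)
})

test_that("implicit and explicit schemes agree on the default fat scenario", {
  pr <- bump_profile()
  tri <- forward_simulate(pr, thermal_properties(), solver_config())
  tre <- forward_simulate(pr, thermal_properties(),
                          solver_config(scheme = "explicit"))
  expect_lt(max(abs(tri$T - tre$T)), 0.02)
})

test_that("refining the grid leaves the surface trace unchanged", {
  pr <- bump_profile()
  tr1 <- forward_simulate(pr, thermal_properties(), solver_config())
  tr2 <- forward_simulate(pr, thermal_properties(),
                          solver_config(dz = 0.05, dt = 0.0125))
  expect_lt(max(abs(tr1$T - tr2$T)), 0.01)
})

test_that("the radiative term vanishes continuously with emissivity", {
  pr <- bump_profile()
  cfg <- solver_config(duration = 40)
  t0 <- forward_simulate(pr, thermal_properties(emissivity = 0), cfg)
  t_small <- forward_simulate(pr, thermal_properties(emissivity = 1e-3), cfg)
  t_half <- forward_simulate(pr, thermal_properties(emissivity = 0.5), cfg)
  d_small <- max(abs(t_small$T - t0$T))
  d_half <- max(abs(t_half$T - t0$T))
  expect_lt(d_small, 0.01)
  expect_lt(d_small, d_half / 100)
})

test_that("solution respects the maximum principle", {
  set.seed(7)
  cfg <- solver_config(duration = 30)
  for (i in 1:5) {
    z <- seq(0, 34, 0.1)
    Tz <- 25 + cumsum(rnorm(length(z), 0, 0.5))
    init <- depth_profile(z, Tz)
    props <- thermal_properties()
    snaps <- simulate_field(init, props, cfg, c(10, 30))
    lo <- min(Tz, props$T_air, props$T_env, cfg$bottom_bc$T_b)
    hi <- max(Tz, props$T_air, props$T_env, cfg$bottom_bc$T_b)
    for (s in snaps) {
      expect_gte(min(s$T), lo - 1e-9)
      expect_lte(max(s$T), hi + 1e-9)
    }
  }
})

test_that("a subsurface peak makes the surface temperature rise first", {
  pr <- bump_profile(z_max = 3, amp = 10)
  tr <- forward_simulate(pr, thermal_properties(), solver_config(duration = 30))
  expect_identical(tr$T[1L], pr$T[1L])  # first sample = initial surface value
  expect_gt(tr$T[6L], tr$T[1L] + 1)    # clear early rise during relaxation
})

test_that("solver configuration is validated", {
  expect_error(solver_config(dz = 5, depth = 34), "at least 10 nodes")
  # explicit stability bound dt <= dz^2 rho cp / (2k)
  expect_error(
    forward_simulate(bump_profile(), thermal_properties(),
                     solver_config(scheme = "explicit", dt = 0.1)),
    "unstable")
  expect_error(solver_config(bottom_bc = "bogus"), "bottom_bc")
  expect_error(
    simulate_field(bump_profile(), thermal_properties(),
                   solver_config(duration = 10), 20),
    "within")
})

test_that("snapshot at t = 0 returns the initial profile on the solver grid", {
  pr <- bump_profile()
  snaps <- simulate_field(pr, thermal_properties(), solver_config(duration = 10), 0)
  z <- seq(0, 34, 0.1)
  expect_equal(snaps[[1L]]$z, z)
  expect_equal(snaps[[1L]]$T, approx(pr$z, pr$T, xout = z, rule = 2)$y)
})

test_that("degenerate layering reproduces the homogeneous solver bitwise", {
  pr <- bump_profile()
  cfg <- solver_config(duration = 20)
  props <- thermal_properties()
  tr1 <- forward_simulate(pr, props, cfg)
  tr2 <- layered_simulate(pr, list(list(thickness = 10, props = props),
                                   list(thickness = 24, props = props)), cfg)
  expect_identical(tr1$T, tr2$T)
})

test_that("two-layer steady state matches series thermal resistance", {
  # fixed bottom at 36, convective top (eps = 0); steady flux
  # q = (T_b - T_air) / (1/h + L1/k1 + L2/k2); interface temperature from
  # the resistance chain
  p1 <- thermal_properties(k = 0.3, emissivity = 0, h_nc = 20, T_air = 20)
  p2 <- thermal_properties(k = 0.5, emissivity = 0, h_nc = 20, T_air = 20)
  cfg <- solver_config(dz = 0.5, dt = 1, depth = 34, duration = 40000,
                       bottom_bc = list(type = "fixed_temperature", T_b = 36))
  init <- depth_profile(seq(0, 34, 0.5), rep(28, 69))
  L1 <- 10e-3; L2 <- 24e-3
  q <- (36 - 20) / (1 / 20 + L1 / 0.3 + L2 / 0.5)
  T_surf_steady <- 20 + q / 20  # surface balance closes the resistance chain
  tr <- layered_simulate(init, list(list(thickness = 10, props = p1),
                                    list(thickness = 24, props = p2)), cfg)
  expect_equal(tr$T[length(tr$T)], T_surf_steady, tolerance = 0.02)
  # trace relaxes into (T_air, T_b) per the maximum principle
  expect_true(all(tr$T[-1] > 20 & tr$T[-1] < 36))
})

test_that("layer thickness mismatch is rejected", {
  pr <- bump_profile()
  props <- thermal_properties()
  expect_error(
    layered_simulate(pr, list(list(thickness = 10, props = props)),
                     solver_config()),
    "sum to")
})
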