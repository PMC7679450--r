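# The candidate profile family, its peak extraction, and the parameter grids.

test_that("power term collapses for B = 0 and the surface identity holds", {
  # B = 0 makes the power term identically 1: constant profile at the anchor
  p <- profile_params(A = 1, B = 0, C = 1, D = 0, T_surf_anchor = 30)
  pr <- generate_profile(p, seq(0, 10, 0.5))
  expect_equal(pr$T, rep(30, length(pr$z)), tolerance = 0)

  # T(0) = anchor - D exactly, for any parameters (the base (0+1)^x = 1)
  set.seed(42)
  for (i in 1:25) {
    p <- profile_params(A = runif(1, 0.2, 5), B = runif(1, 0, 8),
                        C = runif(1, 0.1, 1), D = runif(1, 0, 0.3),
                        T_surf_anchor = runif(1, 20, 40))
    pr <- generate_profile(p)
    expect_equal(pr$T[1L], p$T_surf_anchor - p$D, tolerance = 1e-12)
  }
})

test_that("generated peak matches a dense-grid brute-force maximization", {
  p <- profile_params(A = 1, B = 2, C = 0.5, D = 0.2, T_surf_anchor = 30)
  # independent oracle: direct evaluation of the closed form at 0.001 mm
  z_dense <- seq(0, 34, by = 0.001)
  T_dense <- (30 - 1) + (z_dense + 1)^(2 / (0.5 * (z_dense + 1) + 1)) -
    0.2 * (z_dense + 1)
  j <- which.max(T_dense)
  pm <- peak_metrics(generate_profile(p), refine = TRUE)
  expect_equal(pm$z_max, z_dense[j], tolerance = 0.01)
  expect_equal(pm$T_max, T_dense[j], tolerance = 1e-4)
})

test_that("peak extraction handles boundaries, ties and refinement", {
  z <- seq(0, 10, 0.5)
  # strictly decreasing: boundary maximum at the surface
  dec <- depth_profile(z, 40 - z)
  expect_equal(peak_metrics(dec)$z_max, 0)
  expect_equal(peak_metrics(dec)$T_max, 40)
  # constant: smallest-z tie rule
  expect_equal(peak_metrics(depth_profile(z, rep(25, length(z))))$z_max, 0)
  # parabola peaking at 2.5 mm: quadratic refinement is exact
  par <- depth_profile(z, 40 - (z - 2.5)^2)
  pm <- peak_metrics(par, refine = TRUE)
  expect_equal(pm$z_max, 2.5, tolerance = 1e-9)
  expect_equal(pm$T_max, 40, tolerance = 1e-9)
  # refine off: grid argmax only
  expect_equal(peak_metrics(par, refine = FALSE)$T_max, max(par$T))
})

test_that("profile refinement is stable across grid resolutions", {
  p <- profile_params(A = 1.2, B = 3, C = 0.5, D = 0.05, T_surf_anchor = 29)
  pm_coarse <- peak_metrics(generate_profile(p, seq(0, 34, 0.5)), refine = TRUE)
  pm_fine <- peak_metrics(generate_profile(p, seq(0, 34, 0.05)), refine = TRUE)
  expect_lt(abs(pm_coarse$z_max - pm_fine$z_max), 0.5)
})

test_that("deep field is eventually strictly decreasing when D > 0", {
  for (B in c(1, 4)) {
    p <- profile_params(A = 1, B = B, C = 0.5, D = 0.1, T_surf_anchor = 30)
    pr <- generate_profile(p, seq(0, 34, 0.1))
    tail_T <- pr$T[pr$z >= 25]
    expect_true(all(diff(tail_T) < 0))
  }
})

test_that("profile construction validates its domain", {
  # denominator root inside the range: C(z+1)+A = 0 at z = 19
  p <- profile_params(A = -2, B = 1, C = 0.1, D = 0, T_surf_anchor = 30)
  expect_error(generate_profile(p, seq(0, 34, 0.1)), "denominator")
  expect_error(profile_params(1, 1, 1, -0.1, 30), "D must be")
  expect_error(depth_profile(c(1, 2, 3), c(1, 2, 3)), "start at z = 0")
  expect_error(depth_profile(c(0, 2, 1), c(1, 2, 3)), "strictly increasing")
})

test_that("parameter grid enumerates the Cartesian product deterministically", {
  ranges1 <- list(A = c(1, 1, 1), B = c(2, 2, 1), C = c(0.5, 0.5, 1),
                  D = c(0, 0, 1))
  expect_length(parameter_grid(ranges1, anchor_values = 30), 1L)

  ranges2 <- list(A = c(0.5, 2, 2), B = c(1, 3, 2), C = c(0.3, 0.6, 2),
                  D = c(0, 0.1, 2))
  g <- parameter_grid(ranges2, anchor_values = c(28, 29, 30))
  expect_length(g, 48L)  # 2*2*2*2*3
  # lexicographic order: A slowest, anchor fastest
  expect_equal(g[[1L]]$A, 0.5)
  expect_equal(g[[2L]]$T_surf_anchor, 29)
  expect_equal(g[[48L]]$A, 2)
  # deterministic rebuild
  g2 <- parameter_grid(ranges2, anchor_values = c(28, 29, 30))
  expect_identical(g, g2)
})

test_that("parameter grid drops singular-denominator combinations with a count", {
  # A = -2 with C = 0.1 has its denominator root at z = 19, inside the range
  ranges <- list(A = c(-2, 1, 2), B = c(1, 1, 1), C = c(0.1, 0.1, 1),
                 D = c(0, 0, 1))
  expect_message(g <- parameter_grid(ranges, anchor_values = 30),
                 "dropped 1 of 2")
  expect_length(g, 1L)
  expect_identical(attr(g, "n_dropped"), 1L)
  # analytic check: surviving entry has no root in range
  expect_false(0.1 * (0:34 + 1)[1] + g[[1L]]$A == 0)
})

test_that("inverse design hits requested peak depth and amplitude", {
  for (tgt in list(c(2, 5), c(4.5, 12), c(7, 18))) {
    p <- solve_profile_params(tgt[1], tgt[2], C = 0.5, D = 0.05,
                              T_surf_anchor = 29)
    pr <- generate_profile(p, seq(0, 34, 0.005))
    pm <- peak_metrics(pr, refine = TRUE)
    expect_equal(pm$z_max, tgt[1], tolerance = 0.03)
    expect_equal(pm$T_max - pr$T[length(pr$T)], tgt[2], tolerance = 0.03)
  }
})

test_that("designed grid spans the intended peak-space coverage", {
  g <- design_grid(z_targets = c(1, 5, 10, 15), amp_targets = c(2, 10, 25),
                   C = 0.55, D = 0.02, anchors = 29,
                   surface_peak_D = 0.2)
  peaks <- t(vapply(g, function(p) {
    pr <- generate_profile(p, seq(0, 34, 0.02))
    pm <- peak_metrics(pr, refine = TRUE)
    c(pm$z_max, pm$T_max - pr$T[length(pr$T)])
  }, numeric(2)))
  expect_lte(min(peaks[, 1]), 0.01)   # surface-peak entries reach z_max = 0
  expect_gte(max(peaks[, 1]), 14.5)
  expect_lte(min(peaks[, 2]), 2.5)
  expect_gte(max(peaks[, 2]), 24)
})
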