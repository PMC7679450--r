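# Shared small fixtures. Heavy objects are built lazily and cached for the
# whole test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

fat_props <- function(...) thermal_properties(...)

# short-duration solver config for cheap module tests
quick_cfg <- function(duration = 20, ...) solver_config(duration = duration, ...)

# a small designed database: 3 depths x 3 amplitudes x 2 anchors (+ monotone
# entries), 20 s traces
small_db <- function() {
  cached("small_db", {
    grid <- design_grid(z_targets = c(1.5, 3, 5), amp_targets = c(4, 8, 12),
                        C = 0.55, D = 0.04, anchors = c(28.5, 29),
                        surface_peak_D = 0.2)
    build_database(grid, fat_props(), quick_cfg(), quiet = TRUE)
  })
}

# a representative subsurface-peaked profile
bump_profile <- function(z_max = 3, amp = 10, anchor = 29) {
  p <- solve_profile_params(z_max, amp, C = 0.55, D = 0.04,
                            T_surf_anchor = anchor)
  generate_profile(p, default_z_grid())
}

expect_trace_equal <- function(a, b, tol = 0) {
  expect_equal(a$t, b$t)
  if (tol == 0) expect_identical(a$T, b$T) else expect_equal(a$T, b$T, tolerance = tol)
}
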