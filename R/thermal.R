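#' Thermal properties of the medium and its surface exchange
#'
#' Defaults are the fat-tissue values used throughout: density 860 kg/m3,
#' specific heat 2870 J/(kg K), conductivity 0.23 W/(m K) (plausible range
#' 0.17-0.32 for subcutaneous fat), emissivity 0.98, natural-convection
#' coefficient 13 W/(m2 K) (evaporative losses folded in, as is standard for
#' dry surfaces below 60 degC), with air and radiative surroundings at room
#' temperature. The Stefan-Boltzmann constant is fixed at 5.67e-8 W/(m2 K4)
#' and is not a parameter.
#'
#' @param rho mass density, kg/m3.
#' @param cp specific heat, J/(kg K).
#' @param k thermal conductivity, W/(m K).
#' @param emissivity surface emissivity, in (0, 1]; 0 disables radiation.
#' @param h_nc natural-convection heat-transfer coefficient, W/(m2 K).
#' @param T_air air temperature at the surface, degC.
#' @param T_env surrounding radiative temperature, degC.
#' @export
thermal_properties <- function(rho = 860, cp = 2870, k = 0.23,
                               emissivity = 0.98, h_nc = 13,
                               T_air = 25, T_env = 25) {
  if (rho <= 0 || cp <= 0 || k <= 0)
    stop("rho, cp and k must be positive", call. = FALSE)
  if (emissivity < 0 || emissivity > 1)
    stop("emissivity must lie in [0, 1]", call. = FALSE)
  if (h_nc < 0) stop("h_nc must be >= 0", call. = FALSE)
  structure(list(rho = rho, cp = cp, k = k, emissivity = emissivity,
                 h_nc = h_nc, T_air = T_air, T_env = T_env,
                 stefan_boltzmann = 5.67e-8),
            class = "thermal_properties")
}

#' Finite-volume solver configuration
#'
#' @param dz spatial step, mm.
#' @param dt time step, s.
#' @param depth domain depth, mm (at least 10 nodes).
#' @param duration simulated time, s.
#' @param scheme \code{"implicit"} (Crank-Nicolson, second order in time and
#'   unconditionally stable; the default) or \code{"explicit"} (FTCS, kept as
#'   a cross-check and subject to \code{dt <= dz^2 rho cp / (2 k)}).
#' @param bottom_bc either the string \code{"insulated"} or a list
#'   \code{list(type = "fixed_temperature", T_b = <degC>)} (water-bath
#'   condition, the default at 25 degC).
#' @param output_rate surface-trace sampling rate, Hz.
#' @export
solver_config <- function(dz = 0.1, dt = 0.05, depth = 34, duration = 120,
                          scheme = c("implicit", "explicit"),
                          bottom_bc = list(type = "fixed_temperature", T_b = 25),
                          output_rate = 1) {
  scheme <- match.arg(scheme)
  if (dz <= 0 || dt <= 0 || depth <= 0 || duration <= 0 || output_rate <= 0)
    stop("dz, dt, depth, duration and output_rate must be positive",
         call. = FALSE)
  if (depth / dz < 9)
    stop("depth/dz must give at least 10 nodes", call. = FALSE)
  bottom_bc <- normalize_bottom_bc(bottom_bc)
  structure(list(dz = dz, dt = dt, depth = depth, duration = duration,
                 scheme = scheme, bottom_bc = bottom_bc,
                 output_rate = output_rate),
            class = "solver_config")
}

normalize_bottom_bc <- function(bc) {
  if (is.character(bc) && length(bc) == 1L && bc == "insulated")
    return(list(type = "insulated"))
  if (is.list(bc) && identical(bc$type, "insulated"))
    return(list(type = "insulated"))
  if (is.list(bc) && identical(bc$type, "fixed_temperature")) {
    if (is.null(bc$T_b) || !is.finite(bc$T_b))
      stop("fixed_temperature bottom boundary requires a finite T_b",
           call. = FALSE)
    return(list(type = "fixed_temperature", T_b = as.numeric(bc$T_b)))
  }
  stop("bottom_bc must be \"insulated\" or list(type = \"fixed_temperature\", T_b = ...)",
       call. = FALSE)
}

#' Uniformly sampled surface-temperature time series
#'
#' @param t time since the start of the inactive period, s; uniform spacing
#'   starting at 0.
#' @param T surface temperature, degC.
#' @param meta provenance tag: \code{"simulated"}, \code{"measured"} or
#'   \code{"synthetic"}.
#' @export
surface_trace <- function(t, T, meta = c("simulated", "measured", "synthetic")) {
  meta <- match.arg(meta)
  t <- as.numeric(t); T <- as.numeric(T)
  if (length(t) != length(T) || length(t) < 2L)
    stop("t and T must have equal length >= 2", call. = FALSE)
  if (abs(t[1L]) > 1e-9) stop("trace must start at t = 0", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) stop("time stamps must be strictly increasing", call. = FALSE)
  if (max(abs(dt - mean(dt))) > 1e-9 * max(mean(dt), 1))
    stop("time stamps must be uniformly spaced", call. = FALSE)
  if (any(!is.finite(T))) stop("trace temperatures must be finite", call. = FALSE)
  structure(list(t = t, T = T, meta = meta), class = "surface_trace")
}

#' @export
print.surface_trace <- function(x, ...) {
  cat(sprintf("surface_trace [%s]: %d samples over %.4g s, %.2f -> %.2f degC\n",
              x$meta, length(x$t), max(x$t), x$T[1L], x$T[length(x$T)]))
  invisible(x)
}

# Shared plumbing: interpolate the initial profile onto the solver grid
# (flat extrapolation past its last node), run the compiled marcher.
run_solver <- function(initial, cfg, k_node, rho_cp_node, surf,
                       record_steps, snapshot_steps) {
  z_solver <- seq(0, cfg$depth, by = cfg$dz)
  T0 <- approx(initial$z, initial$T, xout = z_solver, rule = 2)$y
  bc <- cfg$bottom_bc
  .heat_march(T0, cfg$dz * 1e-3, cfg$dt, as.integer(round(cfg$duration / cfg$dt)),
              k_node, rho_cp_node,
              surf$h_nc, surf$emissivity, surf$T_air, surf$T_env,
              if (bc$type == "fixed_temperature") 0L else 1L,
              if (bc$type == "fixed_temperature") bc$T_b else 0,
              if (cfg$scheme == "explicit") 1L else 0L,
              as.integer(record_steps), as.integer(snapshot_steps))
}

check_explicit_stability <- function(props, cfg) {
  dz_m <- cfg$dz * 1e-3
  dt_max <- dz_m^2 * props$rho * props$cp / (2 * props$k)
  if (cfg$dt > dt_max)
    stop(sprintf("explicit scheme unstable: dt = %g s exceeds dz^2*rho*cp/(2k) = %g s",
                 cfg$dt, dt_max), call. = FALSE)
}

#' Forward-simulate the relaxation of a depth profile
#'
#' Integrates the 1D heat-diffusion equation
#' \eqn{\rho c_p \partial T/\partial t = k \partial^2 T/\partial z^2}
#' (no source terms: the laser and forced cooling are off during the inactive
#' period) from the given initial depth profile, with the surface flux balance
#' \eqn{-k \partial T/\partial z = h_{NC} (T_{air} - T_{surf}) +
#' \sigma \epsilon (T_{env}^4 - T_{surf}^4)} — the radiative quartic evaluated
#' on the Kelvin scale — and the configured bottom boundary. Returns the
#' surface-node temperature sampled at \code{cfg$output_rate}.
#'
#' @param initial a [depth_profile()]; values beyond its last node are held
#'   constant when transferring onto the solver grid.
#' @param props a [thermal_properties()] object.
#' @param cfg a [solver_config()] object.
#' @return a [surface_trace()] with \code{meta = "simulated"}; its first
#'   sample equals the initial profile's surface value.
#' @export
forward_simulate <- function(initial, props, cfg) {
  stopifnot(inherits(initial, "depth_profile"),
            inherits(props, "thermal_properties"),
            inherits(cfg, "solver_config"))
  if (cfg$scheme == "explicit") check_explicit_stability(props, cfg)
  n <- length(seq(0, cfg$depth, by = cfg$dz))
  t_out <- seq(0, cfg$duration, by = 1 / cfg$output_rate)
  record_steps <- round(t_out / cfg$dt)
  res <- run_solver(initial, cfg,
                    rep(props$k, n), rep(props$rho * props$cp, n),
                    props, record_steps, integer(0))
  surface_trace(record_steps * cfg$dt, res$surface, meta = "simulated")
}

#' Full temperature-field snapshots during relaxation
#'
#' Same integration as [forward_simulate()] but returns the whole depth field
#' at the requested times (nearest time step).
#'
#' @inheritParams forward_simulate
#' @param snapshot_times times (s) at which to capture the field; must lie in
#'   \code{[0, cfg$duration]}.
#' @return list of [depth_profile()] objects, one per snapshot time.
#' @export
simulate_field <- function(initial, props, cfg, snapshot_times) {
  stopifnot(inherits(initial, "depth_profile"),
            inherits(props, "thermal_properties"),
            inherits(cfg, "solver_config"))
  if (any(snapshot_times < 0 | snapshot_times > cfg$duration))
    stop("snapshot times must lie within [0, duration]", call. = FALSE)
  if (cfg$scheme == "explicit") check_explicit_stability(props, cfg)
  steps <- sort(unique(round(snapshot_times / cfg$dt)))
  n <- length(seq(0, cfg$depth, by = cfg$dz))
  res <- run_solver(initial, cfg,
                    rep(props$k, n), rep(props$rho * props$cp, n),
                    props, integer(0), steps)
  z_solver <- seq(0, cfg$depth, by = cfg$dz)
  lapply(seq_along(steps), function(i)
    depth_profile(z_solver, res$snapshots[, i], role = "candidate"))
}

#' Relaxation of a layered (in-vivo style) medium
#'
#' Multi-layer 1D conduction with piecewise-constant properties: each node
#' takes the properties of the layer containing it, and face conductivities
#' are harmonic means, which enforces flux continuity across interfaces.
#' Surface exchange parameters (h_nc, emissivity, air/surroundings) are taken
#' from the first (surface) layer. Intended for in-vivo style scenarios, e.g.
#' skin over fat with the deep boundary fixed at body temperature (36 degC).
#'
#' @param initial a [depth_profile()].
#' @param layers list of \code{list(thickness = <mm>, props =
#'   thermal_properties(...))}; thicknesses must sum to \code{cfg$depth}.
#' @param cfg a [solver_config()] object.
#' @return a [surface_trace()] with \code{meta = "simulated"}.
#' @export
layered_simulate <- function(initial, layers, cfg) {
  stopifnot(inherits(initial, "depth_profile"), inherits(cfg, "solver_config"))
  thick <- vapply(layers, function(l) as.numeric(l$thickness), numeric(1))
  if (any(thick <= 0)) stop("layer thicknesses must be positive", call. = FALSE)
  if (abs(sum(thick) - cfg$depth) > 1e-9)
    stop(sprintf("layer thicknesses sum to %g mm but cfg$depth is %g mm",
                 sum(thick), cfg$depth), call. = FALSE)
  for (l in layers) stopifnot(inherits(l$props, "thermal_properties"))
  z_solver <- seq(0, cfg$depth, by = cfg$dz)
  bounds <- cumsum(thick)
  layer_of <- pmin(findInterval(z_solver, c(0, bounds), left.open = TRUE) + 0L,
                   length(layers))
  layer_of[1L] <- 1L
  k_node <- vapply(layer_of, function(i) layers[[i]]$props$k, numeric(1))
  rc_node <- vapply(layer_of, function(i)
    layers[[i]]$props$rho * layers[[i]]$props$cp, numeric(1))
  surf <- layers[[1L]]$props
  if (cfg$scheme == "explicit") {
    for (l in layers) check_explicit_stability(l$props, cfg)
  }
  t_out <- seq(0, cfg$duration, by = 1 / cfg$output_rate)
  record_steps <- round(t_out / cfg$dt)
  res <- run_solver(initial, cfg, k_node, rc_node, surf,
                    record_steps, integer(0))
  surface_trace(record_steps * cfg$dt, res$surface, meta = "simulated")
}
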