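#' Default database grid specification
#'
#' The designed ladder used for the package's default database. Resolution is
#' concentrated where a 120 s surface observation is sensitive (the thermal
#' diffusion length in fat is about 6.7 mm) and where the emulated treatment
#' profiles live: a core ladder of peak depths 0.5-8.2 mm every 0.45 mm
#' crossed with amplitudes 2-18.2 degC every 0.6 degC, extended by a coarse
#' coverage ladder out to 15 mm depth and 25 degC amplitude, a shared shape
#' C = 0.55 and bulk slope D = 0.04 degC/mm, plus monotone surface-peak
#' entries; surface anchors default to a 28-30 degC ladder every 0.25 degC.
#' About 5,100 entries.
#'
#' @param anchors surface anchor ladder, degC. For matching a single measured
#'   trace, a practical choice is \code{anchor_bracket(trace)}.
#' @return list passed to [design_grid()]; the core and coverage ladders are
#'   encoded as (depth, amplitude) target pairs.
#' @export
default_grid_spec <- function(anchors = seq(28, 30, by = 0.25)) {
  core <- expand.grid(z = seq(0.5, 8.2, by = 0.45),
                      amp = seq(2, 18.2, by = 0.6))
  deep <- expand.grid(z = seq(9, 15, by = 1.5), amp = seq(3, 25, by = 3))
  hot <- expand.grid(z = c(1, 3, 5, 7), amp = seq(19.5, 25, by = 1.5))
  list(targets = rbind(core, deep, hot),
       C = 0.55, D = 0.04,
       anchors = anchors,
       cell = c(z = 0.45, amp = 0.6))  # core ladder resolution
}

#' Anchor bracket around a measured trace's initial temperature
#'
#' Surface anchors for database construction, centred on the first sample of
#' the measured trace: \code{trace(0) +- half_width} in \code{step} degC
#' increments (the estimated profile must be consistent with the observed
#' initial surface temperature).
#'
#' @param trace a [surface_trace()].
#' @param half_width bracket half-width, degC.
#' @param step ladder step, degC.
#' @export
anchor_bracket <- function(trace, half_width = 1, step = 0.25) {
  stopifnot(inherits(trace, "surface_trace"))
  t0 <- trace$T[1L]
  seq(t0 - half_width, t0 + half_width, by = step)
}

#' Build the default candidate database
#'
#' [design_grid()] on [default_grid_spec()] forward-simulated with the fat
#' properties and default solver settings.
#'
#' @param grid_spec as returned by [default_grid_spec()].
#' @param props a [thermal_properties()].
#' @param cfg a [solver_config()].
#' @param quiet passed to [build_database()].
#' @export
default_database <- function(grid_spec = default_grid_spec(),
                             props = thermal_properties(),
                             cfg = solver_config(), quiet = FALSE) {
  grid <- do.call(design_grid,
                  grid_spec[intersect(names(grid_spec),
                                      names(formals(design_grid)))])
  build_database(grid, props, cfg, quiet = quiet)
}

#' Synthetic peak-recovery study
#'
#' The package's end-to-end validation experiment, mirroring the ex-vivo
#' protocol with simulated truths: draw a seeded ensemble of off-grid truth
#' profiles ([scenario_suite()]), forward-simulate each relaxation, add
#' sensor noise, match every noisy trace against the database at each
#' requested window length, and tabulate the peak-error estimators dT_max and
#' dz_max against the known truths.
#'
#' @param n_per_class scenarios per amplitude class (ensemble size is twice
#'   this).
#' @param seed master seed for the scenario suite.
#' @param windows matching windows t_m, s.
#' @param db a prebuilt \code{profile_db}, or \code{NULL} to build
#'   [default_database()].
#' @param props,cfg physical properties and solver settings (used for truth
#'   simulation and, when \code{db} is NULL, the database build).
#' @param quiet suppress progress messages.
#' @return data frame with one row per (scenario, window): scenario id,
#'   amplitude class, true/estimated peak metrics, \code{dT_max},
#'   \code{dz_max}, residual; the database is attached as attribute
#'   \code{db}.
#' @export
peak_recovery_study <- function(n_per_class = 15, seed = 1,
                                windows = c(30, 60, 90, 120),
                                db = NULL,
                                props = thermal_properties(),
                                cfg = solver_config(),
                                quiet = FALSE) {
  if (is.null(db)) db <- default_database(props = props, cfg = cfg,
                                          quiet = quiet)
  suite <- scenario_suite(n_per_class, seed)
  rows <- list()
  for (i in seq_along(suite)) {
    sc <- suite[[i]]
    truth <- make_truth(sc)
    trace <- synth_trace(truth, props, cfg, sc)
    sweep <- tm_sweep(trace, truth, db, windows)
    pk <- attr(truth, "peak")
    rows[[i]] <- data.frame(
      scenario = i, class = sc$amplitude_class,
      amplitude = attr(truth, "amplitude"),
      T_max_true = pk$T_max, z_max_true = pk$z_max,
      sweep, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "db") <- db
  out
}

#' Summarize a recovery study per window
#'
#' @param study output of [peak_recovery_study()].
#' @return data frame per window: mean and median absolute errors, standard
#'   deviations of the signed errors, ensemble size.
#' @export
summarize_recovery <- function(study) {
  do.call(rbind, lapply(split(study, study$t_m), function(s)
    data.frame(t_m = s$t_m[1L],
               n = nrow(s),
               mean_abs_dT = mean(abs(s$dT_max)),
               mean_abs_dz = mean(abs(s$dz_max)),
               median_abs_dT = median(abs(s$dT_max)),
               median_abs_dz = median(abs(s$dz_max)),
               sd_dT = sd(s$dT_max),
               sd_dz = sd(s$dz_max))))
}
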