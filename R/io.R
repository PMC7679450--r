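# CSV/JSON readers and writers. Conventions everywhere: depth z in mm with
# z = 0 at the air-tissue surface (positive downward); time in s with t = 0
# at the start of the inactive period; temperatures in degC.

read_two_col <- function(path, col1, col2) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c(col1, col2) %in% names(df)))
    stop(sprintf("%s: expected columns '%s,%s', found '%s'",
                 path, col1, col2, paste(names(df), collapse = ",")),
         call. = FALSE)
  x <- df[[col1]]; y <- df[[col2]]
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad))
    stop(sprintf("%s: non-finite value at data row %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  list(x = x, y = y)
}

#' Read a surface trace from CSV
#'
#' Expects header \code{time_s,temperature_C}. Non-uniform (jittered) time
#' stamps are resampled onto a uniform grid by linear interpolation, with a
#' warning; non-monotone stamps or non-finite values are errors naming the
#' offending rows.
#'
#' @param path CSV file path.
#' @param meta provenance tag for the returned trace.
#' @return a [surface_trace()].
#' @export
read_trace <- function(path, meta = "measured") {
  d <- read_two_col(path, "time_s", "temperature_C")
  t <- d$x; T <- d$y
  mono <- which(diff(t) <= 0)
  if (length(mono))
    stop(sprintf("%s: time stamps not strictly increasing at data row %s",
                 path, paste(mono + 1L, collapse = ", ")), call. = FALSE)
  if (abs(t[1L]) > 1e-9)
    stop(path, ": trace must start at t = 0", call. = FALSE)
  dt <- diff(t)
  if (max(abs(dt - mean(dt))) > 1e-9 * max(mean(dt), 1)) {
    warning(sprintf("%s: non-uniform time stamps; resampling %d samples onto a uniform grid",
                    path, length(t)), call. = FALSE)
    tu <- seq(0, t[length(t)], length.out = length(t))
    T <- approx(t, T, xout = tu)$y
    t <- tu
  }
  surface_trace(t, T, meta = meta)
}

#' Read a depth profile from CSV
#'
#' Expects header \code{depth_mm,temperature_C}; the depth column must start
#' at 0 (the tissue surface) and increase strictly.
#'
#' @param path CSV file path.
#' @param role role tag for the returned profile.
#' @return a [depth_profile()].
#' @export
read_profile <- function(path, role = "reference") {
  d <- read_two_col(path, "depth_mm", "temperature_C")
  if (abs(d$x[1L]) > 1e-12)
    stop(path, ": depth column must start at 0 (tissue surface)", call. = FALSE)
  depth_profile(d$x, d$y, role = role)
}

#' Write a depth profile / surface trace to CSV
#'
#' Numeric values are serialized with 17 significant digits so that
#' write-then-read reproduces them exactly.
#'
#' @param profile a [depth_profile()].
#' @param trace a [surface_trace()].
#' @param path destination CSV.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "depth_profile"))
  write_num_csv(data.frame(depth_mm = profile$z, temperature_C = profile$T),
                path)
  invisible(path)
}

#' @rdname write_profile
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "surface_trace"))
  write_num_csv(data.frame(time_s = trace$t, temperature_C = trace$T), path)
  invisible(path)
}

#' Write a match result as JSON (plus the estimated profile as CSV)
#'
#' @param result a \code{match_result} from [match_trace()].
#' @param path destination JSON path; the estimated profile is written next
#'   to it as \code{<path-sans-ext>_profile.csv}.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "match_result"))
  prof_path <- sub("\\.json$", "", path)
  prof_path <- paste0(prof_path, "_profile.csv")
  write_profile(result$estimated_profile, prof_path)
  pm <- peak_metrics(result$estimated_profile)
  jsonlite::write_json(
    list(best_params = unclass(result$best_params),
         T_max = pm$T_max, z_max = pm$z_max,
         residual = result$residual, t_m_used = result$t_m_used,
         n_candidates = result$n_candidates,
         runner_up_gap = result$runner_up_gap,
         index = result$index,
         estimated_profile = basename(prof_path)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from JSON
#'
#' Top-level keys: \code{properties}, \code{solver}, \code{grid_spec},
#' \code{match}, \code{paths}, \code{log_level}; all optional, unknown keys
#' (at the top level and inside \code{properties}/\code{solver}/\code{match})
#' are rejected with an error. Missing sections fall back to package
#' defaults.
#'
#' @param path JSON file path.
#' @return list with components \code{properties} ([thermal_properties()]),
#'   \code{solver} ([solver_config()]), \code{match} ([match_config()]),
#'   \code{grid_spec}, \code{paths}, \code{log_level}.
#' @export
read_run_config <- function(path) {
  cfgj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("properties", "solver", "grid_spec", "match", "paths", "log_level")
  extra <- setdiff(names(cfgj), known)
  if (length(extra))
    stop(sprintf("%s: unknown configuration key(s): %s", path,
                 paste(extra, collapse = ", ")), call. = FALSE)
  check_keys <- function(x, allowed, section) {
    x <- if (is.null(x)) list() else as.list(x)
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop(sprintf("%s: unknown key(s) in '%s': %s", path, section,
                   paste(extra, collapse = ", ")), call. = FALSE)
    x
  }
  props <- do.call(thermal_properties,
                   check_keys(cfgj$properties,
                              setdiff(names(formals(thermal_properties)), ""),
                              "properties"))
  solver <- do.call(solver_config,
                    check_keys(cfgj$solver,
                               setdiff(names(formals(solver_config)), ""),
                               "solver"))
  match <- do.call(match_config,
                   check_keys(cfgj$match,
                              setdiff(names(formals(match_config)), ""),
                              "match"))
  list(properties = props, solver = solver, match = match,
       grid_spec = cfgj$grid_spec, paths = cfgj$paths,
       log_level = if (is.null(cfgj$log_level)) "info" else cfgj$log_level)
}
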