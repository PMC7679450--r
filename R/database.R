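#' Build the candidate-profile database
#'
#' For every parameter set in \code{grid}, evaluates the candidate profile on
#' the solver depth grid and forward-simulates its 120 s (by default)
#' relaxation, storing profile and surface trace column-wise. All entries
#' share one depth grid and one time grid; entry order follows \code{grid}.
#'
#' @param grid list of [profile_params()] (from [parameter_grid()],
#'   [design_grid()], or hand-built).
#' @param props a [thermal_properties()] object.
#' @param cfg a [solver_config()] object.
#' @param quiet suppress the progress message.
#' @return an object of class \code{profile_db} with elements \code{params}
#'   (data frame), \code{z}, \code{t}, \code{profiles} (depth x entry),
#'   \code{traces} (time x entry), \code{peaks} (refined peak metrics per
#'   entry), \code{props}, \code{solver} and \code{fingerprint}.
#' @export
build_database <- function(grid, props, cfg, quiet = FALSE) {
  stopifnot(inherits(props, "thermal_properties"),
            inherits(cfg, "solver_config"))
  if (!is.list(grid) || length(grid) == 0L)
    stop("grid must be a non-empty list of profile_params", call. = FALSE)
  for (p in grid)
    if (!inherits(p, "profile_params"))
      stop("grid entries must be profile_params objects", call. = FALSE)
  if (length(grid) > 1e5)
    warning("database has more than 1e5 entries; consider a coarser grid ",
            "(accuracy/computation tradeoff)", call. = FALSE)
  z <- seq(0, cfg$depth, by = cfg$dz)
  t_out <- round(seq(0, cfg$duration, by = 1 / cfg$output_rate) / cfg$dt) * cfg$dt
  n <- length(grid)
  profiles <- matrix(NA_real_, length(z), n)
  traces <- matrix(NA_real_, length(t_out), n)
  ok <- logical(n)
  t0 <- Sys.time()
  for (i in seq_len(n)) {
    pr <- tryCatch(generate_profile(grid[[i]], z), error = function(e) NULL)
    if (is.null(pr)) next
    profiles[, i] <- pr$T
    traces[, i] <- forward_simulate(pr, props, cfg)$T
    ok[i] <- TRUE
  }
  if (!any(ok))
    stop("no valid database entries: every parameter set failed on the solver grid",
         call. = FALSE)
  n_bad <- sum(!ok)
  params <- do.call(rbind, lapply(grid[ok], function(p)
    data.frame(A = p$A, B = p$B, C = p$C, D = p$D,
               T_surf_anchor = p$T_surf_anchor)))
  profiles <- profiles[, ok, drop = FALSE]
  traces <- traces[, ok, drop = FALSE]
  peaks <- do.call(rbind, lapply(seq_len(ncol(profiles)), function(i) {
    pm <- peak_metrics(depth_profile(z, profiles[, i]))
    data.frame(T_max = pm$T_max, z_max = pm$z_max)
  }))
  db <- structure(list(params = params, z = z, t = t_out,
                       profiles = profiles, traces = traces, peaks = peaks,
                       props = props, solver = cfg,
                       fingerprint = db_fingerprint(params, props, cfg),
                       version = DB_FORMAT_VERSION),
                  class = "profile_db")
  if (!quiet)
    message(sprintf("build_database: %d entries (%d invalid dropped) in %.1f s",
                    ncol(traces), n_bad,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  db
}

DB_FORMAT_VERSION <- "1"

# Content hash over a canonical text serialization of the inputs that
# determine the database: realized parameter table, physical properties and
# solver configuration. Uses base R's md5 (tools::md5sum) via a temp file.
db_fingerprint <- function(params, props, cfg) {
  canon <- c(
    apply(params, 1L, function(r) paste(sprintf("%.17g", r), collapse = ",")),
    paste(sprintf("%.17g", unlist(props, use.names = FALSE)), collapse = ","),
    paste(c(sprintf("%.17g", c(cfg$dz, cfg$dt, cfg$depth, cfg$duration,
                               cfg$output_rate)),
            cfg$scheme, cfg$bottom_bc$type,
            if (!is.null(cfg$bottom_bc$T_b)) sprintf("%.17g", cfg$bottom_bc$T_b)),
          collapse = ","))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(canon, f)
  unname(tools::md5sum(f))
}

#' @export
print.profile_db <- function(x, ...) {
  cat(sprintf("profile_db: %d entries, depth 0-%.4g mm (%d nodes), trace 0-%.4g s (%d samples)\n",
              ncol(x$traces), max(x$z), length(x$z), max(x$t), length(x$t)))
  cat(sprintf("  fingerprint %s\n", x$fingerprint))
  invisible(x)
}

db_entry_params <- function(db, i) {
  p <- db$params[i, ]
  profile_params(p$A, p$B, p$C, p$D, p$T_surf_anchor)
}

fmt17 <- function(x) sprintf("%.17g", x)

write_num_csv <- function(df, path) {
  cols <- lapply(df, function(col) if (is.numeric(col)) fmt17(col) else as.character(col))
  out <- do.call(paste, c(cols, sep = ","))
  writeLines(c(paste(names(df), collapse = ","), out), path)
}

#' Persist / restore a profile database
#'
#' \code{save_database()} writes a directory holding a JSON manifest
#' (format version, fingerprint, properties, solver configuration, entry
#' count) plus columnar CSV payloads at 17 significant digits, so that
#' \code{load_database()} reproduces every numeric array exactly. On load the
#' fingerprint is recomputed from the restored content and must equal the
#' manifest's, otherwise a corruption error is raised.
#'
#' @param db a \code{profile_db}.
#' @param path directory to create/fill.
#' @return \code{save_database()} the path, invisibly; \code{load_database()}
#'   a \code{profile_db}.
#' @export
save_database <- function(db, path) {
  stopifnot(inherits(db, "profile_db"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    format_version = db$version,
    fingerprint = db$fingerprint,
    n_entries = ncol(db$traces),
    n_depth = length(db$z),
    n_time = length(db$t),
    props = unclass(db$props),
    solver = unclass(db$solver))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_num_csv(db$params, file.path(path, "params.csv"))
  write_num_csv(data.frame(depth_mm = db$z), file.path(path, "depth_grid.csv"))
  write_num_csv(data.frame(time_s = db$t), file.path(path, "time_grid.csv"))
  writeLines(apply(db$profiles, 2L, function(col) paste(fmt17(col), collapse = ",")),
             file.path(path, "profiles.csv"))
  writeLines(apply(db$traces, 2L, function(col) paste(fmt17(col), collapse = ",")),
             file.path(path, "traces.csv"))
  invisible(path)
}

#' @rdname save_database
#' @export
load_database <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", path, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(as.character(manifest$format_version), DB_FORMAT_VERSION))
    stop(sprintf("incompatible database format version %s (expected %s)",
                 manifest$format_version, DB_FORMAT_VERSION), call. = FALSE)
  params <- utils::read.csv(file.path(path, "params.csv"))
  z <- utils::read.csv(file.path(path, "depth_grid.csv"))$depth_mm
  t_out <- utils::read.csv(file.path(path, "time_grid.csv"))$time_s
  read_mat <- function(file, nrow_expect, ncol_expect) {
    lines <- readLines(file.path(path, file))
    if (length(lines) != ncol_expect)
      stop(sprintf("corrupt database payload: %s has %d entries, manifest says %d",
                   file, length(lines), ncol_expect), call. = FALSE)
    m <- vapply(strsplit(lines, ",", fixed = TRUE), function(x) {
      v <- as.numeric(x)
      if (length(v) != nrow_expect || any(!is.finite(v)))
        stop(sprintf("corrupt database payload in %s", file), call. = FALSE)
      v
    }, numeric(nrow_expect))
    matrix(m, nrow = nrow_expect)
  }
  if (nrow(params) != manifest$n_entries)
    stop("corrupt database payload: params.csv row count does not match manifest",
         call. = FALSE)
  profiles <- read_mat("profiles.csv", manifest$n_depth, manifest$n_entries)
  traces <- read_mat("traces.csv", manifest$n_time, manifest$n_entries)
  props <- do.call(thermal_properties,
                   manifest$props[setdiff(names(manifest$props), "stefan_boltzmann")])
  sv <- manifest$solver
  cfg <- solver_config(dz = sv$dz, dt = sv$dt, depth = sv$depth,
                       duration = sv$duration, scheme = sv$scheme,
                       bottom_bc = sv$bottom_bc, output_rate = sv$output_rate)
  fp <- db_fingerprint(params, props, cfg)
  if (!identical(fp, manifest$fingerprint))
    stop("database fingerprint mismatch: content does not match manifest ",
         "(corrupted or edited database)", call. = FALSE)
  peaks <- do.call(rbind, lapply(seq_len(ncol(profiles)), function(i) {
    pm <- peak_metrics(depth_profile(z, profiles[, i]))
    data.frame(T_max = pm$T_max, z_max = pm$z_max)
  }))
  structure(list(params = params, z = z, t = t_out, profiles = profiles,
                 traces = traces, peaks = peaks, props = props, solver = cfg,
                 fingerprint = fp, version = DB_FORMAT_VERSION),
            class = "profile_db")
}
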