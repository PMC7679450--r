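#' Matching configuration
#'
#' @param t_m matching window length, s; the inversion uses the trace segment
#'   \code{[0, t_m]} of the inactive period.
#' @param metric fit metric; only \code{"rmse"} (root-mean-square deviation
#'   over uniformly weighted samples) is implemented.
#' @param anchor_tolerance candidates whose simulated trace differs from the
#'   measurement by more than this at t = 0 are excluded before matching,
#'   degC. The default 0.3 covers the 0.25 degC anchor-ladder quantization
#'   plus sensor noise on the first sample while pruning candidates whose
#'   initial surface temperature contradicts the measurement (those otherwise
#'   act as impostors, trading an initial-temperature offset against peak
#'   depth along a flat residual valley).
#' @export
match_config <- function(t_m = 120, metric = "rmse", anchor_tolerance = 0.3) {
  metric <- match.arg(metric, "rmse")
  if (t_m <= 0) stop("t_m must be positive", call. = FALSE)
  if (anchor_tolerance <= 0) stop("anchor_tolerance must be positive", call. = FALSE)
  structure(list(t_m = t_m, metric = metric,
                 anchor_tolerance = anchor_tolerance),
            class = "match_config")
}

#' Match a measured surface trace against the database
#'
#' Candidates are first filtered by the surface anchor: only database entries
#' whose simulated trace starts within \code{cfg$anchor_tolerance} of the
#' measured \code{trace(0)} are considered. Database traces are then linearly
#' interpolated onto the measured time stamps inside \code{[0, t_m]}
#' (measurement time stamps are treated as ground truth) and the RMS deviation
#' is computed; the smallest residual wins. Exact residual ties are broken by
#' the smaller peak depth, then by database order. No interpolation between
#' entries is performed: the estimate is a stored member, and grid density —
#' not interpolation — controls resolution.
#'
#' @param measured a [surface_trace()] covering \code{[0, t_m]}.
#' @param db a \code{profile_db} from [build_database()].
#' @param cfg a [match_config()].
#' @return an object of class \code{match_result}: \code{best_params},
#'   \code{estimated_profile} (a database member, \code{role_tag} =
#'   "estimated"), \code{residual} (degC), \code{t_m_used},
#'   \code{n_candidates} (after anchor filtering), \code{runner_up_gap} and
#'   \code{index} (database entry number).
#' @export
match_trace <- function(measured, db, cfg = match_config()) {
  stopifnot(inherits(measured, "surface_trace"), inherits(db, "profile_db"),
            inherits(cfg, "match_config"))
  t_end <- max(measured$t)
  if (cfg$t_m > t_end + 1e-9)
    stop(sprintf("matching window t_m = %g s exceeds the measured duration %g s",
                 cfg$t_m, t_end), call. = FALSE)
  cand <- which(abs(db$traces[1L, ] - measured$T[1L]) <= cfg$anchor_tolerance)
  if (length(cand) == 0L)
    stop("no database candidate matches the measured initial surface ",
         "temperature within the anchor tolerance; widen the anchor bracket",
         call. = FALSE)
  sel <- measured$t <= cfg$t_m + 1e-9
  tt <- measured$t[sel]
  ym <- measured$T[sel]
  # shared linear-interpolation weights: db time grid -> measured stamps
  i0 <- pmin(pmax(findInterval(tt, db$t), 1L), length(db$t) - 1L)
  w <- (tt - db$t[i0]) / (db$t[i0 + 1L] - db$t[i0])
  w <- pmin(pmax(w, 0), 1)
  Tc <- db$traces[, cand, drop = FALSE]
  interp <- Tc[i0, , drop = FALSE] * (1 - w) + Tc[i0 + 1L, , drop = FALSE] * w
  resid <- sqrt(colMeans((interp - ym)^2))
  ord <- order(resid, db$peaks$z_max[cand], seq_along(cand))
  best <- cand[ord[1L]]
  runner_up_gap <- if (length(ord) > 1L) resid[ord[2L]] - resid[ord[1L]] else NA_real_
  est <- depth_profile(db$z, db$profiles[, best], role = "estimated")
  structure(list(best_params = db_entry_params(db, best),
                 estimated_profile = est,
                 residual = resid[ord[1L]],
                 t_m_used = cfg$t_m,
                 n_candidates = length(cand),
                 runner_up_gap = runner_up_gap,
                 index = best),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  pm <- peak_metrics(x$estimated_profile)
  cat(sprintf("match_result: entry %d of %d candidates, RMSE %.4g degC over [0, %g] s\n",
              x$index, x$n_candidates, x$residual, x$t_m_used))
  cat(sprintf("  estimated peak %.2f degC at %.2f mm (runner-up gap %.3g degC)\n",
              pm$T_max, pm$z_max, x$runner_up_gap))
  invisible(x)
}

#' Peak-error estimators between an estimated and a reference profile
#'
#' Applies [peak_metrics()] (with sub-grid refinement) to both profiles and
#' returns the signed differences, estimated minus reference: the
#' peak-temperature error dT_max (degC) and the peak-depth error dz_max (mm).
#'
#' @param estimated,reference [depth_profile()] objects; grids may differ.
#' @return list with \code{dT_max}, \code{dz_max}, and the two peak-metric
#'   pairs (\code{estimated}, \code{reference}).
#' @export
evaluate_estimate <- function(estimated, reference) {
  pe <- peak_metrics(estimated, refine = TRUE)
  pr <- peak_metrics(reference, refine = TRUE)
  list(dT_max = pe$T_max - pr$T_max,
       dz_max = pe$z_max - pr$z_max,
       estimated = pe, reference = pr)
}

#' Sweep the matching window
#'
#' Repeats [match_trace()] for each window length and evaluates the peak
#' errors against a reference profile, reproducing the window-convergence
#' analysis (estimation accuracy improves as the matching window grows).
#'
#' @param measured a [surface_trace()].
#' @param reference the reference [depth_profile()] (e.g. the synthetic
#'   truth, or a measured cross-section profile).
#' @param db a \code{profile_db}.
#' @param windows vector of window lengths t_m, s.
#' @param cfg a [match_config()]; its \code{t_m} is overridden per window.
#' @param out optional CSV path for the report.
#' @return data frame with one row per window: \code{t_m}, \code{dT_max},
#'   \code{dz_max}, \code{residual}, \code{T_max_est}, \code{z_max_est},
#'   \code{index}.
#' @export
tm_sweep <- function(measured, reference, db, windows,
                     cfg = match_config(), out = NULL) {
  stopifnot(length(windows) >= 1L)
  rows <- lapply(windows, function(w) {
    cfg$t_m <- w
    m <- match_trace(measured, db, cfg)
    ev <- evaluate_estimate(m$estimated_profile, reference)
    data.frame(t_m = w, dT_max = ev$dT_max, dz_max = ev$dz_max,
               residual = m$residual,
               T_max_est = ev$estimated$T_max, z_max_est = ev$estimated$z_max,
               index = m$index)
  })
  res <- do.call(rbind, rows)
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}
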