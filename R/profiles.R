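#' Parameters of the candidate depth-temperature-profile family
#'
#' The candidate family used to span plausible depth temperature profiles is
#'
#' \deqn{T(z) = (T_{surf} - 1) + (z + 1)^{B / (C (z + 1) + A)} - D (z + 1)}
#'
#' with depth \eqn{z} in millimetres. \code{A}, \code{B} and \code{C} are
#' dimensionless shape parameters: the power term rises from 1 at the surface,
#' peaks below it, and relaxes back towards 1 at depth, so \code{B} mainly
#' controls the peak amplitude while the ratio \code{A/C} controls the peak
#' depth. \code{D} (degC/mm) is a linear correction for the bulk temperature
#' deeper in the tissue; \code{T_surf_anchor} (degC) anchors the surface value,
#' \code{T(0) = T_surf_anchor - D}.
#'
#' @param A,B,C dimensionless shape parameters. The exponent denominator
#'   \code{C*(z+1) + A} must not vanish anywhere on the evaluation range.
#' @param D bulk-correction slope, degC/mm; must be non-negative.
#' @param T_surf_anchor surface anchor temperature, degC.
#' @return an object of class \code{profile_params}.
#' @seealso [generate_profile()], [parameter_grid()], [design_grid()]
#' @export
profile_params <- function(A, B, C, D, T_surf_anchor) {
  for (v in list(A, B, C, D, T_surf_anchor))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("profile parameters must be single finite numbers", call. = FALSE)
  if (D < 0)
    stop("D must be >= 0 (non-increasing deep-temperature correction)",
         call. = FALSE)
  structure(list(A = A, B = B, C = C, D = D, T_surf_anchor = T_surf_anchor),
            class = "profile_params")
}

#' @export
print.profile_params <- function(x, ...) {
  cat(sprintf(
    "profile_params: A=%.4g B=%.4g C=%.4g D=%.4g degC/mm, anchor=%.4g degC\n",
    x$A, x$B, x$C, x$D, x$T_surf_anchor))
  invisible(x)
}

#' Temperature-versus-depth container
#'
#' @param z depth grid in mm, strictly increasing, starting at 0 (the
#'   air-tissue surface, z positive downward).
#' @param T temperature at each depth, degC, all finite.
#' @param role one of \code{"candidate"}, \code{"reference"},
#'   \code{"estimated"}.
#' @return an object of class \code{depth_profile}.
#' @export
depth_profile <- function(z, T, role = c("candidate", "reference", "estimated")) {
  role <- match.arg(role)
  z <- as.numeric(z); T <- as.numeric(T)
  if (length(z) != length(T) || length(z) < 3L)
    stop("z and T must have equal length >= 3", call. = FALSE)
  if (any(!is.finite(z)) || any(diff(z) <= 0))
    stop("depth grid must be finite and strictly increasing", call. = FALSE)
  if (abs(z[1L]) > 1e-12)
    stop("depth grid must start at z = 0 (tissue surface)", call. = FALSE)
  if (any(!is.finite(T)))
    stop("profile temperatures must all be finite", call. = FALSE)
  structure(list(z = z, T = T, role_tag = role), class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  pk <- peak_metrics(x)
  cat(sprintf(
    "depth_profile [%s]: %d nodes over 0-%.4g mm, peak %.2f degC at %.2f mm\n",
    x$role_tag, length(x$z), max(x$z), pk$T_max, pk$z_max))
  invisible(x)
}

# Check whether the exponent denominator C*(z+1)+A has a root inside the
# z-range; the denominator is linear in z so a sign test suffices.
denominator_singular <- function(A, C, z_range) {
  d0 <- C * (z_range[1L] + 1) + A
  d1 <- C * (z_range[2L] + 1) + A
  d0 == 0 || d1 == 0 || sign(d0) != sign(d1)
}

# Raw evaluation of the profile family without finiteness guards (used by the
# designers, where transient overflow during root bracketing is acceptable).
eval_family <- function(params, z) {
  u <- z + 1
  (params$T_surf_anchor - 1) + u^(params$B / (params$C * u + params$A)) -
    params$D * u
}

#' Default depth grid for profile evaluation
#'
#' 0 to 34 mm (sample thickness) at 0.1 mm.
#' @param depth maximum depth, mm.
#' @param dz grid step, mm.
#' @export
default_z_grid <- function(depth = 34, dz = 0.1) seq(0, depth, by = dz)

#' Evaluate a candidate depth temperature profile
#'
#' Pointwise, deterministic evaluation of the candidate family (see
#' [profile_params()]) on a depth grid.
#'
#' @param params a [profile_params()] object.
#' @param z_grid depth grid in mm (strictly increasing, starting at 0).
#' @return a [depth_profile()] with \code{role_tag = "candidate"}.
#' @export
generate_profile <- function(params, z_grid = default_z_grid()) {
  stopifnot(inherits(params, "profile_params"))
  z_grid <- as.numeric(z_grid)
  if (denominator_singular(params$A, params$C, range(z_grid)))
    stop("exponent denominator C*(z+1)+A vanishes inside the depth range",
         call. = FALSE)
  T <- eval_family(params, z_grid)
  if (any(!is.finite(T)))
    stop("profile evaluation produced non-finite temperatures", call. = FALSE)
  out <- depth_profile(z_grid, T, role = "candidate")
  out$params <- params
  out
}

#' Peak temperature and peak depth of a profile
#'
#' Grid argmax with ties broken toward the smallest depth. With
#' \code{refine = TRUE} and an interior argmax, a 3-point quadratic
#' (parabolic) interpolation through the argmax and its neighbours gives
#' sub-grid estimates of both the peak depth and the peak temperature; the
#' refined depth is clamped to the bracketing interval.
#'
#' @param profile a [depth_profile()].
#' @param refine logical; apply parabolic sub-grid refinement.
#' @return list with \code{T_max} (degC) and \code{z_max} (mm).
#' @export
peak_metrics <- function(profile, refine = TRUE) {
  stopifnot(inherits(profile, "depth_profile"))
  T <- profile$T; z <- profile$z
  j <- which.max(T)  # first maximum == smallest-depth tie rule
  T_max <- T[j]; z_max <- z[j]
  if (isTRUE(refine) && j > 1L && j < length(T)) {
    z3 <- z[(j - 1L):(j + 1L)]; T3 <- T[(j - 1L):(j + 1L)]
    # parabola through three (possibly unevenly spaced) points
    d21 <- (T3[2L] - T3[1L]) / (z3[2L] - z3[1L])
    d32 <- (T3[3L] - T3[2L]) / (z3[3L] - z3[2L])
    curv <- (d32 - d21) / (z3[3L] - z3[1L])
    if (curv < 0) {
      zv <- (z3[1L] + z3[2L]) / 2 - d21 / (2 * curv)
      zv <- min(max(zv, z3[1L]), z3[3L])
      Tv <- T3[1L] + d21 * (zv - z3[1L]) + curv * (zv - z3[1L]) * (zv - z3[2L])
      if (Tv >= T_max) { z_max <- zv; T_max <- Tv }
    }
  }
  list(T_max = T_max, z_max = z_max)
}

#' Cartesian grid of candidate profile parameters
#'
#' Linearly spaced values per parameter, combined as a full Cartesian product
#' in deterministic lexicographic order (A slowest, then B, C, D, anchor).
#' Combinations whose exponent denominator vanishes inside \code{z_range}, or
#' with \code{D < 0}, are dropped; the number dropped is reported via
#' \code{message()} and attached as attribute \code{n_dropped}.
#'
#' @param ranges named list with components \code{A}, \code{B}, \code{C},
#'   \code{D}, each a numeric \code{c(min, max, count)} (count >= 1,
#'   min <= max).
#' @param anchor_values vector of surface anchor temperatures, degC.
#' @param z_range depth range (mm) on which candidates must be valid.
#' @return list of [profile_params()] objects.
#' @export
parameter_grid <- function(ranges, anchor_values, z_range = c(0, 34)) {
  need <- c("A", "B", "C", "D")
  if (!all(need %in% names(ranges)))
    stop("ranges must contain components A, B, C, D", call. = FALSE)
  vals <- lapply(need, function(nm) {
    r <- as.numeric(ranges[[nm]])
    if (length(r) != 3L || r[3L] < 1 || r[1L] > r[2L])
      stop(sprintf("range for %s must be c(min, max, count) with count >= 1, min <= max", nm),
           call. = FALSE)
    if (r[3L] == 1) (r[1L] + r[2L]) / 2 else seq(r[1L], r[2L], length.out = r[3L])
  })
  names(vals) <- need
  if (length(anchor_values) < 1L)
    stop("at least one anchor value is required", call. = FALSE)
  grid <- expand.grid(anchor = anchor_values, D = vals$D, C = vals$C,
                      B = vals$B, A = vals$A, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("A", "B", "C", "D", "anchor")]
  if (nrow(grid) == 0L) stop("empty parameter grid", call. = FALSE)
  keep <- !mapply(denominator_singular, grid$A, grid$C,
                  MoreArgs = list(z_range = z_range)) & grid$D >= 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message(sprintf("parameter_grid: dropped %d of %d combinations violating the exponent-denominator invariant",
                    n_dropped, nrow(grid)))
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0L)
    stop("all parameter combinations were invalid on the depth range",
         call. = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i)
    profile_params(grid$A[i], grid$B[i], grid$C[i], grid$D[i], grid$anchor[i]))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Solve profile parameters for a target peak depth and amplitude
#'
#' Inverse design of the candidate family: given the shape parameter \code{C},
#' the bulk slope \code{D} and the surface anchor, find \code{A} and \code{B}
#' such that the profile peaks at depth \code{z_max} (mm) with amplitude
#' \code{amplitude} = peak temperature minus the deep value at the bottom of
#' the grid (degC).
#'
#' The power term of the family peaks where \eqn{u (\ln u - 1) = A/C}
#' (\eqn{u = z + 1}), independently of \code{B}, and the amplitude is strictly
#' increasing in \code{B}, so the two one-dimensional root problems are weakly
#' coupled and alternating \code{uniroot} passes converge in a few sweeps.
#'
#' @param z_max target peak depth, mm (> 0).
#' @param amplitude target peak-minus-deep amplitude, degC (> 0).
#' @param C,D,T_surf_anchor remaining family parameters.
#' @param z_range depth range (mm) over which the profile is evaluated.
#' @param tol convergence tolerance on the achieved depth (mm) and
#'   amplitude (degC).
#' @return a [profile_params()] object, or \code{NULL} when no solution exists
#'   within the search bounds (e.g. a deep peak with too strong a bulk slope).
#' @export
solve_profile_params <- function(z_max, amplitude, C, D, T_surf_anchor,
                                 z_range = c(0, 34), tol = 0.02) {
  stopifnot(z_max > 0, amplitude > 0, C > 0, D >= 0)
  h <- 0.05
  zg <- seq(z_range[1L], z_range[2L], by = h)
  nz <- length(zg)
  measure <- function(A, B) {
    T <- eval_family(list(A = A, B = B, C = C, D = D,
                          T_surf_anchor = T_surf_anchor), zg)
    j <- which.max(T)
    zpk <- zg[j]; Tpk <- T[j]
    if (j > 1L && j < nz && all(is.finite(T[c(j - 1L, j + 1L)]))) {
      den <- T[j - 1L] - 2 * T[j] + T[j + 1L]
      if (den < 0) {  # parabolic sub-grid peak
        off <- 0.5 * (T[j - 1L] - T[j + 1L]) / den
        zpk <- zg[j] + off * h
        Tpk <- T[j] - 0.25 * (T[j - 1L] - T[j + 1L]) * off
      }
    }
    c(zmax = zpk, amp = Tpk - T[nz])
  }
  # initial A from the B-free peak condition u(ln u - 1) = A/C
  u <- z_max + 1
  A <- C * u * (log(u) - 1)
  A_lo <- -C + 1e-8  # keeps C*(z+1)+A > 0 for all z >= 0
  A <- max(A, A_lo + 1e-6)
  B <- 1
  ok <- FALSE
  res <- tryCatch({
    for (sweep in 1:8) {
      # amplitude is monotone increasing in B
      fB <- function(b) measure(A, b)["amp"] - amplitude
      B <- uniroot(fB, lower = 1e-8, upper = 5, extendInt = "upX",
                   tol = 1e-10)$root
      # The achieved peak depth increases with A while the bump term
      # dominates, but collapses to the surface once the bump flattens below
      # the bulk slope D; bracket locally from the current A rather than over
      # a global range.
      fA <- function(a) measure(a, B)["zmax"] - z_max
      f_cur <- fA(A)
      if (abs(f_cur) > 1e-12) {
        lo <- A; hi <- A; found <- FALSE
        if (f_cur < 0) {  # need deeper: step A upward
          prev_z <- f_cur
          for (stp in 1:40) {
            hi <- hi + 0.25 * (1 + 0.25 * stp)
            fz <- fA(hi)
            if (fz >= 0) { found <- TRUE; break }
            if (fz < prev_z - 1e-9) stop("peak depth out of reach")  # collapsing
            prev_z <- fz; lo <- hi
          }
        } else {          # need shallower: step A downward toward -C
          for (stp in 1:60) {
            lo <- max(A_lo + 1e-9, lo - max(0.25, (lo - A_lo) * 0.5))
            if (fA(lo) <= 0) { found <- TRUE; break }
            hi <- lo
            if (lo <= A_lo + 1e-8) break
          }
        }
        if (!found) stop("peak depth out of reach")
        A <- uniroot(fA, lower = lo, upper = hi, tol = 1e-10)$root
      }
      m <- measure(A, B)
      if (abs(m["zmax"] - z_max) < tol && abs(m["amp"] - amplitude) < tol) {
        ok <- TRUE
        break
      }
    }
    ok
  }, error = function(e) FALSE)
  if (!isTRUE(res)) return(NULL)
  profile_params(A, B, C, D, T_surf_anchor)
}

#' Designed parameter grid with uniform peak-space coverage
#'
#' Builds a list of candidate parameters whose profiles tile the
#' (peak depth, amplitude) plane on a regular ladder, by inverse design with
#' [solve_profile_params()]. A raw Cartesian grid in (A, B, C, D) covers that
#' plane extremely unevenly (the amplitude grows exponentially in B over the
#' plausible C range), whereas matching resolution is set by the spacing of
#' peak depths and amplitudes actually represented in the database; the
#' designed ladder makes that spacing explicit and uniform.
#'
#' Surface-peaked candidates (a monotone decreasing profile, \code{B = 0})
#' are appended for a ladder of bulk slopes so the family also covers
#' \code{z_max = 0}.
#'
#' @param z_targets ladder of peak depths, mm (values > 0); crossed with
#'   \code{amp_targets} unless \code{targets} is given.
#' @param amp_targets ladder of peak amplitudes, degC.
#' @param C,D shared shape/bulk parameters of the designed entries.
#' @param anchors vector of surface anchor temperatures, degC.
#' @param surface_peak_D ladder of bulk slopes for the appended monotone
#'   (surface-peak) candidates; use \code{numeric(0)} to omit them.
#' @param z_range depth range, mm.
#' @param targets optional data frame with columns \code{z} and \code{amp}:
#'   explicit (depth, amplitude) target pairs replacing the crossed ladders,
#'   used to mix ladder resolutions as in [default_grid_spec()].
#' @return list of [profile_params()]; attribute \code{n_dropped} counts
#'   unreachable (depth, amplitude) targets.
#' @export
design_grid <- function(z_targets = NULL, amp_targets = NULL, C = 0.55,
                        D = 0.04, anchors,
                        surface_peak_D = seq(0.1, 0.6, by = 0.1),
                        z_range = c(0, 34), targets = NULL) {
  if (is.null(targets)) {
    stopifnot(all(z_targets > 0), all(amp_targets > 0))
    targets <- expand.grid(amp = amp_targets, z = z_targets)[, c("z", "amp")]
  }
  stopifnot(all(targets$z > 0), all(targets$amp > 0), length(anchors) >= 1L)
  shapes <- list()
  n_dropped <- 0L
  for (i in seq_len(nrow(targets))) {
    p <- solve_profile_params(targets$z[i], targets$amp[i], C = C, D = D,
                              T_surf_anchor = 0, z_range = z_range)
    if (is.null(p)) n_dropped <- n_dropped + 1L else
      shapes[[length(shapes) + 1L]] <- p
  }
  if (n_dropped > 0L)
    message(sprintf("design_grid: %d unreachable (depth, amplitude) targets dropped",
                    n_dropped))
  out <- list()
  for (s in shapes)
    for (an in anchors)
      out[[length(out) + 1L]] <- profile_params(s$A, s$B, s$C, s$D, an)
  for (d in surface_peak_D)
    for (an in anchors)
      out[[length(out) + 1L]] <- profile_params(1, 0, C, d, an)
  if (length(out) == 0L) stop("designed grid is empty", call. = FALSE)
  attr(out, "n_dropped") <- n_dropped
  out
}
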