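# Kinematic ramp-release model of mechanical delamination: a row of anchor
# points on the polymer underside is released one after another as the
# corrosion front arrives; the detached gap length is the line integral over
# already-released interface segments.  The model is purely kinematic —
# elastic constants play no role in the timing.

#' Geometry of the anchored polymer-on-substrate specimen
#'
#' A polymer strip bonded to a longer metal substrate, attached at `n_points`
#' anchor points along the interface, counted from the exposed (solution
#' side) edge inward.  By default the points are spaced equally over the
#' polymer footprint.
#'
#' @param polymer_length_mm,polymer_thickness_mm polymer strip, mm.
#' @param substrate_length_mm,substrate_thickness_mm metal substrate, mm.
#' @param n_points number of anchor points (>= 2).
#' @param spacing_mm point spacing, mm; `NULL` = equal spacing over the
#'   polymer footprint.  The points must fit within the footprint.
#' @return An object of class `"detachment_geometry"` with the point
#'   positions `x_mm` (first point at the exposed edge, x = 0).
#' @examples
#' detachment_geometry()  # the 14 mm strip with 23 anchor points
#' @export
detachment_geometry <- function(polymer_length_mm = 14,
                                polymer_thickness_mm = 1,
                                substrate_length_mm = 30,
                                substrate_thickness_mm = 0.2,
                                n_points = 23, spacing_mm = NULL) {
  check_scalar(polymer_length_mm, "polymer_length_mm")
  check_scalar(polymer_thickness_mm, "polymer_thickness_mm")
  check_scalar(substrate_length_mm, "substrate_length_mm")
  check_scalar(substrate_thickness_mm, "substrate_thickness_mm")
  if (!is.numeric(n_points) || n_points < 2) {
    stop_bad("`n_points` must be at least 2", "delamsim_bad_parameter")
  }
  n_points <- as.integer(n_points)
  if (is.null(spacing_mm)) spacing_mm <- polymer_length_mm / (n_points - 1L)
  check_scalar(spacing_mm, "spacing_mm")
  if ((n_points - 1L) * spacing_mm > polymer_length_mm + 1e-9) {
    stop_bad("anchor points do not fit within the polymer footprint",
             "delamsim_bad_parameter")
  }
  structure(list(polymer_length_mm = polymer_length_mm,
                 polymer_thickness_mm = polymer_thickness_mm,
                 substrate_length_mm = substrate_length_mm,
                 substrate_thickness_mm = substrate_thickness_mm,
                 n_points = n_points, spacing_mm = spacing_mm,
                 x_mm = (seq_len(n_points) - 1L) * spacing_mm),
            class = "detachment_geometry")
}

#' @export
print.detachment_geometry <- function(x, ...) {
  cat(sprintf("Detachment geometry: polymer %g x %g mm on substrate %g x %g mm\n",
              x$polymer_length_mm, x$polymer_thickness_mm,
              x$substrate_length_mm, x$substrate_thickness_mm))
  cat(sprintf("  %d anchor points, spacing %.4g mm, outermost at x = %.4g mm\n",
              x$n_points, x$spacing_mm, max(x$x_mm)))
  invisible(x)
}

#' Saturating ramp function
#'
#' The release function of an anchor point: 0 for nonpositive argument (no
#' detachment before the onset), rising linearly, saturating at unity (fully
#' released).
#'
#' @param s dimensionless argument; vectorized.
#' @return Values in `[0, 1]`.
#' @examples
#' ramp(c(-1, 0.5, 2))  # 0, 0.5, 1
#' @export
ramp <- function(s) {
  stopifnot(is.numeric(s))
  pmin(pmax(s, 0), 1)
}

#' Build the time-shifted release schedule
#'
#' Each anchor point's ramp onset is the arrival time of the corrosion front
#' at its position under the square-root-of-time law: `t_i = (x_i / alpha)^2`.
#' Onsets therefore increase strictly (and quadratically, for equal spacing)
#' from the exposed edge inward, securing the points detaching one after the
#' other.
#'
#' @param geometry a [detachment_geometry()] object.
#' @param alpha front coefficient, mm/min^0.5 (> 0).
#' @param ramp_duration_min time for a point's ramp to rise from 0 to 1, min.
#' @param max_displacement_mm saturated vertical displacement of a released
#'   point, mm (kinematic bookkeeping only).
#' @return An object of class `"ramp_schedule"` with `onset_min`, the point
#'   positions and weights, `ramp_duration_min` and `max_displacement_mm`.
#' @examples
#' sched <- build_schedule(detachment_geometry(), alpha = 0.027)
#' head(sched$onset_min)
#' @export
build_schedule <- function(geometry, alpha, ramp_duration_min = 30,
                           max_displacement_mm = 1) {
  stopifnot(inherits(geometry, "detachment_geometry"))
  check_scalar(alpha, "alpha")
  check_scalar(ramp_duration_min, "ramp_duration_min")
  check_scalar(max_displacement_mm, "max_displacement_mm")
  if (geometry$spacing_mm <= 0) {
    stop_bad("point spacing must be positive", "delamsim_bad_parameter")
  }
  onset <- (geometry$x_mm / alpha)^2
  # line-integral weights: each point carries the interface segment behind it
  # (towards the exposed edge); the edge point carries none.  The weights sum
  # to the anchored span, so the gap is bounded by the footprint and the
  # detached length strictly lags the front arrival law.
  w <- c(0, rep(geometry$spacing_mm, geometry$n_points - 1L))
  structure(list(geometry = geometry, alpha = alpha, onset_min = onset,
                 weight_mm = w, ramp_duration_min = ramp_duration_min,
                 max_displacement_mm = max_displacement_mm),
            class = "ramp_schedule")
}

#' @export
print.ramp_schedule <- function(x, ...) {
  cat(sprintf("Ramp release schedule: %d points, alpha = %g mm/min^0.5, ramp %g min\n",
              x$geometry$n_points, x$alpha, x$ramp_duration_min))
  cat(sprintf("  onsets %.3g .. %.5g min\n", min(x$onset_min), max(x$onset_min)))
  invisible(x)
}

#' Detached gap length at given times
#'
#' The line integral over already-detached interface segments.  Binary
#' counting sums the weight of points whose ramp has saturated (fully
#' released); fractional counting weights each segment by its current ramp
#' value.  Both are nondecreasing in time and bounded by the polymer
#' footprint, and fractional counting always dominates binary.
#'
#' @param schedule a [build_schedule()] object.
#' @param t_min times, min (>= 0); vectorized.
#' @param counting `"binary"` or `"fractional"`.
#' @return Gap lengths, mm.
#' @examples
#' sched <- build_schedule(detachment_geometry(), alpha = 0.027)
#' gap_length(sched, c(0, 500, 5000))
#' @export
gap_length <- function(schedule, t_min, counting = c("binary", "fractional")) {
  stopifnot(inherits(schedule, "ramp_schedule"))
  counting <- match.arg(counting)
  if (!is.numeric(t_min) || any(is.na(t_min)) || any(t_min < 0)) {
    stop_bad("`t_min` must be nonnegative", "delamsim_bad_parameter")
  }
  tau <- schedule$ramp_duration_min
  vapply(t_min, function(t) {
    r <- ramp((t - schedule$onset_min) / tau)
    if (counting == "binary") {
      sum(schedule$weight_mm[r >= 1])
    } else {
      sum(schedule$weight_mm * r)
    }
  }, numeric(1))
}

#' Simulate the mechanical delamination gap trace
#'
#' Evaluates [gap_length()] on a time grid and returns the result as a
#' [gap_trace()].
#'
#' @inheritParams gap_length
#' @param t_end_min horizon, min.
#' @param by_min sampling interval, min.
#' @return A `"gap_trace"` data frame (`t_min`, `gap_mm`) with the counting
#'   mode and schedule attached as attributes.
#' @examples
#' sched <- build_schedule(detachment_geometry(), alpha = 0.027)
#' tr <- delamination_trace(sched, t_end_min = 400)
#' tail(tr, 3)
#' @export
delamination_trace <- function(schedule, t_end_min, by_min = 5,
                               counting = c("binary", "fractional")) {
  counting <- match.arg(counting)
  check_scalar(t_end_min, "t_end_min")
  tt <- seq(0, t_end_min, by = by_min)
  tr <- gap_trace(tt, gap_length(schedule, tt, counting))
  attr(tr, "counting") <- counting
  attr(tr, "schedule") <- schedule
  tr
}

#' Vertical displacement of the anchor points
#'
#' Kinematic displacement `max_displacement * ramp` per point; released
#' points approach the saturated displacement.  Has no feedback on the
#' release timing.
#'
#' @inheritParams gap_length
#' @param t_min a single time, min.
#' @return Displacements, mm (one per anchor point).
#' @export
point_displacement <- function(schedule, t_min) {
  stopifnot(inherits(schedule, "ramp_schedule"))
  check_scalar(t_min, "t_min", positive = FALSE)
  schedule$max_displacement_mm *
    ramp((t_min - schedule$onset_min) / schedule$ramp_duration_min)
}
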