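#' Unit conversions for the square-root-of-time front coefficient
#'
#' The front law `X(t) = alpha * sqrt(t)` is conventionally reported with
#' `alpha` in mm per square-root-minute (the units in which detachment traces
#' are read off), while the diffusion solvers work in SI.  These helpers
#' convert between the two.
#'
#' @param alpha front coefficient in mm/min^0.5.
#' @param alpha_si front coefficient in m/s^0.5.
#' @return The coefficient in the other unit system.
#' @examples
#' alpha_to_si(0.027)
#' alpha_from_si(alpha_to_si(0.027))
#' @export
alpha_to_si <- function(alpha) {
  stopifnot(is.numeric(alpha), all(is.finite(alpha)))
  alpha * 1e-3 / sqrt(60)
}

#' @rdname alpha_to_si
#' @export
alpha_from_si <- function(alpha_si) {
  stopifnot(is.numeric(alpha_si), all(is.finite(alpha_si)))
  alpha_si * 1e3 * sqrt(60)
}

# internal shorthands -------------------------------------------------------

min_to_s <- function(t) t * 60
s_to_min <- function(t) t / 60
mm_to_m <- function(x) x * 1e-3
m_to_mm <- function(x) x * 1e3

# trapezoid rule and its running integral; used by the mass-balance checks
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
cumtrapz <- function(x, y) c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))

# error function via the normal CDF
erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
erfc <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)
inv_erfc <- function(p) qnorm(p / 2, lower.tail = FALSE) / sqrt(2)

stop_bad <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "delamsim_error")))
}

check_scalar <- function(x, name, positive = TRUE, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    stop_bad(sprintf("`%s` must be a single finite number", name),
             "delamsim_bad_parameter")
  }
  if (positive && x <= 0) {
    stop_bad(sprintf("`%s` must be > 0 (got %g)", name, x),
             "delamsim_bad_parameter")
  }
  invisible(x)
}
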