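# Corrosion-threshold transport along the thin metal-polymer interlayer.
#
# Solute diffuses along the interlayer from the solution edge (Dirichlet
# c_boundary at x = 0).  An interlayer element is corroded, detached and
# removed once its concentration reaches the limiting value c_limit; removal
# proceeds front-first, so the removed cells always form a contiguous prefix
# from the solution edge, and advances at most one cell per time step.  The
# gap left behind fills with solution, but transport across it remains
# diffusion-limited: removed cells keep carrying the diffusive profile, which
# relaxes towards the boundary concentration.  (Clamping the gap to the
# boundary concentration — instantaneous mixing — would make the front speed
# scale as Di/cell_size, i.e. mesh-dependent and linear in time, and is
# deliberately not assumed; see the package vignette.)  The detachment front
# is then the travelling level set of the threshold concentration, which
# advances as X = 2 beta sqrt(Di t) with beta = inverfc(c_limit/c_boundary).

#' State of the corroding interlayer
#'
#' Cell-centred discretization of the interlayer: positions, concentrations,
#' per-cell removal flags and the index of the first intact cell.  Removed
#' cells must form a contiguous prefix from the solution edge.
#'
#' @param n_cells number of cells (>= 3).
#' @param cell_size cell width, m.
#' @param c initial concentrations, mol/m^3; scalar or length `n_cells`.
#' @param removed logical removal flags; must be a contiguous prefix.
#' @return An object of class `"interlayer_state"` with `x` (cell centres, m),
#'   `c`, `removed`, `front_index` and `cell_size`.
#' @examples
#' interlayer_state(100, 1e-5)
#' @export
interlayer_state <- function(n_cells, cell_size, c = 0,
                             removed = rep(FALSE, n_cells)) {
  if (!is.numeric(n_cells) || n_cells < 3) {
    stop_bad("`n_cells` must be at least 3", "delamsim_bad_parameter")
  }
  n_cells <- as.integer(n_cells)
  check_scalar(cell_size, "cell_size")
  if (length(c) == 1L) c <- rep(c, n_cells)
  stopifnot(length(c) == n_cells, all(is.finite(c)), all(c >= 0))
  stopifnot(is.logical(removed), length(removed) == n_cells)
  n_removed <- sum(removed)
  if (n_removed > 0 && !all(removed[seq_len(n_removed)])) {
    stop_bad("removed cells must form a contiguous prefix from the solution edge",
             "delamsim_corrupt_state")
  }
  structure(list(x = (seq_len(n_cells) - 0.5) * cell_size, c = c,
                 removed = removed, front_index = n_removed + 1L,
                 cell_size = cell_size),
            class = "interlayer_state")
}

#' @export
print.interlayer_state <- function(x, ...) {
  cat(sprintf("Interlayer state: %d cells of %.3g mm, %d removed (front at %.4g mm)\n",
              length(x$c), m_to_mm(x$cell_size), x$front_index - 1L,
              m_to_mm((x$front_index - 1L) * x$cell_size)))
  invisible(x)
}

# one Crank-Nicolson step of the interlayer field; returns the new
# concentration vector.  Left face Dirichlet c_boundary, right face no-flux.
interlayer_cn_step <- function(cc, D, c_b, dx, dt, theta = 0.5) {
  n <- length(cc)
  r <- D * dt / dx^2
  tr <- theta * r
  er <- (1 - theta) * r
  lower <- rep(-tr, n)
  diagv <- rep(1 + 2 * tr, n)
  upper <- rep(-tr, n)
  # cell 1: flux through the left face uses the half-cell distance
  diagv[1] <- 1 + 3 * tr
  rhs1 <- cc[1] + er * (2 * c_b - 3 * cc[1] + cc[2]) + 2 * tr * c_b
  # cell n: no-flux right face
  diagv[n] <- 1 + tr
  idx <- 2:(n - 1L)
  rhs <- c(rhs1,
           cc[idx] + er * (cc[idx + 1L] - 2 * cc[idx] + cc[idx - 1L]),
           cc[n] + er * (cc[n - 1L] - cc[n]))
  thomas_solve(lower, diagv, upper, rhs)
}

#' Advance the corroding interlayer by one time step
#'
#' One diffusion step (Crank-Nicolson, unconditionally stable) followed by
#' the removal rule: if the first intact cell has reached the limiting
#' concentration it is flagged removed and the front advances — at most one
#' cell per step, front-first, so the removed prefix stays contiguous.
#'
#' @param state an [interlayer_state()] object.
#' @param params a [transport_params()] object.
#' @param dt time step, s.
#' @return The updated `"interlayer_state"`.
#' @examples
#' p <- kps_sylgard_params()
#' tp <- transport_params(p$Di, p$c0, alpha = p$alpha, cell_size = 1e-5)
#' st <- interlayer_state(50, tp$cell_size)
#' interlayer_step(st, tp, dt = 10)
#' @export
interlayer_step <- function(state, params, dt) {
  stopifnot(inherits(state, "interlayer_state"),
            inherits(params, "transport_params"))
  check_scalar(dt, "dt")
  n_removed <- sum(state$removed)
  if (n_removed + 1L != state$front_index ||
      (n_removed > 0 && !all(state$removed[seq_len(n_removed)]))) {
    stop_bad("corrupt state: removed cells are not a contiguous prefix",
             "delamsim_corrupt_state")
  }
  cc <- interlayer_cn_step(state$c, params$Di, params$c_boundary,
                           state$cell_size, dt)
  fi <- state$front_index
  removed <- state$removed
  if (fi <= length(cc) && cc[fi] >= params$c_limit) {
    removed[fi] <- TRUE
    fi <- fi + 1L
  }
  structure(list(x = state$x, c = cc, removed = removed, front_index = fi,
                 cell_size = state$cell_size),
            class = "interlayer_state")
}

#' Run the interlayer corrosion simulation
#'
#' Integrates the interlayer transport-and-removal scheme over a horizon and
#' returns the detachment front (removed-prefix length) as a function of
#' time.  Time steps are quadratically graded so the early, fast part of the
#' front is resolved; the front can advance at most one cell per step, which
#' the grading keeps non-binding after the first few cells.
#'
#' @param params a [transport_params()] object.
#' @param length interlayer length, m.
#' @param t_end horizon, s.
#' @param n_steps number of time steps.
#' @param out_every store a trace point every this many steps (the final
#'   state is always stored).
#' @return An object of class `"interlayer_solution"`: list with `trace` (a
#'   [front_trace()], min/mm), `state` (final [interlayer_state()]) and
#'   `params`.  Warns if the front never advanced a single cell.
#' @examples
#' p <- kps_sylgard_params()
#' tp <- transport_params(p$Di, p$c0, alpha = p$alpha, cell_size = 2e-5)
#' sol <- run_interlayer(tp, length = 4e-3, t_end = 1800, n_steps = 200)
#' tail(sol$trace, 2)
#' @export
run_interlayer <- function(params, length, t_end, n_steps = 1000,
                           out_every = 5L) {
  stopifnot(inherits(params, "transport_params"))
  check_scalar(length, "length")
  check_scalar(t_end, "t_end")
  n_steps <- as.integer(n_steps)
  n <- as.integer(round(length / params$cell_size))
  if (n < 3) {
    stop_bad("fewer than 3 cells: cell_size too coarse for this length",
             "delamsim_resolution")
  }
  dx <- params$cell_size
  D <- params$Di
  c_b <- params$c_boundary
  c_lim <- params$c_limit
  times <- t_end * seq(0, 1, length.out = n_steps + 1)^2

  cc <- numeric(n)
  fi <- 1L
  t_out <- 0
  x_out <- 0
  for (k in seq_len(n_steps)) {
    dt <- times[k + 1L] - times[k]
    theta <- if (k <= 4L) 1 else 0.5
    cc <- interlayer_cn_step(cc, D, c_b, dx, dt, theta)
    if (fi <= n && cc[fi] >= c_lim) fi <- fi + 1L   # at most one cell per step
    if (k %% out_every == 0L || k == n_steps) {
      t_out <- c(t_out, times[k + 1L])
      x_out <- c(x_out, (fi - 1L) * dx)
    }
  }
  if (fi == 1L) {
    warning(paste("interlayer front did not advance a single cell over the",
                  "horizon; refine cell_size or extend t_end"),
            call. = FALSE)
  }
  removed <- seq_len(n) < fi
  state <- structure(list(x = (seq_len(n) - 0.5) * dx, c = cc,
                          removed = removed, front_index = fi,
                          cell_size = dx),
                     class = "interlayer_state")
  trace <- front_trace(s_to_min(t_out), m_to_mm(x_out))
  structure(list(trace = trace, state = state, params = params,
                 length = length, t_end = t_end),
            class = "interlayer_solution")
}

#' @export
print.interlayer_solution <- function(x, ...) {
  n <- nrow(x$trace)
  cat(sprintf("Interlayer corrosion run: X(%.4g min) = %.4g mm (%d cells removed)\n",
              x$trace$t_min[n], x$trace$X_mm[n], x$state$front_index - 1L))
  invisible(x)
}

#' @export
plot.interlayer_solution <- function(x, ...) {
  plot(x$trace, ...)
  invisible(x)
}

#' Calibrate the removal threshold from the empirical front law
#'
#' The corrosion front is the travelling level set of the limiting
#' concentration in the diffusion field fed by the solution edge, which
#' advances as `X = 2 beta sqrt(Di t)` with
#' `beta = inverfc(c_limit / c_boundary)`.  Matching the measured coefficient
#' `alpha` fixes `beta = alpha_SI / (2 sqrt(Di))` and hence
#' `c_limit = c_boundary * erfc(beta)`.
#'
#' @param alpha front coefficient, mm/min^0.5.
#' @param Di interlayer diffusion coefficient, m^2/s.
#' @param c_boundary solution concentration, mol/m^3.
#' @return The limiting concentration, mol/m^3 (always below `c_boundary`).
#' @examples
#' p <- kps_sylgard_params()
#' calibrate_removal_threshold(p$alpha, p$Di, p$c0)
#' @export
calibrate_removal_threshold <- function(alpha, Di, c_boundary) {
  check_scalar(alpha, "alpha")
  check_scalar(Di, "Di")
  check_scalar(c_boundary, "c_boundary")
  beta <- alpha_to_si(alpha) / (2 * sqrt(Di))
  c_boundary * erfc(beta)
}

#' Equivalent Stefan loading of a removal threshold
#'
#' Maps the threshold ratio of the corrosion model onto the loading `c0/S`
#' of the immobilization Stefan problem that produces the same front
#' coefficient: the level-set similarity coefficient
#' `beta = inverfc(c_limit / c_boundary)` is pushed through the exact
#' transcendental relation.  Useful for cross-checking the interlayer scheme
#' against [stefan_beta()].
#'
#' @param params a [transport_params()] object.
#' @return The equivalent dimensionless loading `c0 / S`.
#' @export
equivalent_loading <- function(params) {
  stopifnot(inherits(params, "transport_params"))
  beta <- inv_erfc(params$c_limit / params$c_boundary)
  sqrt(pi) * beta * exp(beta^2) * erf(beta)
}
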