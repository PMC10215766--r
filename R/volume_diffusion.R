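# Crank-Nicolson solver for 1-D Fickian diffusion through a finite slab:
# Dirichlet (infinite source) at x = 0, no-flux at x = L.  The time grid is
# quadratically stretched so the step is dense near t = 0, where the Dirichlet
# jump makes the surface flux singular; the first few steps use backward Euler
# to damp Crank-Nicolson ringing on the discontinuous start.

thomas_solve <- function(lower, diagv, upper, rhs) {
  n <- length(diagv)
  cp <- numeric(n)
  dp <- numeric(n)
  cp[1] <- upper[1] / diagv[1]
  dp[1] <- rhs[1] / diagv[1]
  for (i in 2:n) {
    denom <- diagv[i] - lower[i] * cp[i - 1]
    cp[i] <- upper[i] / denom
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / denom
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Solve volume diffusion through a silicone slab
#'
#' Integrates Fick's second law `dc/dt = D d2c/dx2` on `0 <= x <= L` with a
#' constant-concentration (infinite-source) boundary `c(0, t) = c0`, a no-flux
#' wall at `x = L` (the metal is treated as an inert indicator, not a sink),
#' and initial condition `c(x, 0) = c_init` (0 by default).  Discretization is
#' second-order central differences on a uniform grid with a Crank-Nicolson
#' theta scheme; the time grid is stretched quadratically towards `t = 0`.
#'
#' @param params a [diffusion_params()] object.
#' @param t_end simulation horizon, s.
#' @param n_grid number of spatial nodes (>= 3); the default 201 resolves all
#'   documented tolerances with room to spare.
#' @param n_steps number of time steps.
#' @param c_init initial concentration, mol/m^3; a scalar or a vector of
#'   length `n_grid`.
#' @param n_startup number of initial backward-Euler steps.
#' @return An object of class `"slab_solution"`: list with `x` (m), `times`
#'   (s), matrix `C` (`length(times)` x `n_grid`, mol/m^3), the surface influx
#'   `flux0` (mol/m^2/s, positive into the slab) and `params`.
#' @seealso [breakthrough_time()], [mass_balance()]
#' @examples
#' p <- kps_sylgard_params()
#' par <- diffusion_params(p$D_volume, p$c0, p$c_threshold, L = 2e-3)
#' sol <- solve_slab(par, t_end = 3600, n_grid = 101, n_steps = 200)
#' range(sol$C)
#' @export
solve_slab <- function(params, t_end, n_grid = 201, n_steps = 800,
                       c_init = 0, n_startup = 8) {
  stopifnot(inherits(params, "diffusion_params"))
  check_scalar(t_end, "t_end")
  if (!is.numeric(n_grid) || n_grid < 3) {
    stop_bad("`n_grid` must be at least 3", "delamsim_bad_parameter")
  }
  n_grid <- as.integer(n_grid)
  n_steps <- as.integer(n_steps)
  D <- params$D
  c0 <- params$c0
  L <- params$L

  x <- seq(0, L, length.out = n_grid)
  dx <- x[2] - x[1]
  times <- t_end * seq(0, 1, length.out = n_steps + 1)^2

  if (length(c_init) == 1L) c_init <- rep(c_init, n_grid)
  stopifnot(length(c_init) == n_grid, all(is.finite(c_init)))

  C <- matrix(NA_real_, n_steps + 1L, n_grid)
  C[1L, ] <- c_init
  cc <- c_init
  cc[1] <- c0                       # boundary value holds for all t > 0
  m <- n_grid - 1L                  # unknowns: nodes 2..n_grid

  for (k in seq_len(n_steps)) {
    dt <- times[k + 1L] - times[k]
    theta <- if (k <= n_startup) 1 else 0.5
    r <- D * dt / dx^2
    tr <- theta * r
    er <- (1 - theta) * r

    lower <- rep(-tr, m)
    diagv <- rep(1 + 2 * tr, m)
    upper <- rep(-tr, m)
    # explicit part (interior rows, nodes 2..n_grid-1)
    idx <- 2:(n_grid - 1L)
    rhs <- cc[idx] + er * (cc[idx + 1L] - 2 * cc[idx] + cc[idx - 1L])
    rhs[1] <- rhs[1] + tr * c0      # Dirichlet neighbour
    # last row: mirrored ghost node enforces zero flux at x = L
    lower[m] <- -2 * tr
    rhs_last <- cc[n_grid] + 2 * er * (cc[n_grid - 1L] - cc[n_grid])
    rhs <- c(rhs, rhs_last)

    cc[2:n_grid] <- thomas_solve(lower, diagv, upper, rhs)
    C[k + 1L, ] <- cc
  }

  # surface influx J = -D dc/dx(0), one-sided second-order gradient;
  # positive into the slab
  flux0 <- -D * (-3 * C[, 1] + 4 * C[, 2] - C[, 3]) / (2 * dx)

  structure(list(x = x, times = times, C = C, flux0 = flux0, params = params),
            class = "slab_solution")
}

#' @export
print.slab_solution <- function(x, ...) {
  cat(sprintf("Slab diffusion solution: %d nodes, %d times, t_end = %.4g s\n",
              length(x$x), length(x$times), max(x$times)))
  cat(sprintf("  wall concentration at t_end: %.4g mol/m^3 (threshold %.4g)\n",
              x$C[nrow(x$C), ncol(x$C)], x$params$c_threshold))
  invisible(x)
}

#' @export
plot.slab_solution <- function(x, times = NULL, ...) {
  if (is.null(times)) {
    times <- x$times[unique(pmax(1, round(seq(1, length(x$times), length.out = 6))))]
  }
  rows <- vapply(times, function(t) which.min(abs(x$times - t)), integer(1))
  plot(m_to_mm(x$x), x$C[rows[1], ], type = "l", ylim = c(0, x$params$c0),
       xlab = "depth [mm]", ylab = "concentration [mol/m^3]", ...)
  if (length(rows) > 1) matlines(m_to_mm(x$x), t(x$C[rows[-1], , drop = FALSE]),
                                 lty = 1, col = seq_along(rows)[-1])
  invisible(x)
}

#' Discrete mass balance of a solution object
#'
#' Compares the solute inventory with the time-integrated boundary influx.
#' For a slab solution the check is: stored mass minus initial mass equals the
#' cumulative surface influx.  For a moving-boundary solution the inventory is
#' the mobile profile plus the immobilized load `S * X(t)`.  Returns the
#' relative discrepancy at each stored time (skipping `t = 0`).
#'
#' @param sol a `"slab_solution"` or `"stefan_solution"` object.
#' @param ... unused.
#' @return Numeric vector of signed relative errors.
#' @export
mass_balance <- function(sol, ...) UseMethod("mass_balance")

#' @export
mass_balance.slab_solution <- function(sol, from = NULL, ...) {
  # The surface flux cannot be read off the grid while the boundary layer is
  # thinner than a few cells (sqrt(D t) < ~5 dx), so the balance window opens
  # once the layer is resolved; before that the stored mass itself is tiny.
  dx <- sol$x[2] - sol$x[1]
  if (is.null(from)) {
    from <- which(sol$times >= 25 * dx^2 / sol$params$D)[1]
    if (is.na(from)) from <- 1L
    from <- max(from, 2L)
  }
  mass <- apply(sol$C, 1L, function(ci) trapz(sol$x, ci))
  keep <- from:length(sol$times)
  influx <- cumtrapz(sol$times[keep], sol$flux0[keep])
  gained <- mass[keep] - mass[from]
  err <- (gained - influx) / pmax(mass[keep], .Machine$double.eps)
  err[-1]
}

#' Breakthrough time of the colour-change criterion
#'
#' Runs [solve_slab()] until the wall concentration `c(L, t)` first reaches
#' the colour-change threshold, and locates the crossing by linear
#' interpolation between stored time steps.  The horizon starts at
#' `0.5 L^2 / D` (ample for thresholds well below `c0`) and is doubled, up to
#' `max_doublings` times, if the threshold has not yet been crossed.
#'
#' @param params a [diffusion_params()] object with `c_threshold < c0`.
#' @param n_grid,n_steps spatial and temporal resolution per [solve_slab()].
#' @param max_doublings horizon extensions before giving up.
#' @return An object of class `"breakthrough_result"`: list with `t_star` (s)
#'   and `converged`.
#' @examples
#' p <- kps_sylgard_params()
#' par <- diffusion_params(p$D_volume, p$c0, p$c_threshold, L = 1e-3)
#' breakthrough_time(par, n_grid = 101, n_steps = 300)
#' @export
breakthrough_time <- function(params, n_grid = 201, n_steps = 800,
                              max_doublings = 6) {
  stopifnot(inherits(params, "diffusion_params"))
  if (params$c_threshold >= params$c0) {
    stop_bad(sprintf(
      "threshold %.4g mol/m^3 is unreachable: the source concentration %.4g is its supremum",
      params$c_threshold, params$c0), "delamsim_unreachable")
  }
  t_end <- 0.5 * params$L^2 / params$D
  for (i in seq_len(max_doublings + 1L)) {
    sol <- solve_slab(params, t_end, n_grid = n_grid, n_steps = n_steps)
    wall <- sol$C[, ncol(sol$C)]
    hit <- which(wall >= params$c_threshold)
    if (length(hit)) {
      k <- hit[1]
      if (k == 1L) {
        t_star <- sol$times[1]
      } else {
        # linear interpolation between the bracketing snapshots
        w0 <- wall[k - 1L]; w1 <- wall[k]
        t_star <- sol$times[k - 1L] +
          (params$c_threshold - w0) / (w1 - w0) * (sol$times[k] - sol$times[k - 1L])
      }
      return(structure(list(t_star = t_star, converged = TRUE),
                       class = "breakthrough_result"))
    }
    t_end <- t_end * 2
  }
  structure(list(t_star = NA_real_, converged = FALSE),
            class = "breakthrough_result")
}

#' @export
print.breakthrough_result <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Breakthrough at t* = %.5g s (%.3g h)\n", x$t_star,
                x$t_star / 3600))
  } else {
    cat("Threshold not crossed within the explored horizon\n")
  }
  invisible(x)
}

#' Breakthrough times over a set of slab thicknesses
#'
#' Repeats [breakthrough_time()] for each thickness, reproducing the layout of
#' the layered-cuvette assay in which slabs of 1-10 mm are cast over copper
#' plates and the colour-change time is read per thickness.
#'
#' @param params_base a [diffusion_params()] object; its `L` is ignored.
#' @param thicknesses_mm slab thicknesses, mm; positive and distinct.
#' @param ... passed to [breakthrough_time()].
#' @return A data frame of class `"breakthrough_curve"` with columns
#'   `thickness_mm`, `t_star_s`, `t_star_h`, `converged`.
#' @examples
#' p <- kps_sylgard_params()
#' par <- diffusion_params(p$D_volume, p$c0, p$c_threshold, L = 1e-3)
#' breakthrough_curve(par, c(1, 2), n_grid = 101, n_steps = 300)
#' @export
breakthrough_curve <- function(params_base, thicknesses_mm, ...) {
  stopifnot(inherits(params_base, "diffusion_params"))
  if (length(thicknesses_mm) == 0) {
    out <- data.frame(thickness_mm = numeric(0), t_star_s = numeric(0),
                      t_star_h = numeric(0), converged = logical(0))
    class(out) <- c("breakthrough_curve", "data.frame")
    return(out)
  }
  stopifnot(is.numeric(thicknesses_mm), all(thicknesses_mm > 0))
  if (anyDuplicated(thicknesses_mm)) {
    stop_bad("thicknesses must be distinct", "delamsim_bad_parameter")
  }
  rows <- lapply(thicknesses_mm, function(L_mm) {
    p <- diffusion_params(params_base$D, params_base$c0,
                          params_base$c_threshold, mm_to_m(L_mm))
    bt <- breakthrough_time(p, ...)
    data.frame(thickness_mm = L_mm, t_star_s = bt$t_star,
               t_star_h = bt$t_star / 3600, converged = bt$converged)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("breakthrough_curve", "data.frame")
  out
}
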