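#' Reference parameters of the potassium polysulfide / Sylgard 184 test system
#'
#' Experimentally determined constants for the copper / Sylgard 184 assay
#' probed with 2% potassium polysulfide solution: the bulk diffusion
#' coefficient of the polysulfide ion in cured Sylgard 184 (estimated from
#' breakthrough times via the Einstein-Smoluchowski relation), the interface
#' diffusion coefficient, the empirically fitted square-root-of-time boundary
#' coefficient of the detachment front, the source and colour-change threshold
#' concentrations, and the droplet radius of the interface test specimen.
#'
#' @return A named list with elements `D_volume` (m^2/s), `Di` (m^2/s),
#'   `alpha` (mm/min^0.5), `c0` (mol/m^3), `c_threshold` (mol/m^3) and
#'   `droplet_radius` (m).
#' @examples
#' kps_sylgard_params()
#' @export
kps_sylgard_params <- function() {
  list(
    D_volume       = 8.901e-11,  # bulk diffusion coefficient, m^2/s
    Di             = 1.6761e-10, # interface diffusion coefficient, m^2/s
    alpha          = 0.027,      # detachment front coefficient, mm/min^0.5
    c0             = 159.9,      # solution concentration, mol/m^3
    c_threshold    = 24.23,      # copper colour-change threshold, mol/m^3
    droplet_radius = 0.014       # PDMS droplet radius, m
  )
}

#' Parameters for volume diffusion through a silicone slab
#'
#' Bundles and validates the inputs of the slab breakthrough model: diffusion
#' coefficient, infinite-source concentration applied at the exposed surface,
#' the threshold concentration at which the buried copper indicator changes
#' colour, and the slab thickness.
#'
#' @param D diffusion coefficient, m^2/s.
#' @param c0 source concentration held at the exposed surface, mol/m^3.
#' @param c_threshold breakthrough (colour-change) concentration, mol/m^3.
#' @param L slab thickness, m.
#' @return An object of class `"diffusion_params"`.
#' @seealso [solve_slab()], [breakthrough_time()]
#' @examples
#' p <- kps_sylgard_params()
#' diffusion_params(p$D_volume, p$c0, p$c_threshold, L = 10e-3)
#' @export
diffusion_params <- function(D, c0, c_threshold, L) {
  check_scalar(D, "D")
  check_scalar(c0, "c0")
  check_scalar(c_threshold, "c_threshold")
  check_scalar(L, "L")
  structure(list(D = D, c0 = c0, c_threshold = c_threshold, L = L),
            class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat("Slab volume-diffusion parameters\n")
  cat(sprintf("  D           = %.4g m^2/s\n", x$D))
  cat(sprintf("  c0          = %.4g mol/m^3 (infinite source)\n", x$c0))
  cat(sprintf("  c_threshold = %.4g mol/m^3\n", x$c_threshold))
  cat(sprintf("  L           = %.4g mm\n", m_to_mm(x$L)))
  invisible(x)
}

#' Parameters for the Stefan-type interface diffusion problem
#'
#' Interface diffusion with immediate irreversible immobilization: a
#' semi-infinite sheet in contact with a well-stirred solution of extent `l`
#' contains `S` capture sites per unit volume; the captured front `X(t)`
#' advances as solute arrives.  If `S` is not supplied it is calibrated from
#' the empirical front coefficient `alpha` through the exact similarity
#' relation (see [calibrate_site_density()]), which closes the model against
#' its own measured constants.
#'
#' @param Di interface diffusion coefficient, m^2/s.
#' @param c0 boundary (solution) concentration, mol/m^3.
#' @param S immobilization site density, mol/m^3, or `NULL` to calibrate from
#'   `alpha`.
#' @param l extent of the well-stirred solution, m; `Inf` (the default) keeps
#'   the boundary concentration constant, matching an assay whose solution is
#'   refreshed regularly.
#' @param alpha empirical front coefficient, mm/min^0.5; used only when
#'   `S` is `NULL`.
#' @return An object of class `"stefan_params"`.
#' @seealso [track_front()], [goodman_front()], [stefan_beta()]
#' @examples
#' p <- kps_sylgard_params()
#' stefan_params(p$Di, p$c0, alpha = p$alpha)
#' @export
stefan_params <- function(Di, c0, S = NULL, l = Inf, alpha = NULL) {
  check_scalar(Di, "Di")
  check_scalar(c0, "c0")
  check_scalar(l, "l", allow_inf = TRUE)
  if (is.null(S)) {
    if (is.null(alpha)) {
      stop_bad("supply either `S` or `alpha` to calibrate it",
               "delamsim_bad_parameter")
    }
    S <- calibrate_site_density(alpha, Di, c0)
  }
  check_scalar(S, "S")
  structure(list(Di = Di, c0 = c0, S = S, l = l), class = "stefan_params")
}

#' @export
print.stefan_params <- function(x, ...) {
  cat("Moving-boundary interface-diffusion parameters\n")
  cat(sprintf("  Di = %.4g m^2/s, c0 = %.4g mol/m^3, S = %.4g mol/m^3\n",
              x$Di, x$c0, x$S))
  cat(sprintf("  loading c0/S = %.4g, reservoir extent l = %s\n",
              x$c0 / x$S, if (is.finite(x$l)) sprintf("%.4g mm", m_to_mm(x$l))
                          else "infinite"))
  b <- stefan_beta(x$c0 / x$S)
  cat(sprintf("  similarity front: X(t) = 2 beta sqrt(Di t), beta = %.5f\n", b))
  cat(sprintf("  equivalent alpha = %.4g mm/min^0.5\n",
              alpha_from_si(2 * b * sqrt(x$Di))))
  invisible(x)
}

#' Parameters for corrosion-threshold transport along the interlayer
#'
#' The thin composite interlayer between metal and polymer is fed by the
#' solution edge; an interlayer element is corroded, detached and removed once
#' its local concentration reaches the limiting value `c_limit`.  With
#' `c_limit = NULL` the threshold is calibrated so the simulated detachment
#' front reproduces the empirical coefficient `alpha` (see
#' [calibrate_removal_threshold()]).
#'
#' @param Di diffusion coefficient along the interlayer, m^2/s.
#' @param c_boundary solution concentration at the exposed edge, mol/m^3.
#' @param c_limit removal (corrosion) threshold, mol/m^3, strictly between 0
#'   and `c_boundary`; `NULL` calibrates it from `alpha`.
#' @param cell_size interlayer discretization cell, m.
#' @param alpha empirical front coefficient, mm/min^0.5; used only when
#'   `c_limit` is `NULL`.
#' @return An object of class `"transport_params"`.
#' @seealso [run_interlayer()], [interlayer_step()]
#' @examples
#' p <- kps_sylgard_params()
#' transport_params(p$Di, p$c0, alpha = p$alpha)
#' @export
transport_params <- function(Di, c_boundary, c_limit = NULL,
                             cell_size = 5e-6, alpha = NULL) {
  check_scalar(Di, "Di")
  check_scalar(c_boundary, "c_boundary")
  check_scalar(cell_size, "cell_size")
  if (is.null(c_limit)) {
    if (is.null(alpha)) {
      stop_bad("supply either `c_limit` or `alpha` to calibrate it",
               "delamsim_bad_parameter")
    }
    c_limit <- calibrate_removal_threshold(alpha, Di, c_boundary)
  }
  check_scalar(c_limit, "c_limit")
  structure(list(Di = Di, c_boundary = c_boundary, c_limit = c_limit,
                 cell_size = cell_size),
            class = "transport_params")
}

#' @export
print.transport_params <- function(x, ...) {
  cat("Interlayer corrosion-transport parameters\n")
  cat(sprintf("  Di = %.4g m^2/s, c_boundary = %.4g mol/m^3\n",
              x$Di, x$c_boundary))
  cat(sprintf("  c_limit = %.4g mol/m^3 (ratio %.4g), cell = %.3g mm\n",
              x$c_limit, x$c_limit / x$c_boundary, m_to_mm(x$cell_size)))
  invisible(x)
}
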