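# Synthetic stand-ins for the two laboratory assays, so every downstream
# stage (fitting, I/O, CLI) is testable without measured data.  Noise models:
# breakthrough times are positive with scatter growing with the time itself,
# hence multiplicative lognormal noise; front positions are lengths read off
# images, hence additive Gaussian noise.

local_seed <- function(seed) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  invisible(old)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(list = ".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Configuration of the synthetic experiment generators
#'
#' @param seed integer seed; the generators are fully deterministic given the
#'   seed and configuration.
#' @param noise_breakthrough lognormal sigma of the multiplicative
#'   breakthrough-time noise (dimensionless).
#' @param noise_front additive sigma of the front-position noise, mm.
#' @param replicates samples per layer thickness.
#' @param sampling_interval webcam frame interval, min; observation times are
#'   quantized to this grid.
#' @return An object of class `"synthetic_config"`.
#' @examples
#' synthetic_config(seed = 42)
#' @export
synthetic_config <- function(seed = 1L, noise_breakthrough = 0.1,
                             noise_front = 0.015, replicates = 3L,
                             sampling_interval = 5) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  check_scalar(noise_breakthrough, "noise_breakthrough", positive = FALSE)
  check_scalar(noise_front, "noise_front", positive = FALSE)
  check_scalar(sampling_interval, "sampling_interval")
  if (noise_breakthrough < 0 || noise_front < 0) {
    stop_bad("noise sigmas must be >= 0", "delamsim_bad_parameter")
  }
  if (!is.numeric(replicates) || replicates < 1) {
    stop_bad("`replicates` must be >= 1", "delamsim_bad_parameter")
  }
  structure(list(seed = as.integer(seed),
                 noise_breakthrough = noise_breakthrough,
                 noise_front = noise_front,
                 replicates = as.integer(replicates),
                 sampling_interval = sampling_interval),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("Synthetic experiment config: seed %d, %d replicates, ",
                     "%g min cadence\n  sigma(log t_obs) = %g, ",
                     "sigma(X) = %g mm\n"),
              x$seed, x$replicates, x$sampling_interval,
              x$noise_breakthrough, x$noise_front))
  invisible(x)
}

#' Generate synthetic breakthrough-time observations
#'
#' Emulates the layered-cuvette assay: for each slab thickness the model
#' breakthrough time `t_star(L)` is computed with [breakthrough_time()],
#' perturbed multiplicatively (`t_obs = t_star * exp(eps)`,
#' `eps ~ N(0, sigma^2)`) per replicate, and quantized by ceiling to the
#' webcam sampling grid — the colour change is first seen on the next frame.
#'
#' @param params_base a [diffusion_params()] object (its `L` is ignored).
#' @param thicknesses_mm slab thicknesses, mm.
#' @param cfg a [synthetic_config()].
#' @param ... resolution arguments passed to [breakthrough_time()].
#' @return A data frame with columns `thickness_mm`, `replicate`, `t_obs_s`,
#'   and the noiseless curve as attribute `"truth"`.
#' @examples
#' p <- kps_sylgard_params()
#' par <- diffusion_params(p$D_volume, p$c0, p$c_threshold, 1e-3)
#' gen_breakthrough(par, c(1, 2), synthetic_config(1), n_grid = 101,
#'                  n_steps = 300)
#' @export
gen_breakthrough <- function(params_base, thicknesses_mm = 1:10,
                             cfg = synthetic_config(), ...) {
  stopifnot(inherits(cfg, "synthetic_config"))
  curve <- breakthrough_curve(params_base, thicknesses_mm, ...)
  old <- local_seed(cfg$seed)
  on.exit(restore_seed(old))
  dt_s <- min_to_s(cfg$sampling_interval)
  rows <- lapply(seq_len(nrow(curve)), function(i) {
    eps <- rnorm(cfg$replicates, 0, cfg$noise_breakthrough)
    t_obs <- ceiling(curve$t_star_s[i] * exp(eps) / dt_s) * dt_s
    data.frame(thickness_mm = curve$thickness_mm[i],
               replicate = seq_len(cfg$replicates),
               t_obs_s = t_obs)
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- curve
  out
}

#' Generate a synthetic detachment front trace
#'
#' Emulates the droplet detachment assay: the front follows
#' `X = alpha * sqrt(t)` sampled at the webcam cadence, with additive
#' Gaussian measurement noise, floored at zero and made nondecreasing with a
#' running maximum (a detached distance cannot shrink).
#'
#' @param alpha generating front coefficient, mm/min^0.5.
#' @param t_end_min horizon, min.
#' @param cfg a [synthetic_config()].
#' @return A [front_trace()] starting at `(0, 0)`.
#' @examples
#' gen_front_trace(0.027, 100, synthetic_config(7))
#' @export
gen_front_trace <- function(alpha, t_end_min, cfg = synthetic_config()) {
  check_scalar(alpha, "alpha", positive = FALSE)
  if (alpha < 0) stop_bad("`alpha` must be >= 0", "delamsim_bad_parameter")
  check_scalar(t_end_min, "t_end_min")
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- local_seed(cfg$seed)
  on.exit(restore_seed(old))
  tt <- seq(cfg$sampling_interval, t_end_min, by = cfg$sampling_interval)
  X <- alpha * sqrt(tt) + rnorm(length(tt), 0, cfg$noise_front)
  X <- cummax(pmax(X, 0))
  front_trace(c(0, tt), c(0, X))
}
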