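#' Einstein-Smoluchowski diffusion-coefficient estimate
#'
#' `D = x^2 / (2 t)`: the diffusion coefficient implied by a penetration
#' depth `x` reached after time `t`.  This is how the bulk coefficient of the
#' slab assay is estimated from colour-change times.
#'
#' @param x penetration depth, m (>= 0); vectorized.
#' @param t time, s (> 0); vectorized.
#' @return Diffusion coefficient(s), m^2/s.
#' @examples
#' einstein_smoluchowski(10e-3, 5.617346e5)  # ~ 8.9e-11 m^2/s
#' @export
einstein_smoluchowski <- function(x, t) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    stop_bad("`x` must be nonnegative", "delamsim_bad_parameter")
  }
  if (!is.numeric(t) || any(is.na(t)) || any(t <= 0)) {
    stop_bad("`t` must be > 0", "delamsim_bad_parameter")
  }
  x^2 / (2 * t)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with the total sum of squares taken about the
#' mean of the observations.  Can be negative for models worse than the mean.
#' Undefined (rejected) for a constant observed series.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @return The coefficient of determination.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted))
  if (length(observed) != length(predicted) || length(observed) < 2) {
    stop_bad("`observed` and `predicted` must have equal length >= 2",
             "delamsim_bad_parameter")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop_bad("R^2 is undefined for a constant observed series",
             "delamsim_degenerate")
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

# pull (t, X) columns out of whatever trace-like object is supplied
extract_trace_xy <- function(trace) {
  df <- as.data.frame(trace)
  if (all(c("t_min", "X_mm") %in% names(df))) {
    list(t = df$t_min, X = df$X_mm, xlab = "t [min]", ylab = "X [mm]")
  } else if (all(c("t_min", "gap_mm") %in% names(df))) {
    list(t = df$t_min, X = df$gap_mm, xlab = "t [min]", ylab = "gap [mm]")
  } else if (ncol(df) >= 2 && is.numeric(df[[1]]) && is.numeric(df[[2]])) {
    list(t = df[[1]], X = df[[2]], xlab = names(df)[1], ylab = names(df)[2])
  } else {
    stop_bad("cannot find a (time, position) pair in `trace`",
             "delamsim_bad_trace")
  }
}

#' Fit the square-root-of-time front law
#'
#' Least-squares fit of `X = alpha * sqrt(t)` through the origin (the law has
#' no intercept), with the closed-form estimator
#' `alpha_hat = sum(X_i sqrt(t_i)) / sum(t_i)`.  An optional intercept mode
#' (`X = a + alpha sqrt(t)`, via [stats::lm()]) is available for diagnostics
#' only.  Works on [front_trace()] / [gap_trace()] objects or any data frame
#' whose first two numeric columns are time and position; with the standard
#' trace units the coefficient comes out in mm/min^0.5.
#'
#' @param trace a trace object or data frame (>= 2 points, `t >= 0`).
#' @param intercept fit a free intercept (diagnostic mode)?
#' @return An object of class `"sqrt_fit"` with components `alpha_hat`,
#'   `intercept`, `r_squared`, `fitted`, `residuals`, `t`, `X`.  Methods:
#'   `print`, `summary`, `coef`, `predict`, `residuals`, `fitted`, `plot`,
#'   `simulate`.
#' @examples
#' tr <- front_trace(c(0, 25, 100), 0.027 * sqrt(c(0, 25, 100)))
#' fit <- fit_sqrt_law(tr)
#' coef(fit)
#' @export
fit_sqrt_law <- function(trace, intercept = FALSE) {
  xy <- extract_trace_xy(trace)
  t <- xy$t
  X <- xy$X
  if (length(t) < 2) {
    stop_bad("need at least 2 points", "delamsim_bad_parameter")
  }
  if (any(is.na(t)) || any(is.na(X)) || any(t < 0)) {
    stop_bad("trace must be complete with t >= 0", "delamsim_bad_trace")
  }
  if (all(t == 0)) {
    stop_bad("all times are zero: the sqrt-law design is degenerate",
             "delamsim_degenerate")
  }
  if (intercept) {
    fit <- lm(X ~ I(sqrt(t)))
    a0 <- unname(coef(fit)[1])
    alpha_hat <- unname(coef(fit)[2])
  } else {
    a0 <- 0
    alpha_hat <- sum(X * sqrt(t)) / sum(t)
  }
  fitted <- a0 + alpha_hat * sqrt(t)
  res <- X - fitted
  r2 <- if (sum((X - mean(X))^2) > 0) r_squared(X, fitted) else NA_real_
  structure(list(alpha_hat = alpha_hat, intercept = a0, r_squared = r2,
                 fitted = fitted, residuals = res, t = t, X = X,
                 has_intercept = intercept,
                 xlab = xy$xlab, ylab = xy$ylab),
            class = "sqrt_fit")
}

#' @export
print.sqrt_fit <- function(x, ...) {
  cat("Square-root-of-time front law fit: X = alpha * sqrt(t)\n")
  cat(sprintf("  alpha_hat = %.5g mm/min^0.5", x$alpha_hat))
  if (x$has_intercept) cat(sprintf(", intercept = %.4g mm", x$intercept))
  cat(sprintf("\n  R^2 = %.4f over %d points\n", x$r_squared, length(x$t)))
  invisible(x)
}

#' @export
coef.sqrt_fit <- function(object, ...) {
  if (object$has_intercept) {
    c(intercept = object$intercept, alpha = object$alpha_hat)
  } else {
    c(alpha = object$alpha_hat)
  }
}

#' @export
residuals.sqrt_fit <- function(object, ...) object$residuals

#' @export
fitted.sqrt_fit <- function(object, ...) object$fitted

#' @export
predict.sqrt_fit <- function(object, t = NULL, ...) {
  if (is.null(t)) return(object$fitted)
  if (any(t < 0)) stop_bad("`t` must be nonnegative", "delamsim_bad_parameter")
  object$intercept + object$alpha_hat * sqrt(t)
}

#' @export
summary.sqrt_fit <- function(object, ...) {
  structure(list(fit = object,
                 sigma = sd(object$residuals),
                 n = length(object$t)),
            class = "summary.sqrt_fit")
}

#' @export
print.summary.sqrt_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual sd = %.4g mm, n = %d\n", x$sigma, x$n))
  invisible(x)
}

#' @export
plot.sqrt_fit <- function(x, ...) {
  plot(x$t, x$X, xlab = x$xlab, ylab = x$ylab, ...)
  tt <- seq(min(x$t), max(x$t), length.out = 200)
  lines(tt, predict(x, tt), col = 2)
  invisible(x)
}

#' @export
simulate.sqrt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  sigma <- sd(object$residuals)
  lapply(seq_len(nsim), function(i) {
    X <- predict(object, object$t) + rnorm(length(object$t), 0, sigma)
    data.frame(t_min = object$t, X_mm = X)
  })
}

#' Mean coefficient of determination across replicate traces
#'
#' Assesses a model trace against one or more experimental traces: each
#' replicate is linearly interpolated onto the model's time points and its
#' R^2 computed; the average over replicates is returned (a single replicate
#' returns its own R^2).
#'
#' @param predicted a trace-like object (the model).
#' @param observed a trace-like object or list of them (the replicates).
#' @return The mean R^2.
#' @export
mean_r_squared <- function(observed, predicted) {
  if (!is.list(observed) || is.data.frame(observed)) observed <- list(observed)
  p <- extract_trace_xy(predicted)
  vals <- vapply(observed, function(ob) {
    o <- extract_trace_xy(ob)
    pi <- stats::approx(p$t, p$X, xout = o$t, rule = 2)$y
    r_squared(o$X, pi)
  }, numeric(1))
  mean(vals)
}
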