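ref_stefan <- function(...) {
  stefan_params(REF$Di, REF$c0, alpha = REF$alpha, ...)
}

test_that("similarity root vanishes with the loading and increases with it", {
  loadings <- c(1e-6, 1e-4, 0.01, 0.1, 0.5, 2)
  betas <- vapply(loadings, stefan_beta, numeric(1))
  expect_true(all(diff(betas) > 0))
  expect_lt(betas[1], 1e-3)
  # small-loading asymptote beta ~ sqrt(m / 2)
  expect_equal(betas[2], sqrt(1e-4 / 2), tolerance = 1e-3)
})

test_that("similarity root satisfies the transcendental equation to high accuracy", {
  for (m in c(0.005, 0.0366859, 0.2, 1)) {
    b <- stefan_beta(m)
    expect_equal(oracle_stefan_lhs(b), m, tolerance = 1e-10)
  }
  # frozen consistency with the empirically calibrated test system:
  # beta = alpha_SI / (2 sqrt(Di)) maps to a loading of about 0.0367
  b_cal <- (REF$alpha * 1e-3 / sqrt(60)) / (2 * sqrt(REF$Di))
  expect_equal(b_cal, 0.1346196, tolerance = 1e-6)
  expect_equal(oracle_stefan_lhs(b_cal), 0.0366859, tolerance = 1e-5)
  expect_equal(stefan_beta(0.0366859), b_cal, tolerance = 1e-5)
})

test_that("site-density calibration closes the model on the measured front law", {
  S <- calibrate_site_density(REF$alpha, REF$Di, REF$c0)
  expect_equal(S, 4358.618, tolerance = 1e-6)
  b <- stefan_beta(REF$c0 / S)
  expect_equal(alpha_from_si(2 * b * sqrt(REF$Di)), REF$alpha,
               tolerance = 1e-10)
})

test_that("Goodman front starts at the origin and scales self-similarly", {
  sp <- ref_stefan()
  g0 <- goodman_front(sp, 0)
  expect_identical(g0$X, 0)
  g1 <- goodman_front(sp, 600)
  g4 <- goodman_front(sp, 2400)
  expect_equal(g4$X, 2 * g1$X, tolerance = 1e-12)
  # profile is nonnegative on [0, X] with c(X) = 0 and c(0) = c0
  xx <- seq(0, g1$X, length.out = 101)
  cc <- g1$a * (xx - g1$X) + g1$b * (xx - g1$X)^2
  expect_equal(cc[1], sp$c0, tolerance = 1e-9)
  expect_equal(cc[101], 0, tolerance = 1e-12)
  expect_true(all(cc >= -1e-12))
})

test_that("heat-balance-integral beta tracks the exact root within 5%", {
  loadings <- exp(seq(log(0.01), log(0.5), length.out = 21))
  for (m in loadings) {
    expect_lt(abs(goodman_beta(m) / stefan_beta(m) - 1), 0.05)
  }
})

test_that("front tracking reproduces the exact similarity front within 2%", {
  sp <- ref_stefan()
  sol <- track_front(sp, t_end = 200 * 60, n_grid = 121)
  b <- stefan_beta(sp$c0 / sp$S)
  exact <- 2 * b * sqrt(sp$Di * sol$times_s)
  expect_lt(max(abs(sol$X_m - exact) / exact), 0.02)
})

test_that("tracked front is self-similar: sqrt-law fit on the late trace is near-perfect", {
  sp <- ref_stefan()
  sol <- track_front(sp, t_end = 400 * 60,
                     out_times = 60 * seq(5, 400, by = 5))
  tr <- sol$trace
  late <- tr[tr$t_min >= max(tr$t_min) / 2, ]
  fit <- fit_sqrt_law(late)
  expect_gt(fit$r_squared, 0.999)
})

test_that("solute is conserved: mobile profile plus immobilized load equals influx", {
  sol <- track_front(ref_stefan(), t_end = 200 * 60, n_grid = 121)
  expect_lt(max(abs(mass_balance(sol))), 0.01)
})

test_that("a very large site density freezes the front", {
  sp <- stefan_params(REF$Di, REF$c0, S = 1e4 * REF$c0)
  sol <- track_front(sp, t_end = 400 * 60)
  expect_lt(tail(sol$trace$X_mm, 1), 0.05)   # vs 0.54 mm when calibrated
})

test_that("a finite reservoir depletes and the front falls below the infinite-l trace", {
  tt <- 60 * seq(5, 400, by = 5)
  inf_sol <- track_front(ref_stefan(), t_end = 400 * 60, out_times = tt)
  fin_sol <- track_front(ref_stefan(l = 2e-3), t_end = 400 * 60, out_times = tt)
  expect_lt(tail(fin_sol$c_surface, 1), 0.5 * REF$c0)
  expect_true(all(diff(fin_sol$c_surface) <= 1e-9))
  n <- length(tt)
  late <- (n %/% 2):n
  expect_true(all(fin_sol$X_m[late] < inf_sol$X_m[late]))
})

test_that("front positions follow the explicit sqrt-law in assay units", {
  expect_identical(front_position(0.027, 0), 0)
  expect_identical(front_position(0.027, 1), 0.027)
  expect_equal(front_position(0.027, 100), 0.27, tolerance = 1e-12)
  expect_error(front_position(-1, 10), class = "delamsim_bad_parameter")
  expect_error(front_position(0.027, -1), class = "delamsim_bad_parameter")
})

test_that("degenerate and invalid Stefan inputs are refused", {
  expect_error(stefan_beta(0), class = "delamsim_bad_parameter")
  expect_error(stefan_beta(-1), class = "delamsim_bad_parameter")
  expect_error(stefan_params(REF$Di, REF$c0, S = 0),
               class = "delamsim_bad_parameter")
  expect_error(stefan_params(REF$Di, REF$c0, S = -5),
               class = "delamsim_bad_parameter")
  expect_error(stefan_params(REF$Di, REF$c0),
               class = "delamsim_bad_parameter")
  expect_error(goodman_front(ref_stefan(), -1),
               class = "delamsim_bad_parameter")
  expect_error(track_front(ref_stefan(), t_end = 1000, n_grid = 5),
               class = "delamsim_resolution")
})
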