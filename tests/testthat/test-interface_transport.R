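ref_transport <- function(cell = 1e-5, ...) {
  transport_params(REF$Di, REF$c0, alpha = REF$alpha, cell_size = cell, ...)
}

test_that("removal-threshold calibration reproduces the measured front law", {
  clim <- calibrate_removal_threshold(REF$alpha, REF$Di, REF$c0)
  expect_equal(clim, 135.7568, tolerance = 1e-6)
  expect_gt(clim, 0)
  expect_lt(clim, REF$c0)
  # round trip through the level-set similarity coefficient
  beta <- qnorm(clim / REF$c0 / 2, lower.tail = FALSE) / sqrt(2)
  expect_equal(alpha_from_si(2 * beta * sqrt(REF$Di)), REF$alpha,
               tolerance = 1e-9)
})

test_that("no cell is removed while the threshold is never reached", {
  # threshold above the boundary concentration: unreachable by the maximum
  # principle, the front can never leave the solution edge
  tp <- transport_params(REF$Di, c_boundary = REF$c0, c_limit = 1.5 * REF$c0,
                         cell_size = 1e-5)
  sol <- suppressWarnings(run_interlayer(tp, length = 2e-3, t_end = 30 * 60,
                                         n_steps = 300))
  expect_equal(sol$state$front_index, 1L)
  expect_false(any(sol$state$removed))
  expect_true(all(sol$trace$X_mm == 0))
  # threshold just below the boundary value: not reached over a short horizon
  tp2 <- transport_params(REF$Di, c_boundary = REF$c0,
                          c_limit = REF$c0 * 0.999, cell_size = 1e-5)
  sol2 <- suppressWarnings(run_interlayer(tp2, length = 2e-3, t_end = 60,
                                          n_steps = 100))
  expect_equal(sol2$state$front_index, 1L)
})

test_that("diffusion decay without removal: field decays, state stays intact", {
  tp <- transport_params(REF$Di, c_boundary = 1e-9, c_limit = 100,
                         cell_size = 1e-5)
  st <- interlayer_state(50, tp$cell_size, c = 50)   # uniform, below c_limit
  st2 <- interlayer_step(st, tp, dt = 100)
  expect_false(any(st2$removed))
  expect_equal(st2$front_index, 1L)
  expect_lt(sum(st2$c), sum(st$c))   # mass leaks out of the near-zero boundary
})

test_that("front advances monotonically, as a contiguous prefix, one cell per step at most", {
  tp <- ref_transport(cell = 2e-5)
  sol <- run_interlayer(tp, length = 4e-3, t_end = 50 * 60, n_steps = 400)
  expect_true(all(diff(sol$trace$X_mm) >= 0))
  n_rem <- sol$state$front_index - 1L
  expect_true(all(sol$state$removed[seq_len(n_rem)]))
  expect_false(any(sol$state$removed[-seq_len(n_rem)]))
  # removed cells have been overrun by the solution: at or above the threshold
  expect_true(all(sol$state$c[seq_len(n_rem)] >= tp$c_limit - 1e-9))
})

test_that("long-run front fits a sqrt-law with K matching the equivalent Stefan root", {
  tp <- transport_params(REF$Di, REF$c0, c_limit = 100, cell_size = 1e-5)
  sol <- run_interlayer(tp, length = 8e-3, t_end = 150 * 60, n_steps = 800)
  tr <- sol$trace
  late <- tr[tr$t_min >= max(tr$t_min) / 2, ]
  fit <- fit_sqrt_law(late)
  beta_eq <- stefan_beta(equivalent_loading(tp))
  K_exact <- alpha_from_si(2 * beta_eq * sqrt(REF$Di))
  expect_lt(abs(coef(fit) / K_exact - 1), 0.10)
  expect_gt(fit$r_squared, 0.99)
})

test_that("halving the cell size changes the final front position by under 2%", {
  t_end <- 150 * 60
  s1 <- run_interlayer(ref_transport(cell = 5e-6), 6e-3, t_end, n_steps = 800)
  s2 <- run_interlayer(ref_transport(cell = 2.5e-6), 6e-3, t_end, n_steps = 1600)
  x1 <- tail(s1$trace$X_mm, 1)
  x2 <- tail(s2$trace$X_mm, 1)
  expect_lt(abs(x2 - x1) / x2, 0.02)
})

test_that("a vanishing horizon leaves the front at the solution edge", {
  tp <- ref_transport(cell = 2e-5)
  sol <- suppressWarnings(run_interlayer(tp, length = 2e-3, t_end = 1e-3,
                                         n_steps = 10))
  expect_equal(tail(sol$trace$X_mm, 1), 0)
})

test_that("a horizon too short to advance one cell raises a diagnostic", {
  tp <- ref_transport(cell = 2e-5)
  expect_warning(run_interlayer(tp, length = 2e-3, t_end = 1e-3, n_steps = 10),
                 "did not advance")
})

test_that("corrupt (non-contiguous) removal state is rejected", {
  tp <- ref_transport()
  expect_error(interlayer_state(10, 1e-5,
                                removed = c(TRUE, FALSE, TRUE, rep(FALSE, 7))),
               class = "delamsim_corrupt_state")
  st <- interlayer_state(10, 1e-5)
  st$removed[3] <- TRUE    # corrupt behind the validator's back
  expect_error(interlayer_step(st, tp, 1), class = "delamsim_corrupt_state")
})

test_that("transport parameter validation enforces the threshold ordering", {
  expect_error(transport_params(REF$Di, REF$c0, c_limit = -1),
               class = "delamsim_bad_parameter")
  expect_error(transport_params(REF$Di, REF$c0),
               class = "delamsim_bad_parameter")
  expect_error(run_interlayer(ref_transport(cell = 1e-3), length = 2e-3,
                              t_end = 60), class = "delamsim_resolution")
})
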