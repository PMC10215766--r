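test_that("Einstein-Smoluchowski estimate matches its algebraic definition", {
  expect_identical(einstein_smoluchowski(0, 10), 0)
  expect_identical(einstein_smoluchowski(1, 0.5), 1)
  # the reference bulk coefficient implies ~6.5 days through a 10 mm slab
  t10 <- (10e-3)^2 / (2 * REF$D_volume)
  expect_equal(t10, 5.617346e5, tolerance = 1e-6)
  expect_equal(einstein_smoluchowski(10e-3, t10), REF$D_volume,
               tolerance = 1e-12)
  expect_error(einstein_smoluchowski(1, 0), class = "delamsim_bad_parameter")
  expect_error(einstein_smoluchowski(-1, 1), class = "delamsim_bad_parameter")
})

test_that("Einstein-Smoluchowski estimate is monotone in depth and time", {
  expect_true(all(diff(einstein_smoluchowski(c(1, 2, 3) * 1e-3, 100)) > 0))
  expect_true(all(diff(einstein_smoluchowski(1e-3, c(100, 200, 300))) < 0))
})

test_that("noiseless sqrt-law traces are recovered exactly", {
  tt <- seq(0, 400, by = 5)
  tr <- front_trace(tt, 0.027 * sqrt(tt))
  fit <- fit_sqrt_law(tr)
  expect_equal(unname(coef(fit)), 0.027, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-12)
  # an all-zero trace has a zero coefficient
  fit0 <- fit_sqrt_law(front_trace(tt, rep(0, length(tt))))
  expect_identical(unname(coef(fit0)), 0)
})

test_that("sqrt-law estimator is scale-equivariant", {
  tt <- seq(0, 100, by = 5)
  X <- 0.027 * sqrt(tt) + c(0, rep(c(0.01, -0.01), length.out = length(tt) - 1))
  a1 <- unname(coef(fit_sqrt_law(data.frame(t_min = tt, X_mm = X))))
  a3 <- unname(coef(fit_sqrt_law(data.frame(t_min = tt, X_mm = 3 * X))))
  expect_equal(a3, 3 * a1, tolerance = 1e-12)
})

test_that("noisy synthetic traces recover the generating coefficient within 5%", {
  # Monte-Carlo over 200 seeds at the documented noise level
  alphas <- vapply(1:200, function(s) {
    cfg <- synthetic_config(seed = s, noise_front = 0.01)
    tr <- gen_front_trace(0.027, t_end_min = 250, cfg)
    unname(coef(fit_sqrt_law(tr)))
  }, numeric(1))
  expect_lt(max(abs(alphas / 0.027 - 1)), 0.05)
})

test_that("the sqrt-law estimator is unbiased under additive noise", {
  # pure additive Gaussian noise (no monotonicity clipping): the closed-form
  # estimator is linear in the observations, so its bias is exactly zero
  set.seed(314)
  tt <- seq(5, 250, by = 5)
  alphas <- replicate(500, {
    X <- 0.027 * sqrt(tt) + rnorm(length(tt), 0, 0.01)
    unname(coef(fit_sqrt_law(data.frame(t_min = tt, X_mm = X))))
  })
  se <- sd(alphas) / sqrt(length(alphas))
  expect_lt(abs(mean(alphas) - 0.027), 3 * se)
})

test_that("intercept mode reduces to the ordinary least-squares line in sqrt(t)", {
  tt <- seq(0, 100, by = 10)
  X <- 0.05 + 0.027 * sqrt(tt)
  fit <- fit_sqrt_law(data.frame(t_min = tt, X_mm = X), intercept = TRUE)
  expect_equal(unname(coef(fit)), c(0.05, 0.027), tolerance = 1e-9)
})

test_that("predict and simulate methods are consistent with the fitted law", {
  tt <- seq(0, 100, by = 5)
  fit <- fit_sqrt_law(front_trace(tt, 0.03 * sqrt(tt)))
  expect_equal(predict(fit, c(0, 4, 100)), 0.03 * c(0, 2, 10),
               tolerance = 1e-12)
  sims <- simulate(fit, nsim = 2, seed = 11)
  expect_length(sims, 2L)
  expect_equal(sims[[1]]$t_min, tt)
  sims2 <- simulate(fit, nsim = 2, seed = 11)
  expect_identical(sims[[1]]$X_mm, sims2[[1]]$X_mm)
})

test_that("coefficient of determination follows its definition", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5, tolerance = 1e-12)
  obs <- c(2, 4, 5, 7)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  # worse than the mean: negative
  expect_lt(r_squared(c(1, 2, 3), c(3, 2, 1)), 0)
})

test_that("degenerate fitting inputs are rejected", {
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), class = "delamsim_degenerate")
  expect_error(r_squared(1, 1), class = "delamsim_bad_parameter")
  expect_error(fit_sqrt_law(data.frame(t_min = c(0, 0), X_mm = c(0, 1))),
               class = "delamsim_degenerate")
  expect_error(fit_sqrt_law(data.frame(t_min = 1, X_mm = 1)),
               class = "delamsim_bad_parameter")
})

test_that("mean R^2 averages per-replicate agreement against a model trace", {
  tt <- seq(0, 100, by = 10)
  model <- front_trace(tt, 0.027 * sqrt(tt))
  reps <- lapply(c(3, 5), function(s) {
    gen_front_trace(0.027, 100, synthetic_config(seed = s, noise_front = 0.005))
  })
  r_each <- vapply(reps, function(r) {
    pred <- approx(model$t_min, model$X_mm, xout = r$t_min, rule = 2)$y
    r_squared(r$X_mm, pred)
  }, numeric(1))
  expect_equal(mean_r_squared(reps, model), mean(r_each), tolerance = 1e-12)
  expect_equal(mean_r_squared(reps[[1]], model), r_each[1], tolerance = 1e-12)
})
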