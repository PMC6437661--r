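test_that("noise-model fitting recovers known parameters from synthetic residuals", {
  des <- stimulus_design(repeats = 270)          # n = 2160 rows
  pop <- simulate_population(v = 40, seed = 1)
  fit <- iem(simulate_dataset(pop, des, 0.01, 5), channel_basis(8))
  W <- coef(fit)
  tau_star <- 0.02
  sc_star <- 0.05
  set.seed(21)
  n <- des$n; v <- ncol(W)
  Z <- matrix(rnorm(n * 8, sd = sc_star), n, 8) %*% W +
    matrix(rnorm(n * v, sd = tau_star), n, v)
  synth <- voxel_dataset(predict(fit) + Z, des, role = "train")
  nm <- fit_noise_model(fit, synth)
  expect_lt(sqrt(sum((nm$tau - tau_star)^2) / (v * tau_star^2)), 0.05)
  expect_lt(abs(nm$sigma_c - sc_star) / sc_star, 0.15)
  # channel noise absent: sigma_c^2 collapses relative to the voxel variance
  Z0 <- matrix(rnorm(n * v, sd = tau_star), n, v)
  nm0 <- fit_noise_model(fit, voxel_dataset(predict(fit) + Z0, des,
                                            role = "train"))
  expect_lt(nm0$sigma_c^2 / mean(nm0$tau^2), 0.05)
  expect_lt(sqrt(sum((nm0$tau - tau_star)^2) / (v * tau_star^2)), 0.05)
})

test_that("zero residuals are rejected rather than silently fit", {
  pair <- sim_pair(0, seed = 2, v = 10)
  fit <- iem(pair$train, channel_basis(8))
  expect_error(fit_noise_model(fit, pair$train), "residual")
})

test_that("the factorized log-density matches a dense oracle and is axial", {
  pair <- sim_pair(0.01, seed = 3, v = 10)
  fit <- iem(pair$train, channel_basis(8))
  nm <- fit_noise_model(fit, pair$train)
  b <- pair$val$B[5, ]
  for (theta in c(0, 33.7, 90)) {
    ll <- response_log_likelihood(b, theta, fit, nm)
    mu <- drop(eval_basis(fit$basis, theta) %*% coef(fit))
    dense <- -0.5 * (10 * log(2 * pi) + determinant(nm$Omega)$modulus[1] +
                       drop((b - mu) %*% solve(nm$Omega) %*% (b - mu)))
    expect_equal(ll, dense, tolerance = 1e-8)
    expect_equal(ll, response_log_likelihood(b, theta + 180, fit, nm))
  }
  # at the mean, the log-density is -(v log 2pi + log det Omega) / 2
  mu0 <- drop(eval_basis(fit$basis, 45) %*% coef(fit))
  expect_equal(response_log_likelihood(mu0, 45, fit, nm),
               -0.5 * (10 * log(2 * pi) + determinant(nm$Omega)$modulus[1]),
               tolerance = 1e-8)
})

test_that("posteriors are normalized distributions over the grid", {
  pair <- sim_pair(0.008, seed = 4, v = 30)
  fit <- iem(pair$train, channel_basis(8))
  nm <- fit_noise_model(fit, pair$train)
  pm <- posterior_grid(pair$val, fit, nm, grid_step = 1)
  expect_equal(dim(pm$prob), c(216L, 180L))
  expect_lt(max(abs(rowSums(pm$prob) - 1)), 1e-12)
  expect_true(all(pm$prob >= 0))
  expect_error(posterior_grid(pair$val, fit, nm, grid_step = 7), "divide")
  # a zero-weight model is uninformative: every row uniform
  fit0 <- fit
  fit0$weights[] <- 0
  nm0 <- fit_noise_model(fit0, pair$train)
  pm0 <- posterior_grid(pair$val, fit0, nm0, grid_step = 1)
  expect_lt(max(abs(pm0$prob - 1 / 180)), 1e-12)
})

test_that("posterior summaries align to truth and quantify spread", {
  pair <- sim_pair(0.008, seed = 5, v = 50)
  fit <- iem(pair$train, channel_basis(8))
  nm <- fit_noise_model(fit, pair$train)
  pm <- posterior_grid(pair$val, fit, nm, grid_step = 0.5)
  ps <- summarize_posteriors(pm)
  expect_equal(nrow(ps$trials), 216L)
  expect_equal(ps$peak_offset_deg, 0)
  expect_equal(ps$n_modes, 1L)
  expect_lte(ps$median_error_deg, 2)
  # a single symmetric unimodal row centered on truth: error 0, one mode
  g <- seq(0, 179.5, by = 0.5)
  row <- exp(-0.5 * (circular_distance(g, 45) / 5)^2)
  pm1 <- structure(list(grid = g, prob = matrix(row / sum(row), 1),
                        truth = 45, grid_step = 0.5),
                   class = "posterior_map")
  ps1 <- summarize_posteriors(pm1)
  expect_equal(ps1$trials$error_deg, 0)
  expect_equal(ps1$n_modes, 1L)
  expect_equal(ps1$fwhm_deg, 2 * sqrt(2 * log(2)) * 5, tolerance = 0.1)
})
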