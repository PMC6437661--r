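test_that("forward channel responses are the basis rows of the presented stimuli", {
  des <- default_design8(repeats = 2)
  b1 <- channel_basis(8)
  fwd <- forward_channel_responses(des, b1)
  C <- eval_basis(b1, des$orientations)
  for (t in seq_len(des$n))
    expect_equal(fwd$R[t, ], C[match(des$labels[t], des$orientations), ])
  # transformed basis: R2 = R1 P
  tr <- bimodal_transform(8)
  fwd2 <- forward_channel_responses(des, transform_basis(b1, tr))
  expect_lt(max(abs(fwd2$R - fwd$R %*% tr$P)), 1e-12)
})

test_that("least-squares weights match the normal-equations oracle and recover truth", {
  des <- default_design8(repeats = 3)
  b1 <- channel_basis(8)
  R <- forward_channel_responses(des, b1)$R
  W_true <- matrix(sin(1:(8 * 10)), 8, 10)
  data <- voxel_dataset(R %*% W_true, des, sigma = 0, role = "train")
  fit <- iem(data, b1)
  expect_equal(unname(coef(fit)), W_true, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  # explicit (R'R)^{-1} R' B oracle
  noisy <- simulate_dataset(simulate_population(v = 12, seed = 9), des,
                            sigma = 0.05, seed = 10)
  fit2 <- iem(noisy, b1)
  W_oracle <- solve(crossprod(R), crossprod(R, noisy$B))
  expect_lt(max(abs(coef(fit2) - W_oracle)), 1e-10)
})

test_that("rank-deficient channel responses are rejected with the rank", {
  # 4 distinct orientations cannot identify 8 channels
  des <- stimulus_design(c(0, 45, 90, 135), repeats = 3)
  pop <- simulate_population(v = 10, seed = 1)
  dat <- simulate_dataset(pop, des, 0.01, 2)
  expect_error(iem(dat, channel_basis(8)), "rank")
})

test_that("predictions extend to orientations never used in training", {
  pair <- sim_pair(0, seed = 3, v = 15)
  fit <- iem(pair$train, channel_basis(8))
  # on training data at sigma = 0 the fit interpolates exactly
  expect_equal(predict(fit), pair$train$B, tolerance = 1e-9)
  # novel orientations evaluate the basis afresh
  novel <- stimulus_design(c(10, 97.3), repeats = 2)
  Bhat <- predict(fit, novel)
  expect_equal(dim(Bhat), c(4L, 15L))
  C_lo <- eval_basis(channel_basis(8), novel$orientations)
  expect_equal(Bhat, novel$S %*% C_lo %*% coef(fit), tolerance = 1e-12)
  # zero weights predict zero
  fit0 <- fit
  fit0$weights[] <- 0
  expect_equal(predict(fit0), 0 * pair$train$B)
})

test_that("model inversion matches the per-trial least-squares oracle", {
  pair <- sim_pair(0.02, seed = 4, v = 30)
  fit <- iem(pair$train, channel_basis(8))
  recon <- invert_iem(fit, pair$val)
  W <- coef(fit)
  # explicit Eq-style pseudo-inverse
  R_explicit <- pair$val$B %*% t(W) %*% solve(tcrossprod(W))
  expect_lt(max(abs(recon$R - R_explicit)), 1e-10)
  # per-trial brute-force least squares min || b_t - r W ||
  for (t in c(1, 57, 216)) {
    r_t <- solve(tcrossprod(W), W %*% pair$val$B[t, ])
    expect_lt(max(abs(recon$R[t, ] - r_t)), 1e-10)
  }
  # zero validation data reconstructs to zero
  zero <- voxel_dataset(matrix(0, pair$design$n, 30), pair$design,
                        role = "validation")
  expect_equal(max(abs(invert_iem(fit, zero)$R)), 0)
})

test_that("zero-noise reconstruction reproduces the forward responses", {
  pair <- sim_pair(0, seed = 5, v = 50)
  b1 <- channel_basis(8)
  fit <- iem(pair$train, b1)
  recon <- invert_iem(fit, pair$val)
  fwd <- forward_channel_responses(pair$design, b1)
  expect_lt(max(abs(recon$R - fwd$R)), 1e-8)
})

test_that("shift-and-average aligns trials to the presented orientation", {
  pair <- sim_pair(0, seed = 6, v = 40)
  b1 <- channel_basis(8)
  crf <- shift_average(invert_iem(iem(pair$train, b1), pair$val))
  expect_equal(sort(crf$offsets), c(-90, -67.5, -45, -22.5, 0, 22.5, 45, 67.5))
  # zero noise: aligned mean equals the center channel profile at the offsets
  profile <- eval_basis(b1, crf$offsets)[, 1]
  expect_equal(unname(crf$mean), unname(profile), tolerance = 1e-6)
  expect_equal(crf$mean[crf$offsets == 0], 1, tolerance = 1e-6)
  # single trial: mean is the shifted vector, sem is zero
  one <- stimulus_design(c(45), repeats = 1)
  d1 <- voxel_dataset(matrix(pair$val$B[3, ], 1), one, role = "validation")
  fit <- iem(pair$train, b1)
  crf1 <- shift_average(invert_iem(fit, d1))
  expect_equal(crf1$sem, rep(0, 8))
  expect_equal(crf1$n_trials, 1L)
  # off-center orientations are rejected, not interpolated
  off <- stimulus_design(c(10), repeats = 1)
  doff <- voxel_dataset(matrix(0, 1, 40), off, role = "validation")
  expect_error(shift_average(invert_iem(fit, doff)), "center")
})

test_that("variance explained is pooled by default and ordered in noise", {
  pair <- sim_pair(0, seed = 7, v = 20)
  b1 <- channel_basis(8)
  fit <- iem(pair$train, b1)
  expect_equal(variance_explained(fit, pair$train), 1, tolerance = 1e-10)
  # per-voxel variant agrees at sigma = 0 and differs in general
  expect_equal(variance_explained(fit, pair$train, pooled = FALSE), 1,
               tolerance = 1e-10)
  # validation r2 is non-increasing as noise grows along the presets
  r2 <- vapply(noise_presets(), function(s) {
    p <- sim_pair(s, seed = 8, v = 20)
    variance_explained(iem(p$train, b1), p$val)
  }, numeric(1))
  expect_true(all(diff(r2) < 0))
})
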