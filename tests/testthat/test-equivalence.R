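test_that("identity transform gives zero discrepancy in every check", {
  pair <- sim_pair(0.01, seed = 1, v = 30)
  b1 <- channel_basis(8)
  trI <- channel_transform(diag(8))
  fit1 <- iem(pair$train, b1)
  fit2 <- iem(pair$train, transform_basis(b1, trI))
  expect_lt(check_weight_identity(fit1, fit2, trI)$discrepancy, 1e-12)
  r1 <- invert_iem(fit1, pair$val); r2 <- invert_iem(fit2, pair$val)
  expect_lt(check_reconstruction_identity(r1, r2, trI)$discrepancy, 1e-12)
  lo <- stimulus_design(c(10), repeats = 1)
  expect_lt(check_leftout_prediction(fit1, fit2, lo)$discrepancy, 1e-12)
})

test_that("weight, reconstruction and prediction identities hold for real transforms", {
  b1 <- channel_basis(8)
  lo <- stimulus_design(c(10, 50, 125), repeats = 1)
  for (kind in c("bimodal", "random")) {
    for (sigma in c(0, 0.008, 0.032)) {
      pair <- sim_pair(sigma, seed = 2, v = 40)
      tr <- if (kind == "bimodal") bimodal_transform(8)
            else random_transform(8, seed = 2)
      fit1 <- iem(pair$train, b1)
      fit2 <- iem(pair$train, transform_basis(b1, tr))
      expect_lt(check_weight_identity(fit1, fit2, tr)$discrepancy, 1e-8)
      expect_lt(check_reconstruction_identity(invert_iem(fit1, pair$val),
                                              invert_iem(fit2, pair$val),
                                              tr)$discrepancy, 1e-8)
      expect_lt(check_leftout_prediction(fit1, fit2, lo)$discrepancy, 1e-8)
      expect_lt(check_variance_equality(fit1, fit2, pair$val)$discrepancy,
                1e-10)
    }
  }
})

test_that("left-out designs overlapping the training set are rejected", {
  pair <- sim_pair(0.01, seed = 3, v = 10)
  b1 <- channel_basis(8)
  tr <- bimodal_transform(8)
  fit1 <- iem(pair$train, b1)
  fit2 <- iem(pair$train, transform_basis(b1, tr))
  expect_error(
    check_leftout_prediction(fit1, fit2, stimulus_design(c(45), repeats = 1)),
    "training")
})

test_that("inverse-mapped transformed reconstructions equal the unimodal CRF", {
  b1 <- channel_basis(8)
  for (sigma in c(0, 0.008)) {
    pair <- sim_pair(sigma, seed = 4, v = 40)
    fit1 <- iem(pair$train, b1)
    crf1 <- shift_average(invert_iem(fit1, pair$val))
    for (tr in list(bimodal_transform(8), random_transform(8, seed = 4))) {
      fit2 <- iem(pair$train, transform_basis(b1, tr))
      recon2 <- invert_iem(fit2, pair$val)
      back <- recon2
      back$R <- recon2$R %*% tr$Pinv
      back$basis <- b1
      crf_back <- shift_average(back)
      expect_lt(max(abs(crf_back$mean - crf1$mean)), 1e-8)
    }
  }
})

test_that("the equivalence suite aggregates checks and surfaces bad transforms", {
  cfg <- equivalence_config(seeds = 1, sigmas = c(zero = 0, mid = 0.01),
                            v = 25, m = 60, repeats = 5)
  suite <- run_equivalence_suite(cfg)
  expect_length(suite, 2 * 2 * 4)          # 2 transforms x 2 sigmas x 4 checks
  expect_true(attr(suite, "all_pass"))
  df <- as.data.frame(suite)
  expect_true(all(df$pass))
  # an injected singular construction is reported as a failure, not a pass
  bad <- equivalence_config(seeds = 1, sigmas = c(zero = 0),
                            transforms = list(
                              bad = list(kind = "bimodal", lobe_shift = 4,
                                         secondary_gain = 1)),
                            v = 10, m = 30, repeats = 2)
  suite_bad <- run_equivalence_suite(bad)
  expect_false(attr(suite_bad, "all_pass"))
  expect_match(suite_bad[[1]]$identity, "construction")
  # an empty configuration yields an empty report list
  empty <- equivalence_config(seeds = integer(0))
  expect_length(run_equivalence_suite(empty), 0L)
})
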