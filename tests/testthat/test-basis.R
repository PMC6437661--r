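test_that("unimodal basis functions peak at their centers and rectify", {
  b <- channel_basis(8)
  expect_equal(b$p, 7L)
  expect_equal(b$centers, (0:7) * 22.5)
  C <- unname(eval_basis(b, c(0, 45, 22.5)))
  expect_equal(C[1, 1], 1)                      # maximum at own center
  expect_equal(C[2, 1], 0)                      # cos(90 deg) rectified to 0
  expect_equal(C[3, 1], cos(pi / 4)^7, tolerance = 1e-12)  # ~0.0884
  # values in [0, 1], nonnegative everywhere
  grid <- seq(0, 179.5, by = 0.5)
  Cg <- eval_basis(b, grid)
  expect_true(all(Cg >= 0 & Cg <= 1))
  # each channel attains its maximum 1 exactly at its center
  expect_equal(unname(diag(eval_basis(b, b$centers))), rep(1, 8))
})

test_that("basis evaluation is 180-degree periodic and rejects bad input", {
  b <- channel_basis(8)
  theta <- c(3.7, 60, 150.2)
  expect_equal(eval_basis(b, theta), eval_basis(b, theta + 180))
  expect_error(eval_basis(b, numeric(0)), "no stimulus")
  expect_error(channel_basis(1), "k")
  expect_error(channel_basis(8, 0), "p")
})

test_that("default basis at the 8 center orientations is full-rank circulant", {
  b <- channel_basis(8)
  C <- eval_basis(b, (0:7) * 22.5)
  expect_equal(qr(C)$rank, 8L)
  # circulant: every row is the cyclic shift of the first
  for (i in 2:8)
    expect_equal(unname(C[i, ]), unname(C[1, ((0:7 - (i - 1)) %% 8) + 1]))
})

test_that("bimodal transform has the predicted circulant spectrum", {
  tr <- bimodal_transform(8, 3, 0.9)
  ev <- eigen(tr$P, only.values = TRUE)$values
  expect_equal(sort(Mod(ev)), sort(Mod(1 + 0.9 * exp(2i * pi * 3 * (0:7) / 8))),
               tolerance = 1e-12)
  expect_equal(min(Mod(ev)), 0.1, tolerance = 1e-10)
  expect_equal(tr$cond, 19, tolerance = 1e-6)
  expect_error(bimodal_transform(8, 3, 1.0), "singular")
  expect_error(bimodal_transform(8, 8), "lobe_shift")
})

test_that("bimodal channels have two lobes 67.5 degrees apart", {
  b2 <- transform_basis(channel_basis(8), bimodal_transform(8, 3, 0.9))
  grid <- seq(0, 179.5, by = 0.5)
  f <- eval_basis(b2, grid)[, 1]                 # center-0 channel
  curve <- circular_curve(wrap_offsets <- ((grid + 90) %% 180) - 90, f)
  idx <- local_maxima(curve)
  expect_length(idx, 2L)
  peaks <- sort(curve$offsets[idx])
  expect_equal(peaks, c(0, 67.5))
  expect_equal(peak_separation(curve), 67.5)
})

test_that("random transforms are seeded, well conditioned, and invert", {
  t1 <- random_transform(8, seed = 7)
  t2 <- random_transform(8, seed = 7)
  expect_identical(t1$P, t2$P)
  expect_lt(t1$cond, 1e3)
  expect_lt(max(abs(t1$P %*% t1$Pinv - diag(8))), 1e-10)
  # round-trip through the transform restores any vector
  x <- sin(1:8)
  expect_equal(drop(x %*% t1$P %*% t1$Pinv), x, tolerance = 1e-10)
})

test_that("transform_basis satisfies C2 = C1 P and composes with inverses", {
  b1 <- channel_basis(8)
  tr <- bimodal_transform(8)
  b2 <- transform_basis(b1, tr)
  grid <- seq(0, 179, by = 1)
  C1 <- eval_basis(b1, grid)
  expect_lt(max(abs(C1 %*% tr$P - eval_basis(b2, grid))), 1e-12)
  # identity transform leaves evaluations unchanged
  bid <- transform_basis(b1, channel_transform(diag(8)))
  expect_equal(eval_basis(bid, grid), C1)
  # applying P then P^{-1} restores the unimodal evaluations
  binv <- transform_basis(b1, channel_transform(tr$P %*% tr$Pinv))
  expect_lt(max(abs(eval_basis(binv, grid) - C1)), 1e-10)
  # span is preserved: [C1 | C2] has the same rank as C1
  Cc <- eval_basis(b1, (0:7) * 22.5)
  expect_equal(qr(cbind(Cc, Cc %*% tr$P))$rank, qr(Cc)$rank)
  expect_error(transform_basis(b2, tr), "unimodal")
  expect_error(transform_basis(channel_basis(6), tr), "dimension")
})

test_that("stimulus designs are one-hot with sorted distinct orientations", {
  d <- stimulus_design()
  expect_equal(d$n, 216L)
  expect_equal(rowSums(d$S), rep(1, 216))
  expect_true(all(d$S %in% c(0, 1)))
  expect_equal(d$n, d$s * d$repeats)
  expect_error(stimulus_design(c(0, 0, 45)), "distinct")
  expect_error(stimulus_design(c(0, 190)), "180")
})
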