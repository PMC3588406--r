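# Frequency-designed pyramid: filter contract, perfect reconstruction,
# tight-frame normalization.

test_that("filter pair satisfies the power-complementarity contract", {
  fp <- design_pyramid_filters(c(64, 64))
  expect_equal(fp$low[1, 1], 1)                 # DC
  expect_equal(fp$high[1, 1], 0)
  ny <- c(33, 33)                               # (pi, pi)
  expect_equal(fp$low[ny[1], ny[2]], 0)
  expect_equal(fp$high[ny[1], ny[2]], 1)
  expect_lt(max(abs(fp$low^2 + fp$high^2 - 1)), 1e-12)
  expect_true(all(fp$low >= 0))
  expect_error(design_pyramid_filters(c(32, 32), omega_s = 0.6 * pi), "aliasing")
  expect_error(design_pyramid_filters(c(32, 32), omega_p = 0.5, omega_s = 0.3),
               "omega_p < omega_s")
})

test_that("constant images live entirely in the approximation", {
  x <- matrix(0.7, 64, 64)
  d <- pyramid_decompose(x, 3)
  expect_equal(max(abs(d$lowpass - 0.7 * 2^3)), 0, tolerance = 1e-10)
  for (b in d$bandpass) expect_lt(max(abs(b)), 1e-10)
})

test_that("decompose/reconstruct is the identity and conserves energy", {
  set.seed(11)
  x <- rand_gray(64)
  d <- pyramid_decompose(x, 3)
  expect_lt(max_abs(pyramid_reconstruct(d$lowpass, d$bandpass), x), 1e-10)
  e_coeff <- sum(d$lowpass^2) + sum(vapply(d$bandpass, function(b) sum(b^2), 0))
  expect_equal(e_coeff, sum(x^2), tolerance = 1e-10)
  # impulse input: same Parseval identity (tight frame)
  imp <- matrix(0, 64, 64); imp[17, 41] <- 1
  di <- pyramid_decompose(imp, 3)
  ei <- sum(di$lowpass^2) + sum(vapply(di$bandpass, function(b) sum(b^2), 0))
  expect_equal(ei, 1, tolerance = 1e-10)
})

test_that("impulse energy concentrates in the designed frequency annuli", {
  imp <- matrix(0, 64, 64); imp[33, 33] <- 1
  cfg <- sflct_config(levels = 1, dirs_per_level = 16)
  d <- pyramid_decompose(imp, 1, cfg)
  # direct FFT-domain evaluation of the analysis branch as oracle
  fp <- design_pyramid_filters(c(64, 64), cfg$omega_p, cfg$omega_s)
  X <- stats::fft(imp)
  hp_oracle <- Re(stats::fft(X * fp$high, inverse = TRUE)) / 64^2
  expect_lt(max_abs(d$bandpass[[1]], hp_oracle), 1e-12)
})

test_that("non-divisible dimensions give an instructive error", {
  expect_error(pyramid_decompose(matrix(0.1, 60, 60), 3), "divisible.*pad",
               ignore.case = TRUE)
})

test_that("shifting the input by the decimation step shifts the approximation by one sample", {
  set.seed(3)
  imp <- matrix(0, 32, 32); imp[9, 13] <- 1
  cfg <- sflct_config(levels = 1, dirs_per_level = 2)
  a1 <- pyramid_decompose(imp, 1, cfg)$lowpass
  imp2 <- matrix(0, 32, 32); imp2[11, 15] <- 1   # shifted by M = diag(2,2)
  a2 <- pyramid_decompose(imp2, 1, cfg)$lowpass
  expect_lt(max_abs(a2, a1[c(16, 1:15), c(16, 1:15)]), 1e-12)
})
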