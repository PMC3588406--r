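# Composite multiscale directional transform.

test_that("default configuration reproduces the reference parameters", {
  cfg <- sflct_config()
  expect_identical(cfg$levels, 4L)
  expect_identical(cfg$dirs_per_level, c(4L, 8L, 16L, 16L))
  expect_equal(cfg$omega_p, 4 * pi / 21)
  expect_equal(cfg$omega_s, 10 * pi / 21)
  expect_identical(cfg$dfb_filter, "pkva")
  expect_error(sflct_config(levels = 2), "one entry per level")
  expect_error(sflct_config(dirs_per_level = c(3, 8, 16, 16)), "power of two")
  expect_error(sflct_config(omega_s = 2), "aliasing")
})

test_that("decompose/reconstruct is the identity on random images", {
  set.seed(21)
  x <- rand_gray(64)
  cfg <- sflct_config(levels = 3, dirs_per_level = c(4L, 8L, 8L))
  co <- sflct_decompose(x, cfg)
  expect_lt(max_abs(sflct_reconstruct(co), x), 1e-6)
  expect_identical(dim(co$approx), as.integer(dim(x) / 2^3))
  # finest level gets the last (largest) direction count
  expect_length(co$details[[1]], 8L)
  expect_length(co$details[[3]], 4L)
})

test_that("zero image gives all-zero subbands and the transform is linear", {
  cfg <- sflct_config(levels = 2, dirs_per_level = c(4L, 8L))
  z <- sflct_decompose(matrix(0, 32, 32), cfg)
  expect_equal(max(abs(z$approx)), 0)
  for (lvl in z$details) for (s in lvl) expect_equal(max(abs(s)), 0)

  set.seed(31)
  x <- rand_gray(32); y <- rand_gray(32)
  cl <- sflct_decompose(2 * x - 0.5 * y, cfg)
  cx <- sflct_decompose(x, cfg); cy <- sflct_decompose(y, cfg)
  expect_lt(max_abs(cl$approx, 2 * cx$approx - 0.5 * cy$approx), 1e-9)
  for (j in 1:2) for (l in seq_along(cl$details[[j]]))
    expect_lt(max_abs(cl$details[[j]][[l]],
                      2 * cx$details[[j]][[l]] - 0.5 * cy$details[[j]][[l]]), 1e-9)
})

test_that("coefficient bookkeeping matches the documented redundancy", {
  set.seed(41)
  x <- rand_gray(64)
  cfg <- sflct_config(levels = 3, dirs_per_level = c(4L, 8L, 8L))
  red <- sflct_redundancy(sflct_decompose(x, cfg))
  expect_equal(red$redundancy, sum(4^-(0:2)) + 4^-3)
  expect_equal(red$n_pixels, 64 * 64)
})

test_that("non-divisible images are padded and cropped transparently", {
  set.seed(51)
  x <- rand_gray(60, 52)
  cfg <- sflct_config(levels = 2, dirs_per_level = c(4L, 4L))
  co <- sflct_decompose(x, cfg)
  xr <- sflct_reconstruct(co)
  expect_identical(dim(xr), dim(x))
  expect_lt(max_abs(xr, x), 1e-6)
})

test_that("energy is conserved through the full transform", {
  set.seed(61)
  x <- rand_gray(64)
  co <- sflct_decompose(x, sflct_config(levels = 2, dirs_per_level = c(4L, 16L)))
  e <- sum(co$approx^2) +
    sum(vapply(co$details, function(lvl) sum(vapply(lvl, function(s) sum(s^2), 0)), 0))
  expect_equal(e, sum(x^2), tolerance = 1e-10)
})
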