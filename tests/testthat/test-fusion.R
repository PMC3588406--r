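# Fusion rules against hand-worked values and brute-force oracles, plus
# end-to-end pipeline properties.

test_that("region energy matches hand evaluation and a per-pixel oracle", {
  expect_equal(region_energy(matrix(5, 6, 6), 3), matrix(0, 6, 6))
  p <- matrix(c(0, 0, 0, 0, 9, 0, 0, 0, 0), 3, 3)
  expect_equal(region_energy(p, 3)[2, 2], 72)    # mu = 1: 8*1 + 64
  set.seed(71)
  for (i in 1:5) {
    x <- matrix(rnorm(64), 8, 8)
    expect_equal(region_energy(x, 3), oracle_region_energy(x, 3), tolerance = 0)
  }
})

test_that("MRE selects by window energy with ties to B", {
  set.seed(72)
  cA <- matrix(0.3, 8, 8)                       # constant: zero energy
  cB <- matrix(rnorm(64), 8, 8)
  expect_equal(fuse_approx_mre(cA, cB, 3), cB)
  expect_equal(fuse_approx_mre(cB, cB, 3), cB)  # ties everywhere -> B branch
})

test_that("MAV picks the larger magnitude with ties to A", {
  dA <- matrix(c(3, 1, -2, 0), 2, 2)
  dB <- matrix(c(-5, 1, 1, 0), 2, 2)
  expect_equal(fuse_detail_mav(dA, dB), matrix(c(-5, 1, -2, 0), 2, 2))
  expect_equal(fuse_detail_mav(dA, dA), dA)
})

test_that("NCM map reproduces hand-worked neighborhoods and its bounds", {
  nhd <- neighborhood_class("NhdI", cbind(0L, c(0L, 1L)))
  # neighborhood values dA = (1,2), dB = (2,4): Psi = 2*10/(5+20) = 0.8
  dA <- matrix(c(1, 2), 1, 2); dB <- matrix(c(2, 4), 1, 2)
  psi <- ncm_map(dA, dB, nhd)
  expect_equal(psi[1, 1], 0.8)
  # identical non-zero neighborhoods -> exactly 1; negated -> exactly -1
  set.seed(73)
  d <- matrix(rnorm(36), 6, 6)
  nhd5 <- neighborhood_for_subband(8, 0)
  expect_equal(ncm_map(d, d, nhd5), matrix(1, 6, 6))
  expect_equal(ncm_map(d, -d, nhd5), matrix(-1, 6, 6))
  # both neighborhoods zero -> convention Psi = 1
  z <- matrix(0, 4, 4)
  expect_equal(ncm_map(z, z, nhd5), matrix(1, 4, 4))
})

test_that("NCM fusion follows the threshold switch", {
  nhd <- neighborhood_class("NhdI", cbind(0L, c(0L, 1L)))
  dA <- matrix(c(1, 2), 1, 2); dB <- matrix(c(2, 4), 1, 2)
  out <- fuse_detail_ncm(dA, dB, T = 0.75, nhd)
  expect_equal(out[1, 1], 0.8 * 2 + 0.2 * 1)    # Psi = 0.8 >= T: blend
  set.seed(74)
  d <- matrix(rnorm(25), 5, 5)
  nhd5 <- neighborhood_for_subband(8, 0)
  expect_equal(fuse_detail_ncm(d, d, 0.75, nhd5), d)       # self-fusion
  expect_equal(fuse_detail_ncm(d, -d, 0.75, nhd5), d)      # Psi = -1 < T, tie -> A
})

test_that("windowed rules match the brute-force oracles on random subband pairs", {
  set.seed(75)
  nhdI <- neighborhood_for_subband(8, 0)
  nhdII <- neighborhood_for_subband(8, 2)
  for (i in 1:20) {
    dA <- matrix(rnorm(64), 8, 8)
    dB <- matrix(rnorm(64), 8, 8)
    expect_equal(fuse_approx_mre(dA, dB, 3), oracle_mre(dA, dB, 3), tolerance = 0)
    expect_equal(fuse_detail_mav(dA, dB), oracle_mav(dA, dB), tolerance = 0)
    nhd <- if (i %% 2) nhdI else nhdII
    expect_equal(ncm_map(dA, dB, nhd), oracle_ncm_map(dA, dB, nhd), tolerance = 0)
    expect_equal(fuse_detail_ncm(dA, dB, 0.75, nhd),
                 oracle_ncm_fuse(dA, dB, 0.75, nhd), tolerance = 0)
  }
})

test_that("NCM blending stays between the coefficient envelope when Psi is in [T, 1]", {
  set.seed(76)
  nhd <- neighborhood_for_subband(8, 2)
  for (i in 1:10) {
    dA <- matrix(rnorm(49), 7, 7)
    dB <- dA + matrix(rnorm(49, sd = 0.2), 7, 7)   # correlated pair
    psi <- ncm_map(dA, dB, nhd)
    out <- fuse_detail_ncm(dA, dB, 0.75, nhd)
    sel <- psi >= 0.75 & psi <= 1
    expect_true(all(out[sel] >= pmin(dA, dB)[sel] - 1e-12))
    expect_true(all(out[sel] <= pmax(dA, dB)[sel] + 1e-12))
    expect_true(all(psi <= 1 + 1e-12))
  }
})

test_that("the neighborhood map is total and matches the stated orientation rule", {
  for (n in c(2, 4, 8, 16)) for (l in 0:(n - 1)) {
    nhd <- neighborhood_for_subband(n, l)
    expect_s3_class(nhd, "neighborhood_class")
    expect_true(any(nhd$offsets[, 1] == 0 & nhd$offsets[, 2] == 0))
    expect_lte(max(abs(nhd$offsets)), 2)
  }
  expect_identical(neighborhood_for_subband(4, 0)$id, "NhdI")  # horizontal
  expect_identical(neighborhood_for_subband(4, 1)$id, "NhdII") # diagonal
  expect_identical(neighborhood_for_subband(4, 2)$id, "NhdI")  # vertical
  expect_identical(neighborhood_for_subband(4, 3)$id, "NhdII")
  # NhdI arms align with the subband orientation
  expect_true(all(neighborhood_for_subband(8, 0)$offsets[, 1] == 0))
  expect_true(all(neighborhood_for_subband(8, 4)$offsets[, 2] == 0))
})

make_small_pair <- function(seed = 81) {
  make_pair(scene_spec(size = c(64, 64), n_cells = 3, seed = seed))
}
small_cfg <- function() fusion_config(sflct = sflct_config(levels = 2,
                                                           dirs_per_level = c(4L, 8L)))

test_that("fusing an image with its own intensity returns the image", {
  pair <- make_small_pair()
  i_a <- rgb_to_ihs(pair$gfp)$i
  out <- fuse_images(pair$gfp, i_a, small_cfg())
  expect_lt(rgb_max_abs(out, pair$gfp), 1e-5)
  out2 <- fuse_ihs_mre_mav(pair$gfp, i_a, small_cfg())
  expect_lt(rgb_max_abs(out2, pair$gfp), 1e-5)
  out3 <- fuse_t_ihs(pair$gfp, i_a)
  expect_lt(rgb_max_abs(out3, pair$gfp), 1e-9)
})

test_that("a saturation-free input stays grayscale through every pipeline", {
  set.seed(82)
  v <- rand_gray(32)
  gfp <- rgb_image(v, v, v)                      # S = 0 everywhere
  phase <- rand_gray(32)
  cfg <- fusion_config(sflct = sflct_config(levels = 1, dirs_per_level = 4L))
  for (f in list(fuse_images(gfp, phase, cfg), fuse_t_ihs(gfp, phase))) {
    expect_lt(max(abs(f$r - f$g)), 1e-9)
    expect_lt(max(abs(f$b - f$g)), 1e-9)
  }
  expect_lt(max_abs(fuse_t_ihs(gfp, phase)$g, phase), 1e-9)
})

test_that("pipelines are deterministic and genuinely different from each other", {
  pair <- make_small_pair(83)
  cfg <- small_cfg()
  h1 <- fuse_images(pair$gfp, pair$phase, cfg)
  h2 <- fuse_images(pair$gfp, pair$phase, cfg)
  expect_identical(h1$g, h2$g)
  ti <- fuse_t_ihs(pair$gfp, pair$phase)
  mm <- fuse_ihs_mre_mav(pair$gfp, pair$phase, cfg)
  expect_gt(rgb_max_abs(h1, ti), 1e-3)
  expect_gt(rgb_max_abs(h1, mm), 1e-6)
})

test_that("the MRE+MAV baseline equals the manual per-subband composition", {
  pair <- make_small_pair(84)
  cfg <- small_cfg()
  ihs <- rgb_to_ihs(pair$gfp)
  cA <- sflct_decompose(ihs$i, cfg$sflct)
  cB <- sflct_decompose(pair$phase, cfg$sflct)
  fused <- cA
  fused$approx <- fuse_approx_mre(cA$approx, cB$approx, cfg$mre_window)
  for (j in seq_along(cA$details)) for (l in seq_along(cA$details[[j]]))
    fused$details[[j]][[l]] <- fuse_detail_mav(cA$details[[j]][[l]],
                                               cB$details[[j]][[l]])
  i_f <- pmin(pmax(sflct_reconstruct(fused), 0), 1)
  manual <- ihs_to_rgb(ihs_image(i_f, ihs$h, ihs$s))
  expect_lt(rgb_max_abs(fuse_ihs_mre_mav(pair$gfp, pair$phase, cfg), manual), 1e-12)
})

test_that("dimension mismatches are rejected", {
  pair <- make_small_pair()
  expect_error(fuse_images(pair$gfp, rand_gray(32), small_cfg()), "registered")
  expect_error(fusion_config(threshold_T = 0.4), "0.5")
  expect_error(fusion_config(mre_window = 4), "odd")
})
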