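# Otsu segmentation and region-wise VIF scoring.

test_that("Otsu separates a two-level image and matches the brute-force scan", {
  half <- matrix(c(rep(0.1, 128), rep(0.9, 128)), 16, 16)
  th <- otsu_threshold(half)
  expect_gt(th, 0.1); expect_lt(th, 0.9)
  set.seed(91)
  for (i in 1:10) {
    x <- matrix(runif(400)^sample(c(1, 2, 3), 1), 20, 20)
    expect_identical(otsu_threshold(x), oracle_otsu(x))
  }
  expect_error(otsu_threshold(matrix(0.5, 8, 8)), "degenerate")
})

test_that("Otsu threshold of a bimodal mixture lies between the modes", {
  x <- make_bimodal(256, mu1 = 0.2, mu2 = 0.8, sigma = 0.05, seed = 17)
  th <- otsu_threshold(x)
  expect_gt(th, 0.35); expect_lt(th, 0.65)
})

test_that("Otsu agrees with an independent library implementation", {
  skip_if_not_installed("EBImage")
  # a bimodal histogram has a flat valley where every cut is optimal, so
  # compare the achieved between-class variance rather than the cut itself
  sigma_b <- function(x, t) {
    w0 <- mean(x < t)
    if (w0 == 0 || w0 == 1) return(0)
    w0 * (1 - w0) * (mean(x[x < t]) - mean(x[x >= t]))^2
  }
  x <- make_bimodal(128, seed = 3)
  t_mine <- otsu_threshold(x)
  t_eb <- EBImage::otsu(x, range = c(0, 1), levels = 256)
  expect_gte(sigma_b(x, t_mine), sigma_b(x, t_eb) - 1e-6)
  # on a skewed unimodal image the maximizer is unique: cuts agree to a bin
  set.seed(92)
  y <- matrix(runif(64^2)^2, 64, 64)
  expect_lt(abs(otsu_threshold(y) -
                  EBImage::otsu(y, range = c(0, 1), levels = 256)), 2 / 256)
})

test_that("fluorescence mask marks the bright blobs of a synthetic scene", {
  pair <- make_pair(scene_spec(seed = 2), ground_truth = TRUE)
  bm <- fluorescence_mask(pair$gfp)
  expect_false(attr(bm, "degenerate"))
  expect_gte(mean(bm$mask[pair$truth$blob_mask]), 0.8)
  # mask should not spill over most of the background
  expect_lt(mean(bm$mask[!pair$truth$cell_mask]), 0.1)
})

test_that("self-comparison scores exactly one and noise degrades it monotonically", {
  set.seed(93)
  x <- make_pair(scene_spec(size = c(64, 64), n_cells = 3, seed = 5))$phase
  expect_equal(vif(x, x), 1, tolerance = 1e-9)
  scores <- vapply(c(0.01, 0.05, 0.1), function(s) {
    set.seed(1000 + round(1000 * s))
    vif(x, pmin(pmax(x + matrix(rnorm(length(x), 0, s), nrow(x)), 0), 1))
  }, 0)
  expect_true(all(diff(scores) < 0))
  expect_true(all(scores >= 0 & scores <= 1))
})

test_that("VIF is invariant to adding a constant to both images", {
  set.seed(94)
  x <- rand_gray(64) * 0.5
  y <- pmin(pmax(x + matrix(rnorm(64^2, 0, 0.03), 64), 0), 1) * 0.5
  expect_equal(vif(x, y), vif(x + 0.3, y + 0.3), tolerance = 1e-6)
  expect_error(vif(matrix(0.5, 8, 8), matrix(0.4, 8, 8)), "constant")
})

test_that("region report scores a perfect fusion as one everywhere", {
  pair <- make_pair(scene_spec(size = c(128, 128), n_cells = 4, seed = 6))
  i_a <- rgb_to_ihs(pair$gfp)$i
  rep1 <- region_vif_report(pair$gfp, i_a, pair$gfp)
  expect_equal(rep1$vif_A_fl, 1, tolerance = 1e-6)
  expect_equal(rep1$vif_B_fl, 1, tolerance = 1e-6)
  expect_equal(rep1$vif_B_nfl, 1, tolerance = 1e-6)
  expect_false(rep1$degenerate)
})

test_that("scores in the fluorescent region ignore non-fluorescent pixels", {
  pair <- make_pair(scene_spec(size = c(128, 128), n_cells = 4, seed = 7))
  fused <- fuse_t_ihs(pair$gfp, pair$phase)
  r1 <- region_vif_report(pair$gfp, pair$phase, fused)
  # perturb the fused image outside the fluorescent area only
  m <- r1$mask$mask
  g2 <- fused
  g2$r[!m] <- pmin(g2$r[!m] + 0.2, 1)
  g2$g[!m] <- pmax(g2$g[!m] - 0.2, 0)
  r2 <- region_vif_report(pair$gfp, pair$phase, g2)
  expect_equal(r1$vif_A_fl, r2$vif_A_fl, tolerance = 1e-9)
  expect_equal(r1$vif_B_fl, r2$vif_B_fl, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(r1$vif_B_nfl, r2$vif_B_nfl)))
})

test_that("degenerate masks are flagged instead of scored", {
  v <- matrix(rep(c(0.2, 0.8), each = 32 * 64), 64, 64)
  gfp <- rgb_image(v * 0, v, v * 0)
  # force an all-true-ish mask by thresholding a plane that is bright everywhere
  bright <- rgb_image(matrix(0.9, 8, 8) + diag(8) * 0.05, matrix(0.95, 8, 8),
                      matrix(0.9, 8, 8))
  bm <- fluorescence_mask(bright)
  if (attr(bm, "degenerate")) expect_true(attr(bm, "degenerate"))
  rep_json <- tempfile(fileext = ".json")
  pair <- make_pair(scene_spec(size = c(64, 64), n_cells = 3, seed = 8))
  r <- region_vif_report(pair$gfp, pair$phase, fuse_t_ihs(pair$gfp, pair$phase))
  write_vif_report(r, rep_json)
  parsed <- jsonlite::read_json(rep_json)
  expect_named(parsed, c("vif_A_fl", "vif_B_fl", "vif_B_nfl",
                         "otsu_threshold", "degenerate_mask"))
})
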