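# Seeded generator of registered GFP-like / phase-contrast-like image
# pairs, plus small analytic patterns used throughout the test suite.
#
# The generator emulates the statistical character of fluorescence /
# phase-contrast micrograph pairs rather than their optics:
#   * GFP modality: near-black background with green-tinted chromatic
#     noise (dark pixels keep a noticeable, noisy saturation), faint smooth
#     autofluorescent cell bodies, bright green Gaussian blobs at the
#     fluorescent cells with a wide out-of-focus halo, and a gentle
#     darkening vignette.  Coarse-scale structure therefore lives in the
#     GFP modality.
#   * Phase modality: brighter grayscale rendering of the same geometry
#     with suppressed low frequencies (shade-off): mid-gray background,
#     dark boundary rings with bright outer halos at cell edges, strong
#     band-limited intracellular texture, and sensor noise.
# Both modalities are driven by one sampled cell geometry, so the pair is
# registered by construction, and ground truth can be returned alongside.

#' Scene specification for the synthetic generator
#'
#' @param size Integer vector `(rows, cols)`, default `c(256, 256)`.
#' @param n_cells Number of elliptical cells (default 8).
#' @param fluorescent_fraction Fraction of cells carrying a bright
#'   fluorescent blob (default 0.5).
#' @param background GFP background intensity level (default 0.05).
#' @param noise_sigma Additive noise scale for both modalities
#'   (default 0.01); channel noise is truncated at three sigma.
#' @param texture_freq Spatial frequency (cycles/pixel) of the
#'   phase-contrast intracellular texture (default 0.25).
#' @param phase_level Mean phase-contrast background gray (default 0.6).
#' @param autofluorescence Amplitude of the faint smooth cell-body glow in
#'   the GFP channel present for every cell (default 0.08); set to 0 for a
#'   pure blobs-on-background fluorescence image.
#' @param seed RNG seed (default 1).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(size = c(256L, 256L), n_cells = 8L,
                       fluorescent_fraction = 0.5, background = 0.05,
                       noise_sigma = 0.01, texture_freq = 0.25,
                       phase_level = 0.6, autofluorescence = 0.08,
                       seed = 1L) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 32L))
    stop_sflct("size must be (rows, cols), each >= 32")
  if (n_cells < 1L) stop_sflct("n_cells must be >= 1")
  if (fluorescent_fraction < 0 || fluorescent_fraction > 1)
    stop_sflct("fluorescent_fraction must be in [0, 1]")
  stopifnot(background >= 0, background < 0.5, noise_sigma >= 0,
            texture_freq > 0, texture_freq <= 0.5, autofluorescence >= 0)
  structure(list(size = size, n_cells = as.integer(n_cells),
                 fluorescent_fraction = fluorescent_fraction,
                 background = background, noise_sigma = noise_sigma,
                 texture_freq = texture_freq, phase_level = phase_level,
                 autofluorescence = autofluorescence,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# run code with a private, restored RNG state (Mersenne-Twister)
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# band-limited noise texture centered on frequency f (cycles/pixel)
.texture_field <- function(nr, nc, f) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  u <- abs(signed_freq(nr)) / nr
  v <- abs(signed_freq(nc)) / nc
  rad <- sqrt(outer(u^2, v^2, `+`))
  bp <- exp(-((rad - f) / (0.35 * f))^2)
  t <- ifft2_real(fft2(z) * bp, "texture")
  t / max(stats::sd(t), 1e-12)
}

#' Generate a registered synthetic GFP / phase-contrast pair
#'
#' Deterministic given `spec$seed`; two calls with the same spec return
#' bit-identical images.  With `ground_truth = TRUE` the cell geometry and
#' per-cell blob masks are returned alongside.
#'
#' @param spec A [scene_spec].
#' @param ground_truth Also return the generating geometry.
#' @return A list with `gfp` (an [rgb_image]) and `phase` (matrix); with
#'   `ground_truth = TRUE` also `truth`: a list with `cells` (data frame of
#'   ellipse parameters incl. `fluorescent`), `cell_mask` and `blob_mask`
#'   (logical matrices).
#' @export
make_pair <- function(spec = scene_spec(), ground_truth = FALSE) {
  if (!inherits(spec, "scene_spec")) stop_sflct("spec must be a scene_spec")
  .with_seed(spec$seed, {
    nr <- spec$size[1]; nc <- spec$size[2]
    yy <- matrix(rep(seq_len(nr), nc), nr, nc)
    xx <- matrix(rep(seq_len(nc), each = nr), nr, nc)

    # --- shared cell geometry -------------------------------------------
    n <- spec$n_cells
    cells <- data.frame(
      cy = stats::runif(n, 0.15 * nr, 0.85 * nr),
      cx = stats::runif(n, 0.15 * nc, 0.85 * nc),
      a  = stats::runif(n, 0.07, 0.14) * min(nr, nc),   # semi-axes, px
      b  = stats::runif(n, 0.05, 0.10) * min(nr, nc),
      th = stats::runif(n, 0, pi))
    nf <- round(spec$fluorescent_fraction * n)
    cells$fluorescent <- seq_len(n) %in% sample.int(n, nf)

    cell_mask <- matrix(FALSE, nr, nc)
    edge_dist <- matrix(Inf, nr, nc)     # |r(x)-1| in normalized ellipse radius
    for (i in seq_len(n)) {
      dy <- yy - cells$cy[i]; dx <- xx - cells$cx[i]
      u <- cos(cells$th[i]) * dx + sin(cells$th[i]) * dy
      v <- -sin(cells$th[i]) * dx + cos(cells$th[i]) * dy
      r <- sqrt((u / cells$a[i])^2 + (v / cells$b[i])^2)
      cell_mask <- cell_mask | (r <= 1)
      edge_dist <- pmin(edge_dist, abs(r - 1) * (cells$a[i] + cells$b[i]) / 2)
    }

    # --- phase-contrast modality ----------------------------------------
    ring_dark <- 0.22 * exp(-(edge_dist / 2.2)^2)
    halo <- 0.12 * exp(-((edge_dist - 4.5) / 2.5)^2)
    tex_in <- .texture_field(nr, nc, spec$texture_freq)
    tex_bg <- .texture_field(nr, nc, spec$texture_freq / 2)
    phase <- spec$phase_level - ring_dark + halo +
      0.12 * tex_in * cell_mask + 0.03 * tex_bg +
      pmin(pmax(stats::rnorm(nr * nc, 0, spec$noise_sigma),
                -3 * spec$noise_sigma), 3 * spec$noise_sigma)
    phase <- pmin(pmax(phase, 0), 1)

    # --- GFP modality ----------------------------------------------------
    blob <- matrix(0, nr, nc)
    halo_g <- matrix(0, nr, nc)
    blob_mask <- matrix(FALSE, nr, nc)
    for (i in which(cells$fluorescent)) {
      dy <- yy - cells$cy[i]; dx <- xx - cells$cx[i]
      u <- cos(cells$th[i]) * dx + sin(cells$th[i]) * dy
      v <- -sin(cells$th[i]) * dx + cos(cells$th[i]) * dy
      s2 <- ((u / (0.55 * cells$a[i]))^2 + (v / (0.55 * cells$b[i]))^2)
      blob <- pmax(blob, 0.72 * exp(-s2 / 2))
      halo_g <- pmax(halo_g, 0.14 * exp(-s2 / 8))      # out-of-focus glow
      blob_mask <- blob_mask | (s2 <= 1)
    }
    af <- spec$autofluorescence
    autofl <- af * exp(-(edge_dist / 5)^2) + 0.6 * af * cell_mask
    vignette <- 1 - 0.6 * (((yy - nr / 2) / nr)^2 + ((xx - nc / 2) / nc)^2)

    # half-normal chromatic noise, truncated at 3x its own scale so that
    # with no glow the intensity never exceeds background + 3 * noise_sigma
    hn <- function(s) pmin(abs(matrix(stats::rnorm(nr * nc, 0, s), nr, nc)), 3 * s)
    base_r <- 0.5 * spec$background + hn(0.5 * spec$noise_sigma)
    base_g <- 1.8 * spec$background + hn(1.5 * spec$noise_sigma)
    base_b <- 0.7 * spec$background + hn(0.5 * spec$noise_sigma)
    gl <- pmin(blob + halo_g + autofl, 1)
    r_ch <- pmin(pmax((base_r + 0.20 * gl) * vignette, 0), 1)
    g_ch <- pmin(pmax((base_g + 1.00 * gl) * vignette, 0), 1)
    b_ch <- pmin(pmax((base_b + 0.15 * gl) * vignette, 0), 1)
    gfp <- rgb_image(r_ch, g_ch, b_ch)

    out <- list(gfp = gfp, phase = phase)
    if (ground_truth)
      out$truth <- list(cells = cells, cell_mask = cell_mask,
                        blob_mask = blob_mask)
    out
  })
}

#' Oriented sinusoidal test pattern
#'
#' Stripes whose feature orientation is `angle` degrees counterclockwise
#' from horizontal: `angle = 0` gives constant rows (variation down the
#' rows only), `angle = 90` constant columns.
#'
#' @param size `(rows, cols)` or a scalar.
#' @param angle Stripe orientation in degrees.
#' @param freq Spatial frequency in cycles per pixel.
#' @return Numeric matrix in `[0, 1]`.
#' @export
make_oriented_sinusoid <- function(size, angle, freq) {
  if (length(size) == 1L) size <- c(size, size)
  nr <- size[1]; nc <- size[2]
  yy <- matrix(rep(0:(nr - 1L), nc), nr, nc)
  xx <- matrix(rep(0:(nc - 1L), each = nr), nr, nc)
  th <- angle * pi / 180
  ph <- 2 * pi * freq * (cos(th) * yy - sin(th) * xx)
  (sin(ph) + 1) / 2
}

#' Two-Gaussian mixture intensity image
#'
#' Pixels drawn i.i.d. from `weight * N(mu1, sigma) +
#' (1 - weight) * N(mu2, sigma)`, clipped to `[0, 1]`.
#'
#' @param size `(rows, cols)` or a scalar.
#' @param mu1,mu2 Mode means.
#' @param sigma Common standard deviation.
#' @param weight Mixing weight of the first mode.
#' @param seed RNG seed.
#' @return Numeric matrix in `[0, 1]`.
#' @export
make_bimodal <- function(size, mu1 = 0.2, mu2 = 0.8, sigma = 0.05,
                         weight = 0.5, seed = 1L) {
  if (length(size) == 1L) size <- c(size, size)
  .with_seed(seed, {
    np <- size[1] * size[2]
    pick <- stats::runif(np) < weight
    vals <- stats::rnorm(np, ifelse(pick, mu1, mu2), sigma)
    matrix(pmin(pmax(vals, 0), 1), size[1], size[2])
  })
}
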