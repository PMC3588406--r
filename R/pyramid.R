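# Frequency-designed multiscale pyramid.
#
# The pyramid replaces a Laplacian pyramid by a pair of 2D frequency
# responses L(w), H(w) with |L|^2 + |H|^2 = 1 everywhere, L supported on
# ||w||_inf < omega_s with omega_s <= pi/2 so the low-pass branch can be
# decimated by diag(2,2) without aliasing.  Filtering is done in the FFT
# domain with periodic boundaries, which makes perfect reconstruction hold
# to machine precision and makes the transform exactly shift-covariant.

#' Transform configuration for the multiscale/directional decomposition
#'
#' @param levels Number of pyramid levels (default 4).
#' @param dirs_per_level Integer vector, one entry per level, each a power of
#'   two, ordered coarsest to finest (default `c(4, 8, 16, 16)`: 4 directions
#'   at the coarsest detail level, 16 at the finest).
#' @param omega_p Passband corner of the low-pass prototype, radians
#'   (default `4*pi/21`).
#' @param omega_s Stopband corner, radians (default `10*pi/21`); must not
#'   exceed `pi/2` or the decimated low-pass branch would alias.
#' @param dfb_filter Identifier of the directional filter bank realization;
#'   `"pkva"` (the default) selects the critically sampled frequency-domain
#'   fan/wedge bank.
#' @param downsample 2x2 integer decimation matrix for the low-pass branch;
#'   only `diag(2, 2)` is supported.
#' @return An object of class `sflct_config`.
#' @export
sflct_config <- function(levels = 4L,
                         dirs_per_level = c(4L, 8L, 16L, 16L),
                         omega_p = 4 * pi / 21,
                         omega_s = 10 * pi / 21,
                         dfb_filter = "pkva",
                         downsample = diag(2L, 2L)) {
  levels <- as.integer(levels)
  dirs_per_level <- as.integer(dirs_per_level)
  if (levels < 1L) stop_sflct("levels must be a positive integer")
  if (length(dirs_per_level) != levels)
    stop_sflct("dirs_per_level must have one entry per level (%d)", levels)
  if (!all(vapply(dirs_per_level, is_pow2, TRUE)) || any(dirs_per_level < 2L))
    stop_sflct("each dirs_per_level entry must be a power of two >= 2")
  if (!(omega_p > 0 && omega_p < omega_s))
    stop_sflct("need 0 < omega_p < omega_s")
  if (omega_s > pi / 2 + 1e-12)
    stop_sflct("aliasing: low-pass branch not decimable (omega_s > pi/2)")
  if (!all(dim(downsample) == c(2L, 2L)) || !all(downsample == diag(2, 2)))
    stop_sflct("only the diagonal (2,2) downsampling matrix is supported")
  structure(list(levels = levels, dirs_per_level = dirs_per_level,
                 omega_p = omega_p, omega_s = omega_s,
                 dfb_filter = dfb_filter, downsample = downsample),
            class = "sflct_config")
}

#' @export
print.sflct_config <- function(x, ...) {
  cat(sprintf(
    "<sflct_config: %d levels, dirs (coarse->fine) %s, omega_p %.4f, omega_s %.4f, dfb '%s'>\n",
    x$levels, paste(x$dirs_per_level, collapse = ","), x$omega_p, x$omega_s,
    x$dfb_filter))
  invisible(x)
}

# ||w||_inf on the (unshifted) FFT grid of `shape`
.grid_omega_inf <- function(shape) {
  w1 <- abs(2 * pi * signed_freq(shape[1]) / shape[1])
  w2 <- abs(2 * pi * signed_freq(shape[2]) / shape[2])
  outer(w1, w2, pmax)
}

#' Design the pyramid low/high filter pair on an FFT grid
#'
#' The low-pass response is 1 for `||w||_inf <= omega_p`, 0 for
#' `||w||_inf >= omega_s`, with a raised-cosine transition in between
#' (square, `||.||_inf` layout); the high-pass is `sqrt(1 - L^2)` so that
#' `L^2 + H^2 = 1` holds exactly on every grid frequency.
#'
#' @param shape Integer vector `(rows, cols)` of the target grid.
#' @param omega_p,omega_s Pass/stop corner frequencies in radians,
#'   `0 < omega_p < omega_s <= pi/2`.
#' @return A list of class `filter_pair` with real matrices `low` and `high`
#'   in unshifted FFT order.
#' @export
design_pyramid_filters <- function(shape, omega_p = 4 * pi / 21,
                                   omega_s = 10 * pi / 21) {
  if (!(omega_p > 0 && omega_p < omega_s))
    stop_sflct("need 0 < omega_p < omega_s")
  if (omega_s > pi / 2 + 1e-12)
    stop_sflct("aliasing: low-pass branch not decimable (omega_s > pi/2)")
  wi <- .grid_omega_inf(shape)
  t <- pmin(pmax((wi - omega_p) / (omega_s - omega_p), 0), 1)
  low <- cos(pi / 2 * t)
  low[wi >= omega_s] <- 0   # exact zero beyond the stopband corner
  low[wi <= omega_p] <- 1
  high <- sqrt(pmax(1 - low^2, 0))
  structure(list(low = low, high = high), class = "filter_pair")
}

# Fold an FFT-grid spectrum 2x2 (frequency-domain decimation by diag(2,2)).
.fold2 <- function(X) {
  n1 <- nrow(X); n2 <- ncol(X)
  h1 <- n1 / 2L; h2 <- n2 / 2L
  X[1:h1, 1:h2] + X[(h1 + 1):n1, 1:h2] +
    X[1:h1, (h2 + 1):n2] + X[(h1 + 1):n1, (h2 + 1):n2]
}

# Periodize a small-grid spectrum onto the 2x-larger grid (upsampling).
.tile2 <- function(Y) {
  rbind(cbind(Y, Y), cbind(Y, Y))
}

#' Multiscale pyramid analysis
#'
#' Splits an image into `levels` high-pass bands (each kept at the
#' resolution where it was produced) plus one decimated low-pass
#' approximation.  The same filter prototype, sampled on the current grid,
#' is used at every level.  Under the tight-frame normalization used here a
#' constant image `c` produces an approximation equal to `c * 2^levels` and
#' total coefficient energy equals image energy (Parseval).
#'
#' @param img Numeric matrix; dimensions must be divisible by `2^levels`.
#' @param levels Number of levels; defaults to `config$levels`.
#' @param config An [sflct_config] supplying `omega_p`/`omega_s`.
#' @return List with `lowpass` (matrix) and `bandpass` (list of matrices,
#'   element 1 the finest).
#' @export
pyramid_decompose <- function(img, levels = config$levels, config = sflct_config()) {
  check_finite_matrix(img, "img")
  d <- dim(img)
  if (any(d %% 2^levels != 0))
    stop_sflct(paste0("image dimensions %dx%d not divisible by 2^levels = %d; ",
                      "pad to %dx%d first"),
               d[1], d[2], 2^levels,
               2^levels * ceiling(d[1] / 2^levels),
               2^levels * ceiling(d[2] / 2^levels))
  bands <- vector("list", levels)
  cur <- img
  for (j in seq_len(levels)) {
    fp <- design_pyramid_filters(dim(cur), config$omega_p, config$omega_s)
    X <- fft2(cur)
    bands[[j]] <- ifft2_real(X * fp$high, "pyramid highpass")
    cur <- ifft2_real(.fold2(X * fp$low) / 2, "pyramid lowpass")
  }
  list(lowpass = cur, bandpass = bands)
}

#' Multiscale pyramid synthesis
#'
#' Exact inverse of [pyramid_decompose()] (machine precision).
#'
#' @param lowpass Approximation matrix.
#' @param bandpass List of high-pass matrices, finest first.
#' @param config An [sflct_config].
#' @return The reconstructed image matrix.
#' @export
pyramid_reconstruct <- function(lowpass, bandpass, config = sflct_config()) {
  cur <- lowpass
  for (j in rev(seq_along(bandpass))) {
    hb <- bandpass[[j]]
    if (!all(dim(hb) == 2L * dim(cur)))
      stop_sflct("subband shape mismatch at level %d: highpass %dx%d vs lowpass %dx%d",
                 j, nrow(hb), ncol(hb), nrow(cur), ncol(cur))
    fp <- design_pyramid_filters(dim(hb), config$omega_p, config$omega_s)
    X <- fft2(hb) * fp$high + 2 * fp$low * .tile2(fft2(cur))
    cur <- ifft2_real(X, "pyramid reconstruct")
  }
  cur
}
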