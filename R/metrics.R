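# Evaluation: Otsu fluorescence segmentation and region-wise visual
# information fidelity (VIF).
#
# The VIF variant implemented here is the pixel-domain formulation: local
# Gaussian-windowed statistics at four dyadic scales with an additive-noise
# channel model (stabilizing constant sigma_n^2 = 2 on the 0..255 intensity
# scale).  It is deterministic and returns 1 for an undistorted image.
# Scores are comparable within this implementation, not across VIF
# variants.

#' Otsu threshold of a grayscale image
#'
#' Maximizes the between-class variance over a 256-bin histogram of `[0, 1]`
#' intensities; candidate cuts are the interior bin edges `k/256`, and the
#' smallest maximizing cut is returned.
#'
#' @param img Numeric matrix with values in `[0, 1]` and at least two
#'   distinct occupied histogram bins.
#' @return The threshold, a scalar in `(0, 1)`.
#' @export
otsu_threshold <- function(img) {
  check_unit_range(img, "img")
  nb <- 256L
  bin <- pmin(pmax(floor(as.vector(img) * nb), 0), nb - 1L)  # value 1 -> top bin
  counts <- tabulate(bin + 1L, nbins = nb)
  if (sum(counts > 0L) < 2L)
    stop_sflct("degenerate histogram: need at least two occupied gray levels")
  p <- counts / sum(counts)
  mids <- (seq_len(nb) - 0.5) / nb
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nb]
  k <- 1:(nb - 1L)
  valid <- w0[k] > 0 & w0[k] < 1
  sigma_b <- rep(-Inf, nb - 1L)
  sigma_b[valid] <- (mu_t * w0[k][valid] - mu0[k][valid])^2 /
    (w0[k][valid] * (1 - w0[k][valid]))
  k_best <- which.max(sigma_b)
  k_best / nb
}

#' Binary mask container
#'
#' @param mask Logical matrix.
#' @param threshold The scalar threshold that produced it.
#' @return An object of class `binary_mask`; attribute `degenerate` is
#'   `TRUE` when the mask has no `TRUE` or no `FALSE` pixel.
#' @export
binary_mask <- function(mask, threshold) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_sflct("mask must be a logical matrix")
  out <- structure(list(mask = mask, threshold = threshold),
                   class = "binary_mask")
  attr(out, "degenerate") <- !any(mask) || all(mask)
  out
}

#' Fluorescence-area mask of a GFP image
#'
#' Thresholds the IHS intensity plane (or, optionally, the green channel)
#' of the colour image with [otsu_threshold()].
#'
#' @param gfp An [rgb_image].
#' @param channel `"intensity"` (default) or `"green"`.
#' @return A [binary_mask]; `TRUE` marks the fluorescent area.
#' @export
fluorescence_mask <- function(gfp, channel = c("intensity", "green")) {
  channel <- match.arg(channel)
  if (!inherits(gfp, "rgb_image")) stop_sflct("gfp must be an rgb_image")
  plane <- if (channel == "intensity") rgb_to_ihs(gfp)$i else gfp$g
  th <- otsu_threshold(plane)
  binary_mask(plane > th, th)
}

# separable Gaussian 'same' convolution with symmetric padding
.gauss_kernel <- function(n, sd) {
  h <- (n - 1) / 2
  k <- exp(-((-h:h)^2) / (2 * sd^2))
  k / sum(k)
}

.conv2_gauss <- function(x, kern) {
  h <- (length(kern) - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  xp <- pad_symmetric(x, h)
  y <- stats::filter(xp, kern, sides = 2)           # along columns
  y <- y[(h + 1L):(h + nr), , drop = FALSE]
  y <- t(stats::filter(t(y), kern, sides = 2))      # along rows
  y[, (h + 1L):(h + nc), drop = FALSE]
}

#' Visual information fidelity (pixel-domain variant)
#'
#' Compares a distorted image against a reference over four dyadic scales
#' using Gaussian-windowed local statistics; `vif(x, x) = 1`, and values
#' fall toward 0 with increasing distortion.  An optional logical mask
#' restricts the information sums to windows whose center lies in the
#' region (the mask is decimated alongside the images).
#'
#' @param ref Reference image matrix in `[0, 1]` (not constant).
#' @param dist Distorted image matrix, same shape.
#' @param mask Optional logical matrix, same shape as `ref`.
#' @return A scalar score (typically in `[0, 1]`; slightly above 1 is
#'   possible for contrast-enhanced images, as in any VIF formulation).
#' @export
vif <- function(ref, dist, mask = NULL) {
  check_finite_matrix(ref, "ref"); check_finite_matrix(dist, "dist")
  if (!all(dim(ref) == dim(dist))) stop_sflct("ref and dist shapes differ")
  if (max(ref) - min(ref) == 0) stop_sflct("constant reference image")
  if (!is.null(mask)) {
    if (!is.logical(mask) || !all(dim(mask) == dim(ref)))
      stop_sflct("mask must be a logical matrix matching the images")
    if (!any(mask)) stop_sflct("empty region mask")
  }
  x <- ref * 255; y <- dist * 255
  sigma_nsq <- 2
  eps <- 1e-10
  num <- 0; den <- 0
  for (scale in 1:4) {
    n <- 2^(4 - scale + 1) + 1
    kern <- .gauss_kernel(n, n / 5)
    if (scale > 1) {
      x <- .conv2_gauss(x, kern)[seq(1, nrow(x), 2), seq(1, ncol(x), 2), drop = FALSE]
      y <- .conv2_gauss(y, kern)[seq(1, nrow(y), 2), seq(1, ncol(y), 2), drop = FALSE]
      if (!is.null(mask))
        mask <- mask[seq(1, 2 * nrow(x), 2)[seq_len(nrow(x))],
                     seq(1, 2 * ncol(x), 2)[seq_len(ncol(x))], drop = FALSE]
    }
    mu1 <- .conv2_gauss(x, kern); mu2 <- .conv2_gauss(y, kern)
    s1 <- .conv2_gauss(x * x, kern) - mu1^2
    s2 <- .conv2_gauss(y * y, kern) - mu2^2
    s12 <- .conv2_gauss(x * y, kern) - mu1 * mu2
    s1[s1 < 0] <- 0; s2[s2 < 0] <- 0
    g <- s12 / (s1 + eps)
    sv <- s2 - g * s12
    g[s1 < eps] <- 0; sv[s1 < eps] <- s2[s1 < eps]; s1[s1 < eps] <- 0
    g[s2 < eps] <- 0; sv[s2 < eps] <- 0
    sv[g < 0] <- s2[g < 0]; g[g < 0] <- 0
    sv[sv <= eps] <- eps
    tnum <- log10(1 + g^2 * s1 / (sv + sigma_nsq))
    tden <- log10(1 + s1 / sigma_nsq)
    if (is.null(mask)) {
      num <- num + sum(tnum); den <- den + sum(tden)
    } else if (any(mask)) {
      num <- num + sum(tnum[mask]); den <- den + sum(tden[mask])
    }
  }
  if (den == 0) stop_sflct("reference carries no information in the region")
  num / den
}

#' Region-wise VIF report for a fused image
#'
#' Segments the GFP image into fluorescent / non-fluorescent areas with
#' [fluorescence_mask()] and scores the fused intensity plane against both
#' sources: `vif_A_fl` (vs GFP intensity, fluorescent area), `vif_B_fl`
#' (vs phase, fluorescent area), `vif_B_nfl` (vs phase, non-fluorescent
#' area).  If the mask is degenerate the affected scores are `NA` and the
#' report is flagged.
#'
#' @param gfp The source [rgb_image].
#' @param phase The source phase-contrast matrix.
#' @param fused The fused [rgb_image] to evaluate.
#' @param channel Segmentation input passed to [fluorescence_mask()].
#' @return An object of class `vif_report`: list with `vif_A_fl`,
#'   `vif_B_fl`, `vif_B_nfl`, `mask` (a [binary_mask]), and `degenerate`.
#' @export
region_vif_report <- function(gfp, phase, fused,
                              channel = c("intensity", "green")) {
  channel <- match.arg(channel)
  if (!inherits(fused, "rgb_image")) stop_sflct("fused must be an rgb_image")
  bm <- fluorescence_mask(gfp, channel)
  i_a <- rgb_to_ihs(gfp)$i
  i_f <- rgb_to_ihs(fused)$i
  m <- bm$mask
  deg <- isTRUE(attr(bm, "degenerate"))
  score <- function(ref, region) {
    if (!any(region) || all(!region)) return(NA_real_)
    vif(ref, i_f, region)
  }
  out <- structure(list(
    vif_A_fl = if (any(m)) score(i_a, m) else NA_real_,
    vif_B_fl = if (any(m)) score(phase, m) else NA_real_,
    vif_B_nfl = if (any(!m)) score(phase, !m) else NA_real_,
    mask = bm, degenerate = deg), class = "vif_report")
  out
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("<vif_report: A-fl %.4f | B-fl %.4f | B-nfl %.4f | otsu %.4f%s>\n",
              x$vif_A_fl, x$vif_B_fl, x$vif_B_nfl, x$mask$threshold,
              if (x$degenerate) " | DEGENERATE MASK" else ""))
  invisible(x)
}

#' Serialize a VIF report to JSON
#'
#' @param report A `vif_report`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_vif_report <- function(report, path) {
  jsonlite::write_json(
    list(vif_A_fl = report$vif_A_fl, vif_B_fl = report$vif_B_fl,
         vif_B_nfl = report$vif_B_nfl,
         otsu_threshold = report$mask$threshold,
         degenerate_mask = report$degenerate),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
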