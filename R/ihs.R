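# Triangle-model IHS colour transform.
#
# The forward transform maps linear RGB in [0,1] to intensity
# I = (R+G+B)/3, saturation S = 1 - 3 min(R,G,B)/(R+G+B) and hue
# H in [0, 2pi) measured from red through green.  The inverse is the
# standard three-sector triangle inverse; the round-trip is exact to
# floating-point precision away from exact black.

#' RGB image container
#'
#' Bundles three equally shaped numeric matrices with values in `[0, 1]`.
#'
#' @param r,g,b Numeric matrices of equal dimension, values in `[0, 1]`.
#' @return An object of class `rgb_image`: a list with elements `r`, `g`, `b`.
#' @examples
#' img <- rgb_image(matrix(0.2, 4, 4), matrix(0.8, 4, 4), matrix(0.1, 4, 4))
#' @export
rgb_image <- function(r, g, b) {
  check_unit_range(r, "r"); check_unit_range(g, "g"); check_unit_range(b, "b")
  if (!all(dim(r) == dim(g)) || !all(dim(r) == dim(b)))
    stop_sflct("rgb planes must share one shape")
  structure(list(r = r, g = g, b = b), class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d, intensity range %.3f..%.3f>\n",
              nrow(x$r), ncol(x$r),
              min((x$r + x$g + x$b) / 3), max((x$r + x$g + x$b) / 3)))
  invisible(x)
}

#' IHS image container
#'
#' @param i Intensity plane, values in `[0, 1]`.
#' @param h Hue plane in radians, values in `[0, 2pi)`.
#' @param s Saturation plane, values in `[0, 1]`.
#' @return An object of class `ihs_image`.
#' @export
ihs_image <- function(i, h, s) {
  check_unit_range(i, "i")
  check_finite_matrix(h, "h")
  if (min(h) < 0 || max(h) >= 2 * pi)
    stop_sflct("plane 'h' must lie in [0, 2*pi)")
  check_unit_range(s, "s")
  if (!all(dim(i) == dim(h)) || !all(dim(i) == dim(s)))
    stop_sflct("ihs planes must share one shape")
  structure(list(i = i, h = h, s = s), class = "ihs_image")
}

#' Forward triangle IHS transform
#'
#' Converts an [rgb_image] to intensity/hue/saturation.  Conventions for
#' degenerate pixels: exact black (`R+G+B = 0`) gets `S = 0, H = 0`;
#' achromatic pixels (`R = G = B`) get `H = 0`.  The arccos argument is
#' clamped to `[-1, 1]` to absorb floating-point drift.
#'
#' @param img An [rgb_image].
#' @return An [ihs_image] of the same shape.
#' @examples
#' x <- rgb_image(matrix(0, 2, 2), matrix(1, 2, 2), matrix(0, 2, 2))
#' y <- rgb_to_ihs(x)          # I = 1/3, H = 2*pi/3, S = 1
#' @export
rgb_to_ihs <- function(img) {
  if (!inherits(img, "rgb_image")) img <- do.call(rgb_image, as.list(img)[c("r", "g", "b")])
  r <- img$r; g <- img$g; b <- img$b
  sm <- r + g + b
  i <- sm / 3
  mn <- pmin(r, g, b)
  s <- ifelse(sm > 0, 1 - 3 * mn / pmax(sm, .Machine$double.xmin), 0)
  # den^2 = ((R-G)^2 + (R-B)^2 + (G-B)^2)/2 >= 0, zero iff achromatic
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  chrom <- den > 0
  arg <- ifelse(chrom, num / ifelse(chrom, den, 1), 0)
  alpha <- acos(pmin(pmax(arg, -1), 1))
  h <- ifelse(b <= g, alpha, 2 * pi - alpha)
  h[!chrom] <- 0
  s <- pmin(pmax(s, 0), 1)
  h[h >= 2 * pi] <- 0
  ihs_image(i = i, h = h, s = s)
}

#' Inverse triangle IHS transform
#'
#' Applies the three-sector triangle inverse on hue sectors
#' `[0, 2pi/3)`, `[2pi/3, 4pi/3)`, `[4pi/3, 2pi)`.  In each sector one
#' channel is `I(1-S)`, one is `I(1 + S cos(h')/cos(pi/3 - h'))` with the
#' sector-rotated hue `h'`, and the third is `3I` minus the other two; the
#' channel roles per sector are fixed by the round-trip identity with
#' [rgb_to_ihs()].  Out-of-gamut results are clipped to `[0, 1]` and the
#' clip count is logged at WARNING level and attached as attribute
#' `"n_clipped"`.
#'
#' @param img An [ihs_image].
#' @return An [rgb_image]; attribute `n_clipped` counts clipped samples.
#' @export
ihs_to_rgb <- function(img) {
  if (!inherits(img, "ihs_image")) img <- do.call(ihs_image, as.list(img)[c("i", "h", "s")])
  i <- img$i; h <- img$h; s <- img$s
  sector <- pmin(floor(h / (2 * pi / 3)), 2)
  hp <- h - sector * (2 * pi / 3)
  c1 <- i * (1 - s)
  # cos(pi/3 - hp) >= 1/2 on hp in [0, 2pi/3), never degenerate
  c2 <- i * (1 + s * cos(hp) / cos(pi / 3 - hp))
  c3 <- 3 * i - c1 - c2
  r <- ifelse(sector == 0, c2, ifelse(sector == 1, c1, c3))
  g <- ifelse(sector == 0, c3, ifelse(sector == 1, c2, c1))
  b <- ifelse(sector == 0, c1, ifelse(sector == 1, c3, c2))
  planes <- list(r = r, g = g, b = b)
  n_clipped <- sum(vapply(planes, function(p) sum(p < 0 | p > 1), 0))
  if (n_clipped > 0)
    sflct_log("WARNING", "ihs_to_rgb: clipped %d channel samples to [0,1]", n_clipped)
  out <- rgb_image(pmin(pmax(r, 0), 1), pmin(pmax(g, 0), 1), pmin(pmax(b, 0), 1))
  attr(out, "n_clipped") <- n_clipped
  out
}
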