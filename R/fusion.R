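# Coefficient fusion rules and the hybrid fusion pipeline.
#
# Three rules act on the transform coefficients of the two inputs (A = the
# GFP intensity plane, B = the phase-contrast image):
#   * MRE  - maximum region energy: the approximation coefficient whose
#     local window has larger mean-removed energy wins (ties go to B).
#   * MAV  - maximum absolute value: the finest-scale detail coefficient of
#     larger magnitude wins (ties go to A).
#   * NCM  - neighborhood consistency measurement: a normalized correlation
#     Psi over an oriented coefficient neighborhood switches between
#     selection by region energy (Psi < T) and Psi-weighted blending of the
#     signed max/min (Psi >= T).
# All windowed quantities use symmetric padding at the borders.

#' Fusion configuration
#'
#' @param mre_window Odd window side for the region-energy rule (default 3).
#' @param ncm_window Odd window side bounding the NCM neighborhoods
#'   (default 5).
#' @param threshold_T Consistency threshold in (0.5, 1) switching the NCM
#'   rule between selection and weighted blending (default 0.75, the
#'   midpoint of the admissible interval).
#' @param neighborhood_model Optional function
#'   `(n_dirs, l, window) -> neighborhood_class` overriding the built-in
#'   orientation-based assignment (see [neighborhood_for_subband()]).
#' @param abs_compare Logical; if `TRUE` the blending branch of the NCM rule
#'   picks max/min by magnitude instead of signed value (default `FALSE`,
#'   the formula as printed).
#' @param sflct An [sflct_config] for the transform stage.
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(mre_window = 3L, ncm_window = 5L, threshold_T = 0.75,
                          neighborhood_model = NULL, abs_compare = FALSE,
                          sflct = sflct_config()) {
  mre_window <- as.integer(mre_window); ncm_window <- as.integer(ncm_window)
  if (mre_window %% 2L == 0L || mre_window < 3L)
    stop_sflct("mre_window must be odd and >= 3")
  if (ncm_window %% 2L == 0L || ncm_window < 3L)
    stop_sflct("ncm_window must be odd and >= 3")
  if (!(threshold_T > 0.5 && threshold_T < 1))
    stop_sflct("threshold_T must lie in (0.5, 1)")
  if (!is.null(neighborhood_model) && !is.function(neighborhood_model))
    stop_sflct("neighborhood_model must be a function or NULL")
  structure(list(mre_window = mre_window, ncm_window = ncm_window,
                 threshold_T = threshold_T,
                 neighborhood_model = neighborhood_model,
                 abs_compare = isTRUE(abs_compare), sflct = sflct),
            class = "fusion_config")
}

#' Neighborhood class for the NCM rule
#'
#' @param id `"NhdI"` (oriented cross-arm) or `"NhdII"` (rotated diamond).
#' @param offsets Two-column integer matrix of (row, col) offsets; must
#'   contain `(0, 0)`.
#' @return An object of class `neighborhood_class`.
#' @export
neighborhood_class <- function(id, offsets) {
  offsets <- matrix(as.integer(offsets), ncol = 2L)
  if (!any(offsets[, 1] == 0L & offsets[, 2] == 0L))
    stop_sflct("neighborhood offsets must contain (0, 0)")
  structure(list(id = id, offsets = offsets), class = "neighborhood_class")
}

# view of a symmetrically padded plane shifted by (dr, dc); windowed sums
# below accumulate such views in a fixed (column-major) offset order, so an
# independent per-pixel loop using the same order reproduces them exactly
.shifted <- function(xp, h, dr, dc, nr, nc) {
  xp[(1 + h + dr):(nr + h + dr), (1 + h + dc):(nc + h + dc), drop = FALSE]
}

#' Windowed region energy
#'
#' Per position, the sum of squared deviations from the window mean over a
#' square window (symmetric padding at borders).
#'
#' @param c Numeric matrix of coefficients.
#' @param window Odd window side.
#' @return Matrix of the same shape.
#' @export
region_energy <- function(c, window = 3L) {
  check_finite_matrix(c, "c")
  window <- as.integer(window)
  if (window %% 2L == 0L) stop_sflct("window must be odd")
  h <- (window - 1L) %/% 2L
  nr <- nrow(c); nc <- ncol(c)
  xp <- pad_symmetric(c, h)
  offs <- as.matrix(expand.grid(dr = -h:h, dc = -h:h))[, c("dr", "dc")]
  offs <- offs[order(offs[, 2], offs[, 1]), , drop = FALSE]  # column-major
  mu <- NULL
  for (k in seq_len(nrow(offs))) {
    t1 <- .shifted(xp, h, offs[k, 1], offs[k, 2], nr, nc)
    mu <- if (is.null(mu)) t1 else mu + t1
  }
  mu <- mu / window^2
  e <- NULL
  for (k in seq_len(nrow(offs))) {
    t1 <- (.shifted(xp, h, offs[k, 1], offs[k, 2], nr, nc) - mu)^2
    e <- if (is.null(e)) t1 else e + t1
  }
  e
}

#' Approximation fusion by maximum region energy
#'
#' Selects, per position, the coefficient of the input whose window energy
#' ([region_energy()]) is larger; exact ties select the B coefficient.
#'
#' @param cA,cB Equally shaped coefficient matrices.
#' @param window Odd window side (default 3).
#' @return Fused coefficient matrix.
#' @export
fuse_approx_mre <- function(cA, cB, window = 3L) {
  if (!all(dim(cA) == dim(cB))) stop_sflct("cA and cB must have equal shape")
  eA <- region_energy(cA, window)
  eB <- region_energy(cB, window)
  ifelse(eA > eB, cA, cB)
}

#' Detail fusion by maximum absolute value
#'
#' Per position, keeps the coefficient of larger magnitude; ties keep A.
#'
#' @param dA,dB Equally shaped detail subbands.
#' @return Fused subband.
#' @export
fuse_detail_mav <- function(dA, dB) {
  if (!all(dim(dA) == dim(dB))) stop_sflct("dA and dB must have equal shape")
  ifelse(abs(dA) >= abs(dB), dA, dB)
}

# neighborhood sums of f over a neighborhood_class, symmetric padding
.nhd_sums <- function(dA, dB, nhd) {
  offs <- nhd$offsets
  h <- max(abs(offs))
  nr <- nrow(dA); nc <- ncol(dA)
  ap <- pad_symmetric(dA, h); bp <- pad_symmetric(dB, h)
  num <- rhoA <- rhoB <- NULL
  for (k in seq_len(nrow(offs))) {
    sa <- .shifted(ap, h, offs[k, 1], offs[k, 2], nr, nc)
    sb <- .shifted(bp, h, offs[k, 1], offs[k, 2], nr, nc)
    if (is.null(num)) {
      num <- sa * sb; rhoA <- sa * sa; rhoB <- sb * sb
    } else {
      num <- num + sa * sb; rhoA <- rhoA + sa * sa; rhoB <- rhoB + sb * sb
    }
  }
  list(num = num, rhoA = rhoA, rhoB = rhoB)
}

#' Neighborhood consistency map
#'
#' `Psi = 2 * sum(dA * dB) / (sum(dA^2) + sum(dB^2))` over the neighborhood
#' offsets around each position; `Psi = 1` where both neighborhoods are
#' identically zero.  Always `Psi <= 1`; anti-correlated neighborhoods give
#' negative values (no clamping).
#'
#' @param dA,dB Equally shaped subbands.
#' @param nhd A [neighborhood_class].
#' @return Matrix of consistency values.
#' @export
ncm_map <- function(dA, dB, nhd) {
  if (!all(dim(dA) == dim(dB))) stop_sflct("dA and dB must have equal shape")
  s <- .nhd_sums(dA, dB, nhd)
  den <- s$rhoA + s$rhoB
  psi <- ifelse(den > 0, 2 * s$num / ifelse(den > 0, den, 1), 1)
  psi
}

#' Detail fusion by neighborhood consistency
#'
#' Where `Psi < T`, selects the coefficient whose neighborhood energy is
#' larger (ties select A); where `Psi >= T`, blends
#' `Psi * max(dA, dB) + (1 - Psi) * min(dA, dB)` per position with signed
#' comparisons (set `abs_compare` for the magnitude variant).
#'
#' @param dA,dB Equally shaped subbands.
#' @param T Consistency threshold in (0.5, 1).
#' @param nhd A [neighborhood_class].
#' @param abs_compare Use magnitude instead of signed max/min in the
#'   blending branch.
#' @return Fused subband.
#' @export
fuse_detail_ncm <- function(dA, dB, T = 0.75, nhd, abs_compare = FALSE) {
  if (!all(dim(dA) == dim(dB))) stop_sflct("dA and dB must have equal shape")
  s <- .nhd_sums(dA, dB, nhd)
  den <- s$rhoA + s$rhoB
  psi <- ifelse(den > 0, 2 * s$num / ifelse(den > 0, den, 1), 1)
  sel <- ifelse(s$rhoA >= s$rhoB, dA, dB)
  if (abs_compare) {
    mx <- ifelse(abs(dA) >= abs(dB), dA, dB)
    mn <- ifelse(abs(dA) >= abs(dB), dB, dA)
  } else {
    mx <- pmax(dA, dB)
    mn <- pmin(dA, dB)
  }
  blend <- psi * mx + (1 - psi) * mn
  ifelse(psi < T, sel, blend)
}

#' Neighborhood class for a directional subband
#'
#' Subbands whose orientation support starts within 22.5 degrees of
#' horizontal or vertical get Nhd I, a cross-arm of `window` coefficients
#' along the feature orientation (rows for near-horizontal, columns for
#' near-vertical subbands); all other subbands get Nhd II, the 45-degree
#' rotated diamond of positions with even offset parity inside the window.
#' The assignment is total over every supported `(n_dirs, l)`.
#'
#' @param n_dirs Direction count of the subband's level.
#' @param l Direction label, `0 .. n_dirs - 1`.
#' @param config A [fusion_config]; its `neighborhood_model` (if any)
#'   overrides the built-in map, and `ncm_window` bounds the offsets.
#' @return A [neighborhood_class].
#' @export
neighborhood_for_subband <- function(n_dirs, l, config = fusion_config()) {
  if (!is.null(config$neighborhood_model))
    return(config$neighborhood_model(n_dirs, l, config$ncm_window))
  if (l < 0L || l >= n_dirs) stop_sflct("direction label %d out of range", l)
  w <- config$ncm_window
  h <- (w - 1L) %/% 2L
  phi <- dfb_direction_angles(n_dirs)$phi_lo[l + 1L]
  d_h <- min(phi %% 180, 180 - phi %% 180)       # distance to horizontal
  d_v <- abs(phi - 90)                           # distance to vertical
  if (min(d_h, d_v) < 22.5) {
    offs <- if (d_h <= d_v) cbind(0L, -h:h) else cbind(-h:h, 0L)
    neighborhood_class("NhdI", offs)
  } else {
    g <- as.matrix(expand.grid(i = -h:h, j = -h:h))
    g <- g[(abs(g[, 1]) + abs(g[, 2])) %% 2L == 0L &
             (abs(g[, 1]) + abs(g[, 2])) <= 2L, , drop = FALSE]
    neighborhood_class("NhdII", g)
  }
}

# shared scaffolding for the transform-domain fusion pipelines
.fuse_pipeline <- function(gfp, phase, config, detail_rule) {
  if (!inherits(gfp, "rgb_image")) stop_sflct("gfp must be an rgb_image")
  check_unit_range(phase, "phase")
  if (!all(dim(gfp$r) == dim(phase)))
    stop_sflct("gfp (%dx%d) and phase (%dx%d) dimensions differ; inputs must be registered",
               nrow(gfp$r), ncol(gfp$r), nrow(phase), ncol(phase))
  ihs <- rgb_to_ihs(gfp)
  sflct_log("INFO", "fusion: decomposing intensity planes")
  cA <- sflct_decompose(ihs$i, config$sflct)
  cB <- sflct_decompose(phase, config$sflct)
  fusedc <- cA
  fusedc$approx <- fuse_approx_mre(cA$approx, cB$approx, config$mre_window)
  for (j in seq_along(cA$details)) {
    nd <- length(cA$details[[j]])
    for (l1 in seq_len(nd)) {
      fusedc$details[[j]][[l1]] <- detail_rule(
        cA$details[[j]][[l1]], cB$details[[j]][[l1]], j, nd, l1 - 1L)
    }
  }
  i_f <- sflct_reconstruct(fusedc)
  n_out <- sum(i_f < 0 | i_f > 1)
  if (n_out > 0)
    sflct_log("WARNING", "fusion: fused intensity clipped at %d pixels", n_out)
  ihs_to_rgb(ihs_image(pmin(pmax(i_f, 0), 1), ihs$h, ihs$s))
}

#' Hybrid multiscale fusion of a GFP / phase-contrast pair
#'
#' Implements the full pipeline: IHS separation of the colour image, SFL-CT
#' decomposition of its intensity plane and of the phase image, MRE on the
#' approximation, MAV on the finest-level detail subbands, NCM on all other
#' detail subbands, inverse transform, and inverse IHS with the original
#' hue and saturation.  Inputs are assumed registered.
#'
#' @param gfp An [rgb_image] (fluorescence modality).
#' @param phase Grayscale matrix in `[0, 1]`, same dimensions.
#' @param config A [fusion_config].
#' @return The fused [rgb_image].
#' @export
fuse_images <- function(gfp, phase, config = fusion_config()) {
  nhd_cache <- list()
  rule <- function(dA, dB, j, n_dirs, l) {
    if (j == 1L) return(fuse_detail_mav(dA, dB))
    key <- sprintf("%d_%d", n_dirs, l)
    if (is.null(nhd_cache[[key]]))
      nhd_cache[[key]] <<- neighborhood_for_subband(n_dirs, l, config)
    fuse_detail_ncm(dA, dB, config$threshold_T, nhd_cache[[key]],
                    config$abs_compare)
  }
  .fuse_pipeline(gfp, phase, config, rule)
}

#' Baseline: traditional IHS component substitution
#'
#' Replaces the intensity plane of the colour image by the phase image and
#' inverts the IHS transform (conventional component substitution; no
#' multiscale stage).
#'
#' @inheritParams fuse_images
#' @return The fused [rgb_image].
#' @export
fuse_t_ihs <- function(gfp, phase) {
  if (!inherits(gfp, "rgb_image")) stop_sflct("gfp must be an rgb_image")
  check_unit_range(phase, "phase")
  if (!all(dim(gfp$r) == dim(phase)))
    stop_sflct("gfp and phase dimensions differ")
  ihs <- rgb_to_ihs(gfp)
  ihs_to_rgb(ihs_image(phase, ihs$h, ihs$s))
}

#' Baseline: MRE approximation + MAV on all detail subbands
#'
#' Same transform pipeline as [fuse_images()] but with the
#' maximum-absolute-value rule on every detail subband (no NCM).
#'
#' @inheritParams fuse_images
#' @return The fused [rgb_image].
#' @export
fuse_ihs_mre_mav <- function(gfp, phase, config = fusion_config()) {
  .fuse_pipeline(gfp, phase, config,
                 function(dA, dB, j, n_dirs, l) fuse_detail_mav(dA, dB))
}
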