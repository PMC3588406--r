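# Directional filter bank (DFB).
#
# The bank splits a band into n = 2^k wedge-shaped directional subbands,
# critically sampled, with machine-precision reconstruction.  It is realized
# in the frequency domain: the DFT grid is partitioned into n equal-count
# "bowtie" wedges (uniform in the square-angle/slope coordinate, so wedge
# boundaries are straight lines through the origin and areas are equal);
# each wedge's coefficients are packed by an integer lattice fold into a
# small rectangular spectrum whose inverse FFT is the real spatial subband.
# Subbands near the row-frequency axis fold (rows by 2, cols by n/2), those
# near the column-frequency axis fold (rows by n/2, cols by 2), so every
# subband is the (masked) decimation of a wedge band-pass filtered signal -
# spatially coherent and shift covariant.
#
# Exactness is enforced at the index level when the packing plan is built:
# every DFT bin is assigned to exactly one wedge, every packed slot carries
# at most one bin, Hermitian pairs are kept together so all subbands are
# real, and the handful of self-paired bins (where a conjugate pair folds
# onto a single self-conjugate slot) are stored as their real part with the
# imaginary part routed to an otherwise-empty slot.  A plan is therefore a
# bijection of the N1*N2 spectral degrees of freedom onto exactly N1*N2
# stored reals: reconstruction is exact and critical sampling holds with
# equality.

.dfb_cache <- new.env(parent = emptyenv())

# Square-angle coordinate: circular in [-1, 3), period 4, symmetric under
# negation of the frequency vector.  0 = row-frequency axis (horizontal
# image features), 2 = column-frequency axis (vertical features), +-1 the
# diagonals.  Uniform bins in this coordinate give equal-area wedges.
.square_angle <- function(u, v) {
  neg <- (u < 0) | (u == 0 & v < 0)
  cu <- ifelse(neg, -u, u)
  cv <- ifelse(neg, -v, v)
  onaxis <- cu >= abs(cv)
  xi <- numeric(length(cu))
  xi[onaxis] <- ifelse(cu[onaxis] > 0, cv[onaxis] / cu[onaxis], 0)
  xi[!onaxis] <- 2 - cu[!onaxis] / cv[!onaxis]
  xi
}

.circ4 <- function(a, b) {
  d <- (a - b) %% 4
  pmin(d, 4 - d)
}

# Orientation angle (degrees in [0,180), 0 = horizontal image features)
# of the frequency direction with square angle xi.
.phi_of_xi <- function(xi) {
  u <- ifelse(abs(xi) <= 1, 1, abs(2 - xi))
  v <- ifelse(abs(xi) <= 1, xi, ifelse(xi < 2, 1, -1))
  (atan2(u, v) * 180 / pi + 90) %% 180
}

# Wedge geometry table for an n-direction bank.  Wedge boundaries sit on
# the frequency axes and diagonals (uniform, equal-area bins in the square
# angle xi); wedge position index m covers xi in [-1 + 4m/n, -1 + 4(m+1)/n).
# Direction labels l are assigned counterclockwise in feature orientation,
# anchored so that label 0 is the wedge whose orientation support starts at
# horizontal (support lower edge phi_lo = 0).
.dfb_geometry <- function(n) {
  m <- 0:(n - 1L)
  xi_lo <- -1 + 4 * m / n
  xi_hi <- xi_lo + 4 / n
  xi_c <- (xi_lo + xi_hi) / 2
  # feature orientation decreases as xi increases; support lower edge:
  phi_lo <- .phi_of_xi(ifelse(xi_hi >= 3, xi_hi - 4, xi_hi))
  phi_hi_raw <- .phi_of_xi(xi_lo)
  phi_hi <- ifelse(phi_hi_raw == 0, 180, phi_hi_raw)
  # label 0 = wedge containing horizontal orientation; counterclockwise
  wrap <- phi_lo > phi_hi
  w0 <- which(ifelse(wrap, TRUE, phi_lo <= 0 & phi_hi > 0) |
                (!wrap & phi_lo == 0))[1]
  score <- (phi_lo - phi_lo[w0]) %% 180
  lab <- rank(score) - 1L
  cls_R <- abs(xi_c) < 1                     # row-frequency family
  data.frame(m = m, label = as.integer(lab), xi_lo = xi_lo, xi_hi = xi_hi,
             xi_c = xi_c, phi_lo = phi_lo, phi_hi = phi_hi, cls_R = cls_R)
}

#' Orientation support of the directional subbands
#'
#' Direction labels run counterclockwise in feature orientation: subband
#' `l + 1` holds image features whose orientation lies in the returned
#' interval, with label 0 starting at horizontal (0 degrees).  Wedge
#' boundaries sit on the axes and diagonals of the frequency square, so
#' supports are intervals between consecutive `atan`-warped anchors.
#'
#' @param n_dirs Number of directions (power of two >= 2).
#' @return A data frame with one row per direction label (ascending):
#'   `label`, `phi_lo`, `phi_hi` (degrees, `[0, 180]`).
#' @export
dfb_direction_angles <- function(n_dirs) {
  n <- as.integer(n_dirs)
  if (!is_pow2(n) || n < 2L) stop_sflct("n_dirs must be a power of two >= 2")
  g <- .dfb_geometry(n)
  g <- g[order(g$label), c("label", "phi_lo", "phi_hi")]
  rownames(g) <- NULL
  g
}

# slot (0-based linear in an r x c box) of a 0-based linear bin under a
# (possibly sheared) lattice fold; the shears realize quincunx-kernel
# packing for the two-channel fan bank (n = 2)
.slot_of <- function(bin0, n1, r, cc, sh1 = 0L, sh2 = 0L) {
  i1 <- bin0 %% n1
  i2 <- bin0 %/% n1
  ((i1 - sh1 * i2) %% r) + r * ((i2 - sh2 * i1) %% cc)
}

# packing box and shear for one wedge family on an n1 x n2 grid
.fam_params <- function(n1, n2, n, famR) {
  if (n == 2L) {
    if (famR) {
      if (n1 %% n2 != 0L) stop_sflct("grid aspect unsupported for 2 directions")
      list(r = n1, c = n2 %/% 2L, sh1 = n1 %/% n2, sh2 = 0L)
    } else {
      if (n2 %% n1 != 0L) stop_sflct("grid aspect unsupported for 2 directions")
      list(r = n1 %/% 2L, c = n2, sh1 = 0L, sh2 = n2 %/% n1)
    }
  } else if (famR) {
    list(r = n1 %/% 2L, c = (2L * n2) %/% n, sh1 = 0L, sh2 = 0L)
  } else {
    list(r = (2L * n1) %/% n, c = n2 %/% 2L, sh1 = 0L, sh2 = 0L)
  }
}

# Build (and cache) the packing plan for one grid shape and direction count.
.dfb_plan <- function(n1, n2, n) {
  key <- sprintf("%d_%d_%d", n1, n2, n)
  if (!is.null(.dfb_cache[[key]])) return(.dfb_cache[[key]])
  if (!is_pow2(n) || n < 2L) stop_sflct("n_dirs must be a power of two >= 2")
  if (n1 %% 2L != 0L || n2 %% 2L != 0L)
    stop_sflct("band dimensions must be even for the DFB")
  if ((2L * n1) %% n != 0L || (2L * n2) %% n != 0L || n > min(n1, n2))
    stop_sflct("band %dx%d too small / not divisible for %d directions", n1, n2, n)

  nb <- n1 * n2
  bin0 <- 0:(nb - 1L)
  i1 <- bin0 %% n1; i2 <- bin0 %/% n1
  s1 <- ifelse(i1 < n1 / 2, i1, i1 - n1)
  s2 <- ifelse(i2 < n2 / 2, i2, i2 - n2)
  xi <- .square_angle(s1 / n1, s2 / n2)
  m_of_bin <- pmin(floor((xi + 1) * n / 4), n - 1L)

  geom <- .dfb_geometry(n)                   # rows in m order
  lab_of_m <- geom$label
  # per-LABEL geometry vectors (index = label + 1)
  ord <- order(geom$label)
  xi_c <- geom$xi_c[ord]
  cls_R <- geom$cls_R[ord]
  pR <- .fam_params(n1, n2, n, TRUE)
  pC <- .fam_params(n1, n2, n, FALSE)
  box_r <- ifelse(cls_R, pR$r, pC$r)
  box_c <- ifelse(cls_R, pR$c, pC$c)
  lab <- 0:(n - 1L)
  lab_of_bin <- lab_of_m[m_of_bin + 1L]

  conj0 <- ((n1 - i1) %% n1) + n1 * ((n2 - i2) %% n2)
  canon <- bin0 <= conj0
  it_b1 <- bin0[canon]
  it_b2 <- conj0[canon]
  it_self <- it_b1 == it_b2
  it_xi <- xi[canon]
  it_wedge0 <- lab_of_bin[canon]                  # ideal assignment
  ni <- length(it_b1)

  # precompute slots under both box families
  slR1 <- .slot_of(it_b1, n1, pR$r, pR$c, pR$sh1, pR$sh2)
  slR2 <- .slot_of(it_b2, n1, pR$r, pR$c, pR$sh1, pR$sh2)
  slC1 <- .slot_of(it_b1, n1, pC$r, pC$c, pC$sh1, pC$sh2)
  slC2 <- .slot_of(it_b2, n1, pC$r, pC$c, pC$sh1, pC$sh2)
  orbR <- pmin(slR1, slR2); orbC <- pmin(slC1, slC2)
  orbit_in <- function(it, w) if (cls_R[w + 1L]) orbR[it] else orbC[it]

  # occupancy: per wedge, an integer vector over box slots (0 = free)
  occ <- lapply(seq_len(n), function(w) integer(box_r[w] * box_c[w]))
  assign_w <- rep.int(-1L, ni)

  pref_of <- function(it) {
    d <- .circ4(it_xi[it], xi_c)
    order(d, lab)  # wedge indices 1..n, nearest orientation first
  }

  place <- function(it, prefs, visited) {
    for (w1 in prefs) {
      o <- orbit_in(it, w1 - 1L) + 1L
      if (!is.null(visited[[as.character(w1 * (nb + 1L) + o)]])) next
      if (occ[[w1]][o] == 0L) {
        occ[[w1]][o] <<- it
        assign_w[it] <<- w1 - 1L
        return(TRUE)
      }
    }
    # all candidate orbits taken: augmenting path - try to relocate occupants
    for (w1 in prefs) {
      o <- orbit_in(it, w1 - 1L) + 1L
      key2 <- as.character(w1 * (nb + 1L) + o)
      if (!is.null(visited[[key2]])) next
      visited[[key2]] <- TRUE
      other <- occ[[w1]][o]
      occ[[w1]][o] <<- 0L
      if (place(other, pref_of(other), visited)) {
        occ[[w1]][o] <<- it
        assign_w[it] <<- w1 - 1L
        return(TRUE)
      }
      occ[[w1]][o] <<- other
    }
    FALSE
  }

  # first pass: ideal wedge when free; collect the rest
  leftovers <- integer(0)
  for (it in seq_len(ni)) {
    w1 <- it_wedge0[it] + 1L
    o <- orbit_in(it, w1 - 1L) + 1L
    if (occ[[w1]][o] == 0L) {
      occ[[w1]][o] <- it
      assign_w[it] <- it_wedge0[it]
    } else leftovers <- c(leftovers, it)
  }
  for (it in leftovers) {
    if (!place(it, pref_of(it), new.env(parent = emptyenv())))
      stop_sflct("internal error: DFB packing failed for %dx%d, %d dirs", n1, n2, n)
  }

  # assemble per-wedge plans
  wplans <- vector("list", n)
  stuck_w <- integer(0); stuck_slot <- integer(0)
  stuck_b1 <- integer(0); stuck_b2 <- integer(0)
  for (w in seq_len(n)) {
    its <- which(assign_w == w - 1L)
    r <- box_r[w]; cc <- box_c[w]
    s1w <- if (cls_R[w]) slR1[its] else slC1[its]
    s2w <- if (cls_R[w]) slR2[its] else slC2[its]
    selfs <- it_self[its]
    stuck <- !selfs & s1w == s2w
    gb <- c(it_b1[its][selfs], it_b1[its][!selfs & !stuck], it_b2[its][!selfs & !stuck])
    gs <- c(s1w[selfs], s1w[!selfs & !stuck], s2w[!selfs & !stuck])
    if (anyDuplicated(gs) || any(gs < 0) || any(gs >= r * cc))
      stop_sflct("internal error: DFB slot table corrupt (wedge %d)", w)
    wplans[[w]] <- list(box = c(r, cc),
                        gather_bins = gb + 1L, gather_slots = gs + 1L,
                        stuck_slots = s1w[stuck] + 1L,
                        stuck_b1 = it_b1[its][stuck] + 1L,
                        stuck_b2 = it_b2[its][stuck] + 1L,
                        carr = NULL)
    ns <- sum(stuck)
    if (ns) {
      stuck_w <- c(stuck_w, rep.int(w, ns))
      stuck_slot <- c(stuck_slot, s1w[stuck] + 1L)
      stuck_b1 <- c(stuck_b1, it_b1[its][stuck] + 1L)
      stuck_b2 <- c(stuck_b2, it_b2[its][stuck] + 1L)
    }
  }

  # route the lost imaginary parts of stuck pairs into empty slots;
  # empties are symmetric, so each empty conjugate-orbit carries two values
  # (real and imaginary component), each empty self-slot carries one.
  n_stuck <- length(stuck_w)
  carriers <- NULL
  if (n_stuck) {
    cap_w <- integer(0); cap_slot <- integer(0); cap_part <- integer(0)
    cap_selfslot <- logical(0)
    for (w in seq_len(n)) {
      r <- box_r[w]; cc <- box_c[w]
      used <- logical(r * cc)
      used[wplans[[w]]$gather_slots] <- TRUE
      used[wplans[[w]]$stuck_slots] <- TRUE
      empt <- which(!used) - 1L
      if (!length(empt)) next
      e1 <- empt %% r; e2 <- empt %/% r
      ce <- ((r - e1) %% r) + r * ((cc - e2) %% cc)
      selfe <- ce == empt
      se <- empt[selfe]                       # each carries one real value
      if (length(se)) {
        cap_w <- c(cap_w, rep.int(w, length(se)))
        cap_slot <- c(cap_slot, se + 1L)
        cap_part <- c(cap_part, rep.int(1L, length(se)))
        cap_selfslot <- c(cap_selfslot, rep.int(TRUE, length(se)))
      }
      oe <- empt[!selfe & empt < ce]          # conjugate orbit: two values
      if (length(oe)) {
        cap_w <- c(cap_w, rep.int(w, 2L * length(oe)))
        cap_slot <- c(cap_slot, rep(oe + 1L, each = 2L))
        cap_part <- c(cap_part, rep_len(c(1L, 2L), 2L * length(oe)))
        cap_selfslot <- c(cap_selfslot, rep.int(FALSE, 2L * length(oe)))
      }
    }
    if (length(cap_w) < n_stuck)
      stop_sflct("internal error: DFB carrier capacity short (%d < %d)",
                 length(cap_w), n_stuck)
    sel <- seq_len(n_stuck)
    carriers <- data.frame(stuck = sel, wedge = cap_w[sel],
                           slot = cap_slot[sel], part = cap_part[sel],
                           # energy-preserving storage scale: a self-conjugate
                           # carrier slot holds one real, a conjugate orbit two
                           scale = ifelse(cap_selfslot[sel], sqrt(2 / n), 1 / sqrt(n)))
  }

  plan <- list(n1 = n1, n2 = n2, n = n, boxes = cbind(box_r, box_c),
               labels = lab, wedges = wplans,
               stuck = if (n_stuck) data.frame(wedge = stuck_w, slot = stuck_slot,
                                               b1 = stuck_b1, b2 = stuck_b2) else NULL,
               carriers = carriers)
  .dfb_cache[[key]] <- plan
  plan
}

#' Directional filter bank analysis
#'
#' Splits a band into `n_dirs` critically sampled directional subbands.
#' Subband `l + 1` of the returned list holds features oriented near
#' `l * 180 / n_dirs` degrees from horizontal (see [dfb_direction_angles()]).
#' Total coefficient count over all subbands equals the pixel count exactly,
#' and [dfb_reconstruct()] inverts the analysis to machine precision.
#'
#' @param band Numeric matrix (even dimensions, divisible as required by
#'   `n_dirs`).
#' @param n_dirs Number of directions, a power of two >= 2.
#' @param filter_id Filter family identifier; `"pkva"` (default) selects the
#'   frequency-domain wedge bank (kept for configuration compatibility).
#' @return List of `n_dirs` real matrices.
#' @export
dfb_decompose <- function(band, n_dirs, filter_id = "pkva") {
  check_finite_matrix(band, "band")
  plan <- .dfb_plan(nrow(band), ncol(band), as.integer(n_dirs))
  n <- plan$n
  X <- fft2(band)
  vim <- NULL
  if (!is.null(plan$stuck))
    vim <- Im(X[plan$stuck$b1]) * plan$carriers$scale[order(plan$carriers$stuck)]
  out <- vector("list", n)
  for (w in seq_len(n)) {
    wp <- plan$wedges[[w]]
    S <- matrix(0 + 0i, wp$box[1], wp$box[2])
    S[wp$gather_slots] <- X[wp$gather_bins] / sqrt(n)
    if (length(wp$stuck_slots))
      S[wp$stuck_slots] <- (X[wp$stuck_b1] + X[wp$stuck_b2]) / sqrt(2 * n)
    if (!is.null(plan$carriers)) {
      cw <- plan$carriers[plan$carriers$wedge == w, , drop = FALSE]
      if (nrow(cw)) {
        for (j in seq_len(nrow(cw))) {
          add <- if (cw$part[j] == 1L) vim[cw$stuck[j]] + 0i else 1i * vim[cw$stuck[j]]
          S[cw$slot[j]] <- S[cw$slot[j]] + add
          r <- wp$box[1]; cc <- wp$box[2]
          e <- cw$slot[j] - 1L
          ce <- ((r - e %% r) %% r) + r * ((cc - e %/% r) %% cc)
          if (ce != e) S[ce + 1L] <- Conj(S[e + 1L])
        }
      }
    }
    out[[w]] <- ifft2_real(S, "dfb subband")
  }
  out
}

#' Directional filter bank synthesis
#'
#' Exact inverse of [dfb_decompose()].
#'
#' @param subbands List of directional subbands as produced by
#'   [dfb_decompose()].
#' @param filter_id Filter family identifier (see [dfb_decompose()]).
#' @return The reconstructed band matrix.
#' @export
dfb_reconstruct <- function(subbands, filter_id = "pkva") {
  n <- length(subbands)
  b1 <- subbands[[1]]
  # recover grid shape from the family-R box of wedge 1 (label 0, row family)
  if (n == 2L) {
    n1 <- nrow(b1)
    n2 <- 2L * ncol(b1)
  } else {
    n1 <- 2L * nrow(b1)
    n2 <- (n * ncol(b1)) %/% 2L
  }
  plan <- .dfb_plan(n1, n2, n)
  X <- matrix(0 + 0i, n1, n2)
  st <- plan$stuck
  re_st <- if (!is.null(st)) numeric(nrow(st)) else NULL
  im_st <- if (!is.null(st)) numeric(nrow(st)) else NULL
  for (w in seq_len(n)) {
    wp <- plan$wedges[[w]]
    if (!all(dim(subbands[[w]]) == wp$box))
      stop_sflct("subband %d has shape %dx%d, expected %dx%d", w,
                 nrow(subbands[[w]]), ncol(subbands[[w]]), wp$box[1], wp$box[2])
    S <- fft2(subbands[[w]])
    X[wp$gather_bins] <- sqrt(plan$n) * S[wp$gather_slots]
    if (length(wp$stuck_slots)) {
      idx <- which(st$wedge == w)
      re_st[idx] <- sqrt(plan$n / 2) * Re(S[st$slot[idx]])
    }
    if (!is.null(plan$carriers)) {
      cw <- plan$carriers[plan$carriers$wedge == w, , drop = FALSE]
      if (nrow(cw)) {
        val <- S[cw$slot]
        v <- ifelse(cw$part == 1L, Re(val), Im(val))
        im_st[cw$stuck] <- v / cw$scale
      }
    }
  }
  if (!is.null(st)) {
    X[st$b1] <- complex(real = re_st, imaginary = im_st)
    X[st$b2] <- complex(real = re_st, imaginary = -im_st)
  }
  ifft2_real(X, "dfb reconstruct")
}
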