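# Independent brute-force oracles for the windowed fusion rules and for
# Otsu thresholding.  All loop per pixel and accumulate in the same
# column-major / offset-row order that the vectorized implementations
# document, so agreement is exact (not just within tolerance).

pad_sym <- function(x, h) {
  if (h == 0) return(x)
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(h:1, seq_len(nr), nr:(nr - h + 1L))
  ci <- c(h:1, seq_len(nc), nc:(nc - h + 1L))
  x[ri, ci, drop = FALSE]
}

oracle_region_energy <- function(x, w) {
  h <- (w - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  xp <- pad_sym(x, h)
  out <- matrix(0, nr, nc)
  for (n in 1:nc) for (m in 1:nr) {
    mu <- 0
    for (dc in -h:h) for (dr in -h:h) mu <- mu + xp[m + h + dr, n + h + dc]
    mu <- mu / w^2
    e <- 0
    for (dc in -h:h) for (dr in -h:h) e <- e + (xp[m + h + dr, n + h + dc] - mu)^2
    out[m, n] <- e
  }
  out
}

oracle_mre <- function(cA, cB, w) {
  eA <- oracle_region_energy(cA, w)
  eB <- oracle_region_energy(cB, w)
  out <- cB
  out[eA > eB] <- cA[eA > eB]
  out
}

oracle_mav <- function(dA, dB) {
  out <- dA
  for (k in seq_along(dA)) out[k] <- if (abs(dA[k]) >= abs(dB[k])) dA[k] else dB[k]
  out
}

oracle_nhd_stats <- function(dA, dB, offsets) {
  h <- max(abs(offsets))
  nr <- nrow(dA); nc <- ncol(dA)
  ap <- pad_sym(dA, h); bp <- pad_sym(dB, h)
  num <- rhoA <- rhoB <- matrix(0, nr, nc)
  for (n in 1:nc) for (m in 1:nr) {
    s_num <- s_a <- s_b <- 0
    for (k in seq_len(nrow(offsets))) {
      va <- ap[m + h + offsets[k, 1], n + h + offsets[k, 2]]
      vb <- bp[m + h + offsets[k, 1], n + h + offsets[k, 2]]
      s_num <- s_num + va * vb
      s_a <- s_a + va * va
      s_b <- s_b + vb * vb
    }
    num[m, n] <- s_num; rhoA[m, n] <- s_a; rhoB[m, n] <- s_b
  }
  list(num = num, rhoA = rhoA, rhoB = rhoB)
}

oracle_ncm_map <- function(dA, dB, nhd) {
  s <- oracle_nhd_stats(dA, dB, nhd$offsets)
  den <- s$rhoA + s$rhoB
  out <- matrix(1, nrow(dA), ncol(dA))
  nz <- den > 0
  out[nz] <- 2 * s$num[nz] / den[nz]
  out
}

oracle_ncm_fuse <- function(dA, dB, T, nhd) {
  s <- oracle_nhd_stats(dA, dB, nhd$offsets)
  out <- dA
  for (k in seq_along(dA)) {
    den <- s$rhoA[k] + s$rhoB[k]
    psi <- if (den > 0) 2 * s$num[k] / den else 1
    if (psi < T) {
      out[k] <- if (s$rhoA[k] >= s$rhoB[k]) dA[k] else dB[k]
    } else {
      out[k] <- psi * max(dA[k], dB[k]) + (1 - psi) * min(dA[k], dB[k])
    }
  }
  out
}

oracle_otsu <- function(x) {
  nb <- 256L
  bin <- pmin(pmax(floor(as.vector(x) * nb), 0), nb - 1L)
  counts <- tabulate(bin + 1L, nbins = nb)
  p <- counts / sum(counts)
  mids <- (seq_len(nb) - 0.5) / nb
  best <- -Inf; k_best <- NA_integer_
  for (k in 1:(nb - 1L)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    m0 <- sum(p[1:k] * mids[1:k]) / w0
    m1 <- sum(p[(k + 1L):nb] * mids[(k + 1L):nb]) / w1
    sb <- w0 * w1 * (m0 - m1)^2
    if (sb > best) { best <- sb; k_best <- k }
  }
  k_best / nb
}

rand_gray <- function(nr, nc = nr) matrix(stats::runif(nr * nc), nr, nc)
max_abs <- function(a, b) max(abs(a - b))
rgb_max_abs <- function(a, b) max(abs(a$r - b$r), abs(a$g - b$g), abs(a$b - b$b))
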