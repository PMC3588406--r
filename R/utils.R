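#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules: validation, padding, logging,
# and small FFT conveniences.  All images are plain numeric matrices
# (grayscale) or lists of matrices (colour planes), values on [0, 1].

stop_sflct <- function(...) stop(sprintf(...), call. = FALSE)

#' Structured single-line logging
#'
#' Emits `[LEVEL] stage: message` lines via [message()].  The active level is
#' taken from `getOption("sflctfuse.log_level")` (one of `"DEBUG"`, `"INFO"`,
#' `"WARNING"`, `"ERROR"`, default `"WARNING"`).
#'
#' @param level Severity of the record.
#' @param fmt,... `sprintf()` format and arguments.
#' @return Invisibly, the formatted line (emitted or not).
#' @export
sflct_log <- function(level = c("INFO", "DEBUG", "WARNING", "ERROR"), fmt, ...) {
  level <- match.arg(level)
  ranks <- c(DEBUG = 1L, INFO = 2L, WARNING = 3L, ERROR = 4L)
  active <- getOption("sflctfuse.log_level", "WARNING")
  line <- sprintf("[%s] %s", level, sprintf(fmt, ...))
  if (ranks[[level]] >= ranks[[match.arg(active, names(ranks))]]) message(line)
  invisible(line)
}

check_finite_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_sflct("'%s' must be a numeric matrix", name)
  if (!all(is.finite(x)))
    stop_sflct("plane '%s' contains non-finite values", name)
  invisible(x)
}

check_unit_range <- function(x, name) {
  check_finite_matrix(x, name)
  if (min(x) < 0 || max(x) > 1)
    stop_sflct("plane '%s' has values outside [0, 1] (range %.4g..%.4g)",
               name, min(x), max(x))
  invisible(x)
}

# Symmetric (reflect without repeating the edge sample? -- we use the
# conventional "symmetric" reflection that repeats the edge, matching the
# windowed fusion rules' boundary contract) padding by `p` samples each side.
pad_symmetric <- function(x, p) {
  if (p == 0L) return(x)
  nr <- nrow(x); nc <- ncol(x)
  if (p > nr || p > nc)
    stop_sflct("symmetric padding of %d exceeds image size %dx%d", p, nr, nc)
  ri <- c(p:1, seq_len(nr), nr:(nr - p + 1L))
  ci <- c(p:1, seq_len(nc), nc:(nc - p + 1L))
  x[ri, ci, drop = FALSE]
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(X) stats::fft(X, inverse = TRUE) / length(X)

# Real part of an inverse FFT whose input is Hermitian by construction;
# asserts the imaginary residue is numerically negligible.
ifft2_real <- function(X, where = "ifft2_real") {
  y <- ifft2(X)
  im <- max(abs(Im(y)))
  sc <- max(abs(Re(y)), 1)
  if (im > 1e-8 * sc)
    stop_sflct("internal error: non-real reconstruction in %s (imag %.3g)", where, im)
  Re(y)
}

# Signed DFT frequency indices for an axis of length n: 0, 1, ..., -1 order.
signed_freq <- function(n) {
  k <- 0:(n - 1L)
  ifelse(k < n / 2, k, k - n)
}

is_pow2 <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n - 1L)) == 0L
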