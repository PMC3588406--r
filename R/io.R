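# PNG / TIFF image IO.  Integer data are rescaled to [0, 1] by the full
# range of the stored bit depth; writing quantizes to 8 bits with
# round-half-away-from-zero.

#' Read a PNG or TIFF image
#'
#' 8-bit and 16-bit integer data are rescaled to `[0, 1]`; a single-channel
#' file returns a matrix, a three-channel file an [rgb_image].  Images with
#' an alpha channel are rejected.
#'
#' @param path File path (`.png`, `.tif` or `.tiff`).
#' @return A numeric matrix or an [rgb_image].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_sflct("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop_sflct("unsupported image format '%s' (use PNG or TIFF)", ext))
  if (length(dim(arr)) == 2L) return(pmin(pmax(arr, 0), 1))
  nchan <- dim(arr)[3]
  if (nchan == 2L || nchan == 4L)
    stop_sflct("image %s has an alpha channel; flatten it before fusing", path)
  if (nchan != 3L) stop_sflct("unsupported channel count %d in %s", nchan, path)
  arr <- pmin(pmax(arr, 0), 1)
  rgb_image(arr[, , 1], arr[, , 2], arr[, , 3])
}

#' Write an image as 8-bit PNG
#'
#' Values are clipped to `[0, 1]` (with a logged warning when clipping
#' occurs) and quantized with round-half-away-from-zero.
#'
#' @param img Numeric matrix or [rgb_image].
#' @param path Output path (`.png`).
#' @return Invisibly, the path.
#' @export
write_image <- function(img, path) {
  q8 <- function(x) {
    n_out <- sum(x < 0 | x > 1)
    if (n_out > 0)
      sflct_log("WARNING", "write_image: clipped %d samples to [0,1]", n_out)
    x <- pmin(pmax(x, 0), 1)
    floor(x * 255 + 0.5) / 255          # round half away from zero (x >= 0)
  }
  if (inherits(img, "rgb_image")) {
    arr <- array(0, c(dim(img$r), 3L))
    arr[, , 1] <- q8(img$r); arr[, , 2] <- q8(img$g); arr[, , 3] <- q8(img$b)
    png::writePNG(arr, path)
  } else {
    png::writePNG(q8(img), path)
  }
  invisible(path)
}
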