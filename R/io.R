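#' Read a grayscale image (TIFF or PNG)
#'
#' 8- and 16-bit images are read to doubles in `[0, 1]`. Multi-channel
#' inputs are converted to luminance (Rec. 601 weights) with a warning.
#'
#' @param path file path; format chosen by extension (`.tif`, `.tiff`,
#'   `.png`).
#' @param pixel_scale um per pixel to attach to the image.
#' @return A [speckle_image()].
#' @export
read_gray_image <- function(path, pixel_scale = 20) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, " (use TIFF or PNG)"))
  if (length(dim(arr)) == 3) {
    warning("multi-channel image converted to luminance")
    nc <- dim(arr)[3]
    w <- if (nc >= 3) c(0.299, 0.587, 0.114) else rep(1 / nc, nc)
    m <- matrix(0, dim(arr)[1], dim(arr)[2])
    for (k in seq_len(min(nc, 3)))
      m <- m + w[k] * arr[, , k]
  } else {
    m <- arr
  }
  speckle_image(m, pixel_scale = pixel_scale)
}

#' Write a grayscale image (TIFF or PNG)
#'
#' @param image a [speckle_image()] or matrix in `[0, 1]`.
#' @param path output path; format chosen by extension.
#' @param bits 8 or 16 bits per sample.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path, bits = 8) {
  m <- pmin(pmax(image_pixels(image), 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (!bits %in% c(8, 16)) stop("bits must be 8 or 16")
  switch(ext,
    tif = , tiff = tiff::writeTIFF(m, path, bits.per.sample = bits),
    png = png::writePNG(m, path),
    stop("unsupported image format: .", ext, " (use TIFF or PNG)"))
  invisible(path)
}
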