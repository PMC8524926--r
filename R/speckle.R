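#' Speckle image object
#'
#' A grayscale intensity grid with a physical pixel scale. Intensities are
#' stored as doubles in `[0, 1]`; pixel `(x, y)` (zero-based, x = column
#' rightward, y = row downward) lives at `pixels[y + 1, x + 1]`.
#'
#' @param pixels numeric matrix of intensities (rows = image height).
#' @param pixel_scale physical size of one pixel in micrometres. The
#'   default 20 corresponds to the telecentric imaging setup the method
#'   was designed for (one pixel is approximately 20 um on the tooth
#'   surface).
#' @return An object of class `speckle_image`.
#' @export
speckle_image <- function(pixels, pixel_scale = 20) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column")
  if (!all(is.finite(pixels)))
    stop("all intensities must be finite")
  if (any(pixels < 0))
    stop("intensities must be non-negative")
  if (!is.numeric(pixel_scale) || length(pixel_scale) != 1L ||
      !is.finite(pixel_scale) || pixel_scale <= 0)
    stop("pixel_scale must be a single positive number (um/pixel)")
  structure(list(pixels = unname(pixels), pixel_scale = pixel_scale),
            class = "speckle_image")
}

#' @export
print.speckle_image <- function(x, ...) {
  cat(sprintf("<speckle_image> %d x %d px (%.3g x %.3g mm at %g um/px)\n",
              ncol(x$pixels), nrow(x$pixels),
              ncol(x$pixels) * x$pixel_scale / 1000,
              nrow(x$pixels) * x$pixel_scale / 1000, x$pixel_scale))
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              min(x$pixels), max(x$pixels), mean(x$pixels)))
  invisible(x)
}

#' @export
plot.speckle_image <- function(x, ...) {
  m <- x$pixels
  # transpose + row flip so the plot uses image coordinates (y downward)
  image(x = seq_len(ncol(m)) - 1, y = seq_len(nrow(m)) - 1,
        z = t(m[nrow(m):1, , drop = FALSE]),
        col = gray(seq(0, 1, length.out = 256)), asp = 1,
        xlab = "x (px)", ylab = "y (px)", useRaster = TRUE, ...)
  invisible(x)
}

#' @export
dim.speckle_image <- function(x) dim(x$pixels)

#' Generate a synthetic speckle pattern
#'
#' Renders dark, anti-aliased circular speckles at uniformly random centres
#' on a bright background, emulating an airbrushed ink speckle texture.
#' An optional mild Gaussian blur softens disk edges, as airbrushed paint
#' has no hard boundary.
#'
#' @param height,width image size in pixels.
#' @param speckle_diameter on-image dot diameter in pixels (>= 1). The
#'   physical dots of an airbrushed pattern can be smaller than one pixel;
#'   the diameter here is the effective on-image size and is free.
#' @param density expected number of dots per 100 x 100 pixel area. The
#'   default 400 with 4 px dots gives roughly 40% ink coverage, the
#'   mid-range of what speckle-pattern guidance for image correlation
#'   recommends; much sparser patterns leave subsets without texture and
#'   make matches ambiguous.
#' @param seed integer RNG seed; identical arguments give bit-identical
#'   images.
#' @param background,foreground background (bright) and dot (dark)
#'   intensities in `[0, 1]`.
#' @param blur_sigma standard deviation (px) of the post-render Gaussian
#'   blur; 0 disables it.
#' @param pixel_scale um per pixel, stored on the result.
#' @return A [speckle_image()].
#' @examples
#' img <- generate_speckle(128, 128, speckle_diameter = 4, density = 40,
#'                         seed = 1)
#' range(img$pixels)
#' @export
generate_speckle <- function(height, width, speckle_diameter = 4,
                             density = 400, seed = 1L,
                             background = 0.9, foreground = 0.1,
                             blur_sigma = 0.5, pixel_scale = 20) {
  if (height < 1 || width < 1)
    stop("height and width must be positive")
  if (speckle_diameter < 1)
    stop("speckle_diameter must be >= 1 px")
  if (density <= 0)
    stop("density must be > 0")
  n_dots <- max(0L, as.integer(round(density * height * width / 1e4)))
  img <- matrix(background, nrow = height, ncol = width)
  radius <- speckle_diameter / 2
  set.seed(as.integer(seed))
  cx <- runif(n_dots, -radius, width - 1 + radius)
  cy <- runif(n_dots, -radius, height - 1 + radius)
  rpx <- ceiling(radius + 1)
  for (i in seq_len(n_dots)) {
    xs <- max(0, floor(cx[i]) - rpx):min(width - 1, ceiling(cx[i]) + rpx)
    ys <- max(0, floor(cy[i]) - rpx):min(height - 1, ceiling(cy[i]) + rpx)
    if (!length(xs) || !length(ys)) next
    d <- sqrt(outer((ys - cy[i])^2, (xs - cx[i])^2, "+"))
    # coverage ramps linearly across the dot rim (one-pixel anti-aliasing)
    cov <- pmin(1, pmax(0, radius + 0.5 - d))
    sub <- img[ys + 1, xs + 1, drop = FALSE]
    img[ys + 1, xs + 1] <- sub + cov * (foreground - sub)
  }
  if (blur_sigma > 0)
    img <- gaussian_blur(img, blur_sigma)
  img <- pmin(pmax(img, 0), 1)
  speckle_image(img, pixel_scale = pixel_scale)
}

# small separable Gaussian blur with replicated borders
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(mat) {
    n <- nrow(mat)
    idx <- pmin(pmax(outer(seq_len(n), (-r):r, "+"), 1L), n)
    out <- matrix(0, n, ncol(mat))
    for (j in seq_along(k))
      out <- out + k[j] * mat[idx[, j], , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(m))))
}

#' Convert pixels to micrometres
#'
#' @param px displacement or length in pixels.
#' @param pixel_scale um per pixel (default 20).
#' @return value in micrometres.
#' @examples
#' px_to_um(6.2)  # 124 um
#' px_to_um(0.5)  # 10 um
#' @export
px_to_um <- function(px, pixel_scale = 20) px * pixel_scale

#' @rdname px_to_um
#' @param um length in micrometres.
#' @export
um_to_px <- function(um, pixel_scale = 20) um / pixel_scale
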