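#' DIC matching configuration
#'
#' Parameters of the subset-based matcher. Defaults follow common practice
#' for speckle imaging of tooth crowns at ~20 um/pixel: a 39 px subset
#' matched within a 69 px search region on a 4 px lattice, i.e. a +/-15 px
#' displacement range.
#'
#' @param subset_size odd subset (template) side length in px.
#' @param search_size odd search-region side length in px; the subset may
#'   land anywhere inside it, giving a displacement range of
#'   `(search_size - subset_size) / 2` px in each direction.
#' @param step lattice spacing of subset centres in px.
#' @param subpixel logical; refine the integer optimum by maximizing the
#'   correlation against bilinearly interpolated grey levels.
#' @param granularity finest fractional-step size (px) of the subpixel
#'   refinement.
#' @param correlation_floor minimum acceptable correlation in `[0, 1]`;
#'   points below it are flagged invalid.
#' @param prefilter_sigma standard deviation (px) of a Gaussian low-pass
#'   filter applied to both images before matching; 0 disables it.
#'   Speckle images are not band-limited, and matching a sharp template
#'   against an interpolated image then biases subpixel displacements
#'   toward integers (peak locking); a mild prefilter is the standard
#'   countermeasure and costs a ring of border points (the invalid
#'   margin grows by the filter radius).
#' @return An object of class `dic_config`.
#' @export
dic_config <- function(subset_size = 39, search_size = 69, step = 4,
                       subpixel = TRUE, granularity = 0.005,
                       correlation_floor = 0.5, prefilter_sigma = 1.5) {
  subset_size <- as.integer(subset_size)
  search_size <- as.integer(search_size)
  step <- as.integer(step)
  if (subset_size %% 2L == 0L || search_size %% 2L == 0L)
    stop("subset_size and search_size must be odd")
  if (subset_size >= search_size)
    stop("subset_size must be smaller than search_size")
  if (step < 1L) stop("step must be >= 1")
  if (correlation_floor < 0 || correlation_floor > 1)
    stop("correlation_floor must be in [0, 1]")
  if (subpixel && (granularity <= 0 || granularity > 0.5))
    stop("granularity must be in (0, 0.5]")
  if (prefilter_sigma < 0) stop("prefilter_sigma must be >= 0")
  structure(list(subset_size = subset_size, search_size = search_size,
                 step = step, subpixel = isTRUE(subpixel),
                 granularity = granularity,
                 correlation_floor = correlation_floor,
                 prefilter_sigma = prefilter_sigma),
            class = "dic_config")
}

#' @export
print.dic_config <- function(x, ...) {
  cat(sprintf(paste0("<dic_config> subset %d px, search %d px ",
                     "(range +/-%d px), step %d px, subpixel %s",
                     " (granularity %g px), floor %g\n"),
              x$subset_size, x$search_size,
              (x$search_size - x$subset_size) %/% 2L, x$step,
              if (x$subpixel) "on" else "off", x$granularity,
              x$correlation_floor))
  invisible(x)
}

#' Normalized cross-correlation of two equal-size patches
#'
#' The correlation coefficient is the sum of intensity products over the
#' geometric mean of the two patch energies,
#' `C = sum(T * I) / sqrt(sum(T^2) * sum(I^2))`. For non-negative
#' intensities `C` lies in `[0, 1]`, equals 1 for a perfect match, and is
#' invariant to multiplying either patch by a positive constant.
#'
#' @param template,region numeric matrices of identical dimensions.
#' @return The correlation value, or `NA` if either patch has zero energy
#'   (the denominator is undefined; callers should flag such points
#'   invalid).
#' @examples
#' p <- matrix(c(1, 0, 0, 0), 2)
#' ncc(p, p)       # 1: perfect match
#' ncc(p, 2 * p)   # 1: scale invariance
#' @export
ncc <- function(template, region) {
  template <- as.matrix(template); region <- as.matrix(region)
  if (!all(dim(template) == dim(region)))
    stop("template and region must have identical dimensions")
  .ncc_cpp(template, region)
}

image_pixels <- function(x) {
  if (inherits(x, "speckle_image")) x$pixels else as.matrix(x)
}

# apply the matcher's low-pass prefilter to an image pair; returns the
# two matrices plus the extra invalid margin the filter support costs
prefilter_pair <- function(ref, def, sigma) {
  if (sigma <= 0)
    return(list(ref = ref, def = def, margin = 0L))
  list(ref = gaussian_blur(ref, sigma), def = gaussian_blur(def, sigma),
       margin = as.integer(ceiling(3 * sigma)))
}

#' Match one subset between a reference and a deformed image
#'
#' Exhaustive integer-offset NCC search over the search window (the
#' window is small enough that the coarse stage can afford to be
#' exhaustive), followed by subpixel refinement on a shrinking fractional
#' grid evaluated against bilinearly interpolated grey levels of the
#' deformed image. Ties in the integer stage go to the smallest-magnitude
#' displacement so the output is deterministic.
#'
#' @param reference,deformed [speckle_image()]s (or plain matrices) of
#'   identical size.
#' @param center subset centre `c(x, y)` in zero-based px.
#' @param config a [dic_config()].
#' @return list with `u`, `v` (px, deformed minus reference position),
#'   `c` (correlation at the optimum) and `valid`. Points whose search
#'   window leaves the image, whose subset is constant, or whose
#'   correlation falls below the floor are invalid (`u`, `v`, `c` = NA).
#' @export
match_subset <- function(reference, deformed, center,
                         config = dic_config()) {
  ref <- image_pixels(reference); def <- image_pixels(deformed)
  if (!all(dim(ref) == dim(def)))
    stop("reference and deformed images must share dimensions")
  pf <- prefilter_pair(ref, def, config$prefilter_sigma)
  m <- .match_subset_cpp(pf$ref, pf$def, as.integer(center[1]),
                         as.integer(center[2]),
                         config$subset_size, config$search_size,
                         config$subpixel, config$granularity,
                         config$correlation_floor, pf$margin)
  list(u = m[1], v = m[2], c = m[3], valid = m[4] == 1)
}

#' Displacement field container
#'
#' A regular lattice of subset centres with per-point horizontal (`u`) and
#' vertical (`v`) displacement in px, correlation quality `c` and a
#' validity flag. Matrices are indexed `[iy, ix]` matching `grid_y` and
#' `grid_x`.
#'
#' @param grid_x,grid_y lattice coordinates (px) of subset centres.
#' @param u,v,c displacement components (px) and correlation, as
#'   `length(grid_y) x length(grid_x)` matrices.
#' @param valid logical matrix of the same shape.
#' @param step lattice spacing (px); inferred from `grid_x` if missing.
#' @param pixel_scale um per pixel.
#' @param config optional [dic_config()] used to produce the field.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(grid_x, grid_y, u, v,
                               c = NULL, valid = NULL, step = NULL,
                               pixel_scale = 20, config = NULL) {
  u <- as.matrix(u); v <- as.matrix(v)
  ny <- length(grid_y); nx <- length(grid_x)
  if (!all(dim(u) == c(ny, nx)) || !all(dim(v) == c(ny, nx)))
    stop("u and v must be length(grid_y) x length(grid_x) matrices")
  if (is.null(c)) c <- matrix(1, ny, nx)
  if (is.null(valid)) valid <- is.finite(u) & is.finite(v)
  if (is.null(step))
    step <- if (nx > 1) diff(grid_x)[1] else if (ny > 1) diff(grid_y)[1] else 1
  structure(list(grid_x = grid_x, grid_y = grid_y, u = u, v = v, c = c,
                 valid = valid, step = step, pixel_scale = pixel_scale,
                 config = config),
            class = "displacement_field")
}

#' Subset-centre lattice of a region of interest
#'
#' The placement rule behind [compute_displacement_field()]: the first
#' centre sits at `roi origin + subset_size %/% 2` and centres follow
#' every `step` px while the subset stays inside the ROI, giving
#' `floor((extent - subset_size) / step) + 1` sites per axis.
#'
#' @param roi `c(x, y, width, height)` in zero-based px.
#' @param subset_size odd subset side length (px).
#' @param step lattice spacing (px).
#' @return list with `grid_x` and `grid_y` centre coordinates.
#' @export
dic_lattice <- function(roi, subset_size, step) {
  half <- subset_size %/% 2L
  if (roi[3] < subset_size || roi[4] < subset_size)
    stop("ROI is too small for a single subset (", subset_size, " px)")
  list(grid_x = seq(roi[1] + half, roi[1] + roi[3] - 1 - half, by = step),
       grid_y = seq(roi[2] + half, roi[2] + roi[4] - 1 - half, by = step))
}

#' Compute the displacement field of an image pair
#'
#' Places subset centres on a regular lattice over the region of interest
#' and matches each with [match_subset()]. The first centre sits at
#' `roi origin + subset_size %/% 2`, subsequent centres every `step` px;
#' along each axis the number of lattice sites is
#' `floor((roi_extent - subset_size) / step) + 1`. Centres whose search
#' window leaves the image are kept on the lattice but marked invalid.
#'
#' @param reference,deformed [speckle_image()]s of identical size.
#' @param roi region of interest `c(x, y, width, height)` in zero-based
#'   px; default covers the whole image.
#' @param config a [dic_config()].
#' @return A [displacement_field()].
#' @examples
#' ref <- generate_speckle(96, 96, seed = 3)
#' def <- warp_image(ref, deformation_spec("translation",
#'                                         translation = c(2, 1)))
#' f <- compute_displacement_field(ref, def,
#'        config = dic_config(subset_size = 21, search_size = 31,
#'                            step = 8))
#' summary(f)
#' @export
compute_displacement_field <- function(reference, deformed, roi = NULL,
                                       config = dic_config()) {
  ref <- image_pixels(reference); def <- image_pixels(deformed)
  if (!all(dim(ref) == dim(def)))
    stop("reference and deformed images must share dimensions")
  H <- nrow(ref); W <- ncol(ref)
  if (is.null(roi)) roi <- c(0, 0, W, H)
  lat <- dic_lattice(roi, config$subset_size, config$step)
  grid_x <- lat$grid_x
  grid_y <- lat$grid_y
  pts <- expand.grid(x = grid_x, y = grid_y) # x varies fastest
  pf <- prefilter_pair(ref, def, config$prefilter_sigma)
  res <- .match_grid_cpp(pf$ref, pf$def, as.integer(pts$x),
                         as.integer(pts$y),
                         config$subset_size, config$search_size,
                         config$subpixel, config$granularity,
                         config$correlation_floor, pf$margin)
  nx <- length(grid_x); ny <- length(grid_y)
  shape <- function(col) matrix(res[, col], nrow = ny, ncol = nx,
                                byrow = TRUE)
  ps <- if (inherits(reference, "speckle_image")) reference$pixel_scale else 20
  displacement_field(grid_x, grid_y, u = shape(1), v = shape(2),
                     c = shape(3), valid = shape(4) == 1,
                     step = config$step, pixel_scale = ps, config = config)
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field> %d x %d grid points, step %g px\n",
              length(x$grid_x), length(x$grid_y), x$step))
  nv <- sum(x$valid)
  cat(sprintf("  valid: %d/%d (%.1f%%)\n", nv, length(x$valid),
              100 * nv / length(x$valid)))
  if (nv > 0)
    cat(sprintf("  u in [%.3f, %.3f] px, v in [%.3f, %.3f] px, mean c %.4f\n",
                min(x$u[x$valid]), max(x$u[x$valid]),
                min(x$v[x$valid]), max(x$v[x$valid]),
                mean(x$c[x$valid])))
  invisible(x)
}

#' @export
summary.displacement_field <- function(object, ...) {
  v <- object$valid
  out <- list(
    n_points = length(v), n_valid = sum(v),
    u = if (any(v)) summary(object$u[v]) else NULL,
    v = if (any(v)) summary(object$v[v]) else NULL,
    mean_correlation = if (any(v)) mean(object$c[v]) else NA_real_,
    mean_magnitude_px = if (any(v))
      mean(sqrt(object$u[v]^2 + object$v[v]^2)) else NA_real_)
  class(out) <- "summary.displacement_field"
  out
}

#' @export
print.summary.displacement_field <- function(x, ...) {
  cat(sprintf("Displacement field: %d/%d valid points\n", x$n_valid,
              x$n_points))
  if (!is.null(x$u)) {
    cat("u (px):\n"); print(x$u)
    cat("v (px):\n"); print(x$v)
    cat(sprintf("mean correlation %.4f, mean |d| %.4f px\n",
                x$mean_correlation, x$mean_magnitude_px))
  }
  invisible(x)
}

#' @export
plot.displacement_field <- function(x, component = c("v", "u", "c",
                                                     "magnitude"), ...) {
  component <- match.arg(component)
  m <- switch(component, u = x$u, v = x$v, c = x$c,
              magnitude = sqrt(x$u^2 + x$v^2))
  m[!x$valid] <- NA
  image(x = x$grid_x, y = x$grid_y, z = t(m),
        col = grDevices::hcl.colors(64, "viridis"), asp = 1,
        xlab = "x (px)", ylab = "y (px)",
        main = paste("displacement:", component), useRaster = TRUE, ...)
  invisible(x)
}

#' @export
as.data.frame.displacement_field <- function(x, ...) {
  d <- expand.grid(x = x$grid_x, y = x$grid_y)
  data.frame(x = d$x, y = d$y,
             u = as.vector(t(x$u)), v = as.vector(t(x$v)),
             c = as.vector(t(x$c)), valid = as.vector(t(x$valid)))
}

#' Median-filter a displacement field
#'
#' Component-wise median filtering of `u` and `v` over the lattice, the
#' standard despiking step before strain estimation. Invalid points are
#' excluded from every window and stay invalid.
#'
#' @param field a [displacement_field()].
#' @param kernel odd window side length in grid points; 1 is the
#'   identity.
#' @return The filtered [displacement_field()].
#' @export
median_filter_field <- function(field, kernel = 3) {
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L)
    stop("kernel must be an odd integer >= 1")
  if (kernel == 1L) return(field)
  h <- kernel %/% 2L
  ny <- length(field$grid_y); nx <- length(field$grid_x)
  u <- field$u; v <- field$v
  for (iy in seq_len(ny)) {
    ys <- max(1, iy - h):min(ny, iy + h)
    for (ix in seq_len(nx)) {
      if (!field$valid[iy, ix]) next
      xs <- max(1, ix - h):min(nx, ix + h)
      w <- field$valid[ys, xs]
      u[iy, ix] <- median(field$u[ys, xs][w])
      v[iy, ix] <- median(field$v[ys, xs][w])
    }
  }
  field$u <- u; field$v <- v
  field
}

#' Random-error metric of a static image series
#'
#' For each field of a static series (nominally zero deformation) the
#' mean displacement magnitude over valid grid points,
#' `g = mean(sqrt(u^2 + v^2))`, measures the random error of the
#' correlation system; the series is summarized by the mean, variance and
#' standard deviation of `g`.
#'
#' @param fields a [displacement_field()] or list of them sharing a grid.
#' @return list with `g` (per-field values, px), `mean`, `variance`, `sd`,
#'   and `g_um` (per-field values in um), of class `static_series_error`.
#' @export
static_series_error <- function(fields) {
  if (inherits(fields, "displacement_field")) fields <- list(fields)
  if (!length(fields)) stop("need at least one displacement field")
  if (!all(vapply(fields, inherits, TRUE, "displacement_field")))
    stop("fields must be displacement_field objects")
  g <- vapply(fields, function(f) {
    v <- f$valid
    if (!any(v)) return(NA_real_)
    mean(sqrt(f$u[v]^2 + f$v[v]^2))
  }, numeric(1))
  ps <- fields[[1]]$pixel_scale
  structure(list(g = g, g_um = g * ps, mean = mean(g),
                 variance = if (length(g) > 1) var(g) else 0,
                 sd = if (length(g) > 1) sd(g) else 0),
            class = "static_series_error")
}

#' @export
print.static_series_error <- function(x, ...) {
  cat(sprintf(paste0("<static_series_error> %d field(s): g in ",
                     "[%.4g, %.4g] px, mean %.4g px, variance %.4g\n"),
              length(x$g), min(x$g), max(x$g), x$mean, x$variance))
  invisible(x)
}
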