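#' Local first-order plane fit of a displacement window
#'
#' Fits `u ~ a0 + a1*x + a2*y` and `v ~ b0 + b1*x + b2*y` by least squares
#' over a square window of lattice points, in local px coordinates
#' centred on the fit point, so `a1 = du/dx`, `a2 = du/dy`, `b1 = dv/dx`,
#' `b2 = dv/dy` directly. Solved via the pseudo-inverse of the local
#' coordinate matrix (QR-based). Windows are truncated at the field
#' border; the fit is refused (NULL) when fewer than 3 valid points remain
#' or the points are collinear.
#'
#' @param field a [displacement_field()].
#' @param center grid index `c(ix, iy)` (1-based column/row into
#'   `grid_x`/`grid_y`).
#' @param window odd window side length in grid points (default 5).
#' @return list with coefficients `a0, a1, a2, b0, b1, b2` and the number
#'   of points used, of class `plane_fit`; or `NULL` when the window is
#'   rank deficient.
#' @export
local_plane_fit <- function(field, center, window = 5) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1 grid point")
  h <- window %/% 2L
  ix <- center[1]; iy <- center[2]
  nx <- length(field$grid_x); ny <- length(field$grid_y)
  xs <- max(1, ix - h):min(nx, ix + h)
  ys <- max(1, iy - h):min(ny, iy + h)
  w <- field$valid[ys, xs, drop = FALSE]
  if (sum(w) < 3) return(NULL)
  # local coordinates in px, centred on the fit point
  X <- outer(rep(1, length(ys)), field$grid_x[xs] - field$grid_x[ix])[w]
  Y <- outer(field$grid_y[ys] - field$grid_y[iy], rep(1, length(xs)))[w]
  P <- cbind(1, X, Y)
  qrP <- qr(P)
  if (qrP$rank < 3) return(NULL)
  a <- unname(qr.coef(qrP, field$u[ys, xs, drop = FALSE][w]))
  b <- unname(qr.coef(qrP, field$v[ys, xs, drop = FALSE][w]))
  structure(list(a0 = a[1], a1 = a[2], a2 = a[3],
                 b0 = b[1], b1 = b[2], b2 = b[3],
                 n_points = sum(w)),
            class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf("<plane_fit> u: %.4g %+.4g x %+.4g y | v: %.4g %+.4g x %+.4g y (%d pts)\n",
              x$a0, x$a1, x$a2, x$b0, x$b1, x$b2, x$n_points))
  invisible(x)
}

#' Principal strains of the 2D infinitesimal strain state
#'
#' `eps_1,2 = (eps_x + eps_y)/2 +/- sqrt(((eps_x - eps_y)/2)^2 +
#' (gamma_xy/2)^2)` with `eps_1 >= eps_2`. The maximum principal strain
#' highlights a crack regardless of its orientation, which is why crack
#' extraction operates on `eps_1` rather than on a unidirectional
#' component.
#'
#' @param eps_x,eps_y normal strains (dimensionless), vectors or matrices.
#' @param gamma_xy engineering shear strain `du/dy + dv/dx`.
#' @return list with `eps_1` (max) and `eps_2` (min), same shape as input.
#' @examples
#' principal_strain(0.004, 0, 0)    # (0.004, 0)
#' principal_strain(0, 0, 0.002)    # (0.001, -0.001)
#' @export
principal_strain <- function(eps_x, eps_y, gamma_xy) {
  m <- (eps_x + eps_y) / 2
  r <- sqrt(((eps_x - eps_y) / 2)^2 + (gamma_xy / 2)^2)
  list(eps_1 = m + r, eps_2 = m - r)
}

#' Strain field from a displacement field
#'
#' At every lattice point, a windowed least-squares plane fit
#' ([local_plane_fit()]) of the displacement components gives the
#' displacement gradients with respect to pixel coordinates, from which
#' `eps_x = du/dx`, `eps_y = dv/dy` and the engineering shear
#' `gamma_xy = du/dy + dv/dx` follow, plus principal strains via
#' [principal_strain()]. Strains are reported in image coordinates
#' (y downward); no axis flip is applied.
#'
#' @param field a [displacement_field()] (median filtering, if wanted,
#'   is applied beforehand with [median_filter_field()]).
#' @param window odd fit-window side length in grid points (default 5,
#'   balancing noise suppression against smearing of the crack
#'   signature).
#' @return An object of class `strain_field` with `grid_x`, `grid_y`,
#'   matrices `eps_x`, `eps_y`, `gamma_xy`, `eps_1`, `eps_2` and `valid`.
#' @examples
#' f <- analytic_displacement_field(
#'   deformation_spec("affine", dudx = 0.005),
#'   grid_x = seq(20, 100, 4), grid_y = seq(20, 100, 4))
#' s <- strain_from_displacement(f)
#' range(s$eps_x[s$valid])  # 0.005
#' @export
strain_from_displacement <- function(field, window = 5) {
  nx <- length(field$grid_x); ny <- length(field$grid_y)
  eps_x <- eps_y <- gxy <- matrix(NA_real_, ny, nx)
  ok <- matrix(FALSE, ny, nx)
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      if (!field$valid[iy, ix]) next
      fit <- local_plane_fit(field, c(ix, iy), window = window)
      if (is.null(fit)) next
      eps_x[iy, ix] <- fit$a1
      eps_y[iy, ix] <- fit$b2
      gxy[iy, ix] <- fit$a2 + fit$b1
      ok[iy, ix] <- TRUE
    }
  }
  pr <- principal_strain(eps_x, eps_y, gxy)
  structure(list(grid_x = field$grid_x, grid_y = field$grid_y,
                 eps_x = eps_x, eps_y = eps_y, gamma_xy = gxy,
                 eps_1 = pr$eps_1, eps_2 = pr$eps_2, valid = ok,
                 step = field$step, pixel_scale = field$pixel_scale,
                 window = window),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("<strain_field> %d x %d grid points (window %d)\n",
              length(x$grid_x), length(x$grid_y), x$window))
  if (any(x$valid))
    cat(sprintf("  eps_1 in [%.4g, %.4g], eps_2 in [%.4g, %.4g]\n",
                min(x$eps_1[x$valid]), max(x$eps_1[x$valid]),
                min(x$eps_2[x$valid]), max(x$eps_2[x$valid])))
  invisible(x)
}

#' @export
plot.strain_field <- function(x, component = c("eps_1", "eps_2", "eps_x",
                                               "eps_y", "gamma_xy"), ...) {
  component <- match.arg(component)
  m <- x[[component]]
  m[!x$valid] <- NA
  image(x = x$grid_x, y = x$grid_y, z = t(m),
        col = grDevices::hcl.colors(64, "viridis"), asp = 1,
        xlab = "x (px)", ylab = "y (px)", main = paste("strain:", component),
        useRaster = TRUE, ...)
  invisible(x)
}

#' @export
as.data.frame.strain_field <- function(x, ...) {
  d <- expand.grid(x = x$grid_x, y = x$grid_y)
  data.frame(x = d$x, y = d$y,
             eps_x = as.vector(t(x$eps_x)), eps_y = as.vector(t(x$eps_y)),
             gamma_xy = as.vector(t(x$gamma_xy)),
             eps_1 = as.vector(t(x$eps_1)), eps_2 = as.vector(t(x$eps_2)),
             valid = as.vector(t(x$valid)))
}

#' Displacement field evaluated from an analytic deformation
#'
#' Samples the ground-truth displacement function of a
#' [deformation_spec()] on a lattice, producing an ideal (noise-free,
#' fully valid) [displacement_field()]. Used to validate the strain and
#' crack-kinematics stages independently of the matcher.
#'
#' @param spec a [deformation_spec()].
#' @param grid_x,grid_y lattice coordinates in px.
#' @param pixel_scale um per pixel.
#' @return A [displacement_field()].
#' @export
analytic_displacement_field <- function(spec, grid_x, grid_y,
                                        pixel_scale = 20) {
  f <- displacement_function(spec)
  pts <- expand.grid(x = grid_x, y = grid_y)
  uv <- f(pts$x, pts$y)
  nx <- length(grid_x); ny <- length(grid_y)
  displacement_field(grid_x, grid_y,
                     u = matrix(uv[, 1], ny, nx, byrow = TRUE),
                     v = matrix(uv[, 2], ny, nx, byrow = TRUE),
                     pixel_scale = pixel_scale)
}
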