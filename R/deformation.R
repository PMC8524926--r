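#' Analytic deformation specification
#'
#' Describes a ground-truth displacement field used to warp a reference
#' speckle image into a synthetic "deformed" image. Four kinds are
#' supported:
#' \describe{
#'   \item{translation}{rigid translation by `translation = c(tx, ty)` px.}
#'   \item{affine}{linear field `u = tx + dudx*x + dudy*y`,
#'     `v = ty + dvdx*x + dvdy*y` (gradients dimensionless).}
#'   \item{crack}{piecewise-rigid field discontinuous across a polyline
#'     `path` (n x 2 matrix of (x, y) px). The face on the negative side of
#'     the path normal (face A) and the positive side (face B) each undergo
#'     a rigid motion; the jump across the path equals `opening` px along
#'     the path normal (A to B) plus `slip` px along the tangent, split
#'     symmetrically between the faces, composed with per-face rotations
#'     `rotation_A`/`rotation_B` (radians) about `reference_A`/
#'     `reference_B` (default: the path midpoint).}
#'   \item{composite}{sum of the displacement fields of `components`, a
#'     list of deformation specs.}
#' }
#'
#' @param kind one of `"translation"`, `"affine"`, `"crack"`,
#'   `"composite"`.
#' @param ... kind-specific parameters, see Details above.
#' @param noise_sigma standard deviation of additive i.i.d. Gaussian
#'   intensity noise applied by [warp_image()] after warping, in intensity
#'   units (images live in `[0, 1]`).
#' @param seed integer seed for the noise.
#' @return An object of class `deformation_spec`.
#' @examples
#' deformation_spec("translation", translation = c(3, 2))
#' deformation_spec("crack",
#'   path = cbind(c(64, 64), c(0, 127)), opening = 0.5)
#' @export
deformation_spec <- function(kind = c("translation", "affine", "crack",
                                      "composite"),
                             ..., noise_sigma = 0, seed = 1L) {
  kind <- match.arg(kind)
  p <- list(...)
  defaults <- switch(kind,
    translation = list(translation = c(0, 0)),
    affine = list(translation = c(0, 0), dudx = 0, dudy = 0,
                  dvdx = 0, dvdy = 0),
    crack = list(path = NULL, opening = 0, slip = 0,
                 rotation_A = 0, rotation_B = 0,
                 reference_A = NULL, reference_B = NULL),
    composite = list(components = list()))
  unknown <- setdiff(names(p), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s) for kind '", kind, "': ",
         paste(unknown, collapse = ", "))
  # plain merge: modifyList would recurse into list-valued parameters
  # (e.g. the components of a composite) and mangle them
  for (nm in names(defaults))
    if (!nm %in% names(p)) p[[nm]] <- defaults[[nm]]
  if (kind == "crack") {
    if (is.null(p$path) || !is.matrix(p$path) || ncol(p$path) != 2 ||
        nrow(p$path) < 2)
      stop("a crack spec needs 'path', an n x 2 (x, y) matrix with n >= 2")
    mid <- colMeans(p$path)
    if (is.null(p$reference_A)) p$reference_A <- mid
    if (is.null(p$reference_B)) p$reference_B <- mid
  }
  if (kind == "composite") {
    if (!length(p$components) ||
        !all(vapply(p$components, inherits, TRUE, "deformation_spec")))
      stop("composite needs a non-empty list of deformation_spec components")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(kind = kind, parameters = p,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "deformation_spec")
}

#' @export
print.deformation_spec <- function(x, ...) {
  cat(sprintf("<deformation_spec> kind = %s, noise_sigma = %g, seed = %d\n",
              x$kind, x$noise_sigma, x$seed))
  invisible(x)
}

# signed distance helpers ---------------------------------------------------

# distance from points (qx, qy) to a polyline, plus the side sign:
# positive on the side the segment normal (-ty, tx)... points toward.
# Used both for the crack deformation field and for skeleton comparison.
polyline_distance <- function(qx, qy, path, signed = FALSE) {
  n <- nrow(path)
  best <- rep(Inf, length(qx))
  side <- rep(0, length(qx))
  for (i in seq_len(n - 1)) {
    p1 <- path[i, ]; p2 <- path[i + 1, ]
    dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
    len2 <- dx * dx + dy * dy
    if (len2 == 0) next
    t <- pmin(1, pmax(0, ((qx - p1[1]) * dx + (qy - p1[2]) * dy) / len2))
    ex <- qx - (p1[1] + t * dx); ey <- qy - (p1[2] + t * dy)
    d2 <- ex * ex + ey * ey
    hit <- d2 < best
    best[hit] <- d2[hit]
    if (signed) {
      cr <- dx * (qy - p1[2]) - dy * (qx - p1[1])
      side[hit] <- sign(cr[hit])
    }
  }
  d <- sqrt(best)
  if (signed) list(distance = d, side = side) else d
}

#' Evaluate the ground-truth displacement field of a deformation spec
#'
#' @param spec a [deformation_spec()].
#' @return A function `f(x, y)` taking vectors of pixel coordinates and
#'   returning a two-column matrix `cbind(u, v)` in px.
#' @examples
#' f <- displacement_function(deformation_spec("translation",
#'                                             translation = c(3, 2)))
#' f(10, 20)  # (3, 2)
#' @export
displacement_function <- function(spec) {
  if (!inherits(spec, "deformation_spec"))
    stop("spec must be a deformation_spec")
  p <- spec$parameters
  switch(spec$kind,
    translation = function(x, y) {
      cbind(u = rep(p$translation[1], length(x)),
            v = rep(p$translation[2], length(x)))
    },
    affine = function(x, y) {
      cbind(u = p$translation[1] + p$dudx * x + p$dudy * y,
            v = p$translation[2] + p$dvdx * x + p$dvdy * y)
    },
    crack = {
      path <- p$path
      # unit tangent/normal of the overall path direction; the normal
      # points from face A toward face B
      dirv <- path[nrow(path), ] - path[1, ]
      tv <- dirv / sqrt(sum(dirv^2))
      nv <- c(-tv[2], tv[1])
      jump <- p$opening * nv + p$slip * tv
      function(x, y) {
        s <- polyline_distance(x, y, path, signed = TRUE)$side
        # points exactly on the path are assigned to face A
        s[s == 0] <- -1
        u <- numeric(length(x)); v <- numeric(length(x))
        for (face in c(-1, 1)) {
          idx <- s == face
          if (!any(idx)) next
          if (face < 0) {
            tr <- -jump / 2; th <- p$rotation_A; ref <- p$reference_A
          } else {
            tr <- jump / 2; th <- p$rotation_B; ref <- p$reference_B
          }
          rx <- x[idx] - ref[1]; ry <- y[idx] - ref[2]
          u[idx] <- tr[1] + (cos(th) - 1) * rx - sin(th) * ry
          v[idx] <- tr[2] + sin(th) * rx + (cos(th) - 1) * ry
        }
        cbind(u = u, v = v)
      }
    },
    composite = {
      fns <- lapply(p$components, displacement_function)
      function(x, y) {
        out <- matrix(0, length(x), 2, dimnames = list(NULL, c("u", "v")))
        for (f in fns) out <- out + f(x, y)
        out
      }
    })
}

#' Warp a speckle image by an analytic deformation field
#'
#' Produces the synthetic deformed image by inverse mapping: the output
#' intensity at pixel `(x, y)` is the reference image sampled bilinearly
#' at `(x, y) - u(x, y)`, with the displacement field evaluated at the
#' target pixel (exact for translations and for the small piecewise-rigid
#' motions used here). Samples falling outside the reference are set to
#' `fill`. Additive Gaussian noise of sd `spec$noise_sigma` is then applied
#' under `spec$seed` and intensities are clipped to `[0, 1]`.
#'
#' @param image a [speckle_image()].
#' @param spec a [deformation_spec()].
#' @param fill intensity for out-of-domain samples (default 0).
#' @return A [speckle_image()] of the same size.
#' @export
warp_image <- function(image, spec, fill = 0) {
  if (!inherits(image, "speckle_image")) stop("image must be a speckle_image")
  m <- image$pixels
  H <- nrow(m); W <- ncol(m)
  f <- displacement_function(spec)
  xs <- rep(0:(W - 1), each = H)
  ys <- rep(0:(H - 1), times = W)
  uv <- f(xs, ys)
  sx <- xs - uv[, 1]
  sy <- ys - uv[, 2]
  out <- bilinear_sample(m, sx, sy, fill = fill)
  out <- matrix(out, nrow = H, ncol = W)
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    out <- out + matrix(rnorm(H * W, sd = spec$noise_sigma), H, W)
  }
  out <- pmin(pmax(out, 0), 1)
  speckle_image(out, pixel_scale = image$pixel_scale)
}

# vectorized bilinear sampling of matrix m at zero-based (x, y); exact at
# integer coordinates (no floating-point blending is applied there)
bilinear_sample <- function(m, x, y, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  ok <- x >= 0 & y >= 0 & x <= W - 1 & y <= H - 1
  out <- rep(fill, length(x))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  i00 <- m[cbind(y0 + 1, x0 + 1)]
  i10 <- m[cbind(y0 + 1, x1 + 1)]
  i01 <- m[cbind(y1 + 1, x0 + 1)]
  i11 <- m[cbind(y1 + 1, x1 + 1)]
  val <- i00 * (1 - fx) * (1 - fy) + i10 * fx * (1 - fy) +
         i01 * (1 - fx) * fy + i11 * fx * fy
  exact <- fx == 0 & fy == 0
  val[exact] <- i00[exact]
  out[ok] <- val
  out
}
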