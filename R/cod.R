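#' Partition displacement grid points into the two crack faces
#'
#' Around a skeleton point the crack is approximated by its local tangent
#' line; valid displacement grid points near the point are split by the
#' sign of their across-crack offset into face A (negative side of the
#' normal) and face B (positive side). Points inside the exclusion band
#' are dropped: their matched subsets straddle the discontinuity and mix
#' the motion of both faces. The usable face depth extends `window` grid
#' points beyond the band on each side.
#'
#' @param point skeleton point `c(x, y)` in px.
#' @param tangent local crack tangent angle in radians.
#' @param field a [displacement_field()].
#' @param window face depth in grid points beyond the exclusion band
#'   (default 7).
#' @param exclusion_band half-width (px) of the dropped strip along the
#'   crack; defaults to half the matcher's subset size when the field
#'   carries its configuration, else half a lattice step.
#' @return list with data frames `A` and `B` (columns x, y, u, v).
#' @export
split_faces <- function(point, tangent, field, window = 7,
                        exclusion_band = NULL) {
  if (window < 1) stop("window must be >= 1 grid point")
  if (is.null(exclusion_band))
    exclusion_band <- if (!is.null(field$config))
      field$config$subset_size / 2 else field$step / 2
  reach <- exclusion_band + window * field$step
  tv <- c(cos(tangent), sin(tangent))
  nv <- c(-tv[2], tv[1])
  d <- as.data.frame(field)
  d <- d[d$valid, , drop = FALSE]
  dx <- d$x - point[1]; dy <- d$y - point[2]
  along <- dx * tv[1] + dy * tv[2]
  across <- dx * nv[1] + dy * nv[2]
  near <- abs(along) <= reach & abs(across) <= reach &
    abs(across) > exclusion_band
  list(A = d[near & across < 0, c("x", "y", "u", "v")],
       B = d[near & across > 0, c("x", "y", "u", "v")])
}

#' Rigid-body motion fit of one crack face
#'
#' Least-squares fit of a small-rotation rigid motion
#' `u = tx - theta * (y - ry)`, `v = ty + theta * (x - rx)` to the
#' displacement samples of one face; `(tx, ty)` is the face's lip
#' displacement at the reference point and `theta` its rotation. Exact
#' when the samples come from such a motion. At least three
#' non-collinear points are required; collinear sets are rejected
#' (returning `NULL`) since a face estimate from points on a single line
#' is too fragile to trust.
#'
#' @param points data frame with columns `x`, `y`, `u`, `v`.
#' @param reference_point `c(x, y)` px; defaults to the points' centroid.
#' @return list (`face_motion`) with `lip_displacement`, `rotation`,
#'   `reference_point`, `n_points`; or `NULL` if the fit is not possible.
#' @export
fit_face_motion <- function(points, reference_point = NULL) {
  if (nrow(points) < 3) return(NULL)
  if (is.null(reference_point))
    reference_point <- c(mean(points$x), mean(points$y))
  dx <- points$x - reference_point[1]
  dy <- points$y - reference_point[2]
  # collinearity: the smaller principal extent of the point cloud
  cv <- cbind(dx - mean(dx), dy - mean(dy))
  ev <- eigen(crossprod(cv) / nrow(cv), symmetric = TRUE,
              only.values = TRUE)$values
  if (ev[2] < 1e-9 * max(ev[1], 1)) return(NULL)
  n <- nrow(points)
  # stacked system for (tx, ty, theta)
  A <- rbind(cbind(1, 0, -dy),
             cbind(0, 1, dx))
  rhs <- c(points$u, points$v)
  coef <- unname(qr.coef(qr(A), rhs))
  structure(list(lip_displacement = c(coef[1], coef[2]),
                 rotation = coef[3],
                 reference_point = reference_point,
                 n_points = n),
            class = "face_motion")
}

#' Displacement of a fitted face at a point
#'
#' Evaluates the face's rigid motion at `point`: the lip displacement
#' plus the rotation term `(R - I) (point - reference)`, i.e. the face
#' displacement of the crack kinematic model expressed with the position
#' vector taken from the face's reference point. The rotation is applied
#' in the same small-angle linearization the fit uses
#' (`R - I ~ [[0, -theta], [theta, 0]]`), keeping estimator and
#' evaluation consistent so a globally rigid field yields an exactly
#' zero relative displacement.
#'
#' @param face a `face_motion` from [fit_face_motion()].
#' @param point `c(x, y)` px.
#' @return displacement `c(u, v)` in px.
#' @export
face_displacement_at <- function(face, point) {
  th <- face$rotation
  p <- c(point[1] - face$reference_point[1],
         point[2] - face$reference_point[2])
  face$lip_displacement + c(-th * p[2], th * p[1])
}

#' Relative displacement between the two crack faces at a point
#'
#' `delta = delta_B - delta_A`, each face's displacement evaluated at the
#' skeleton point from its fitted rigid motion.
#'
#' @param face_A,face_B `face_motion` fits.
#' @param point skeleton point `c(x, y)` px.
#' @return `c(u, v)` relative displacement in px.
#' @export
relative_displacement <- function(face_A, face_B, point) {
  face_displacement_at(face_B, point) - face_displacement_at(face_A, point)
}

#' Decompose a relative displacement into opening and slip
#'
#' The crack inclination angle `alpha_r` is the unsigned angle between
#' the relative displacement and the local crack tangent, in
#' `[0, pi/2]`. The opening (COD) is the normal component
#' `delta_n = sin(alpha_r) * ||delta||` (non-negative by construction)
#' and the slip the tangential component
#' `delta_t = cos(alpha_r) * ||delta||`.
#'
#' @param delta relative displacement `c(u, v)` px.
#' @param tangent crack tangent angle in radians (`NA` flags the point).
#' @return list with `alpha_r`, `delta_n`, `delta_t` (px).
#' @export
decompose_cod <- function(delta, tangent) {
  if (!is.finite(tangent))
    return(list(alpha_r = NA_real_, delta_n = NA_real_,
                delta_t = NA_real_))
  mag <- sqrt(sum(delta^2))
  if (mag == 0)
    return(list(alpha_r = 0, delta_n = 0, delta_t = 0))
  tv <- c(cos(tangent), sin(tangent))
  ct <- min(1, abs(sum(delta * tv)) / mag)
  alpha_r <- acos(ct)
  list(alpha_r = alpha_r, delta_n = sin(alpha_r) * mag,
       delta_t = ct * mag)
}

# total-least-squares tangent angle of up to w skeleton points around
# index i (principal direction of the local point cloud)
local_tangent <- function(path, i, w) {
  h <- w %/% 2
  idx <- max(1, i - h):min(nrow(path), i + h)
  if (length(idx) < 2) return(NA_real_)
  pts <- path[idx, , drop = FALSE]
  cv <- sweep(pts, 2, colMeans(pts))
  e <- eigen(crossprod(cv), symmetric = TRUE)
  if (e$values[1] <= 0) return(NA_real_)
  atan2(e$vectors[2, 1], e$vectors[1, 1])
}

#' Crack opening displacement along a skeleton
#'
#' For every point of the skeleton's main path: the local crack tangent
#' is fitted (total least squares) to `window` consecutive skeleton
#' points; [split_faces()] collects clean displacement samples on each
#' face; [fit_face_motion()] estimates each face's rigid motion;
#' [relative_displacement()] forms the face-relative displacement and
#' [decompose_cod()] splits it into opening (`delta_n`) and slip
#' (`delta_t`). Points with an undersized or degenerate face sample are
#' flagged and carry NA.
#'
#' @param field a [displacement_field()].
#' @param skeleton a `crack_skeleton` (or a two-column (x, y) path
#'   matrix).
#' @param window fitting window `w` in grid points (default 7); used both
#'   for the tangent fit and the face depth.
#' @param pixel_scale um per px for the um columns; defaults to the
#'   field's.
#' @param exclusion_band see [split_faces()].
#' @return A data frame of class `cod_profile` with columns `x`, `y`,
#'   `tangent`, `alpha_r`, `delta_x`, `delta_y`, `delta_n_px`,
#'   `delta_n_um`, `delta_t_px`, `delta_t_um`, `valid`.
#' @export
cod_profile <- function(field, skeleton, window = 7, pixel_scale = NULL,
                        exclusion_band = NULL) {
  path <- if (inherits(skeleton, "crack_skeleton"))
    main_path(skeleton) else as.matrix(skeleton)
  if (is.null(path) || !nrow(path)) stop("skeleton is empty")
  if (is.null(pixel_scale)) pixel_scale <- field$pixel_scale
  n <- nrow(path)
  out <- data.frame(x = path[, 1], y = path[, 2], tangent = NA_real_,
                    alpha_r = NA_real_, delta_x = NA_real_,
                    delta_y = NA_real_, delta_n_px = NA_real_,
                    delta_n_um = NA_real_, delta_t_px = NA_real_,
                    delta_t_um = NA_real_, valid = FALSE)
  for (i in seq_len(n)) {
    tg <- local_tangent(path, i, window)
    out$tangent[i] <- tg
    if (!is.finite(tg)) next
    faces <- split_faces(path[i, ], tg, field, window = window,
                         exclusion_band = exclusion_band)
    fa <- fit_face_motion(faces$A)
    fb <- fit_face_motion(faces$B)
    if (is.null(fa) || is.null(fb)) next
    delta <- relative_displacement(fa, fb, path[i, ])
    dec <- decompose_cod(delta, tg)
    out$delta_x[i] <- delta[1]
    out$delta_y[i] <- delta[2]
    out$alpha_r[i] <- dec$alpha_r
    out$delta_n_px[i] <- dec$delta_n
    out$delta_n_um[i] <- dec$delta_n * pixel_scale
    out$delta_t_px[i] <- dec$delta_t
    out$delta_t_um[i] <- dec$delta_t * pixel_scale
    out$valid[i] <- TRUE
  }
  if (!any(out$valid))
    warning("no skeleton point had enough clean points on both faces")
  attr(out, "window") <- window
  attr(out, "pixel_scale") <- pixel_scale
  class(out) <- c("cod_profile", "data.frame")
  out
}

#' @export
print.cod_profile <- function(x, ...) {
  nv <- sum(x$valid)
  cat(sprintf("<cod_profile> %d skeleton point(s), %d with COD estimate\n",
              nrow(x), nv))
  if (nv > 0)
    cat(sprintf(paste0("  opening delta_n: max %.3f px (%.2f um), ",
                       "mean %.3f px; slip delta_t: max %.3f px\n"),
                max(x$delta_n_px, na.rm = TRUE),
                max(x$delta_n_um, na.rm = TRUE),
                mean(x$delta_n_px, na.rm = TRUE),
                max(x$delta_t_px, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.cod_profile <- function(x, ...) {
  s <- c(0, cumsum(sqrt(diff(x$x)^2 + diff(x$y)^2)))
  plot(s[x$valid], x$delta_n_um[x$valid], type = "b", pch = 16,
       xlab = "arc length along crack (px)",
       ylab = expression(paste("opening ", delta[n], " (", mu, "m)")),
       ...)
  invisible(x)
}

#' Maximum opening versus fitting window size
#'
#' Recomputes the COD profile for a range of window sizes `w` and reports
#' the maximum opening for each: small windows lose face samples to the
#' exclusion band and underestimate the opening, so the curve typically
#' rises and then plateaus once the faces are well sampled; the default
#' `w = 7` sits on the plateau.
#'
#' @param field a [displacement_field()].
#' @param skeleton a `crack_skeleton` or (x, y) path matrix.
#' @param windows integer vector of window sizes (grid points).
#' @param ... passed to [cod_profile()].
#' @return data frame with `w`, `max_delta_n_px`, `max_delta_n_um`,
#'   `mean_delta_n_px`, `n_valid`.
#' @export
cod_window_sweep <- function(field, skeleton, windows = seq(3, 15, by = 2),
                             ...) {
  rows <- lapply(windows, function(w) {
    prof <- suppressWarnings(cod_profile(field, skeleton, window = w, ...))
    ok <- prof$valid
    data.frame(w = w,
               max_delta_n_px = if (any(ok)) max(prof$delta_n_px[ok]) else NA,
               max_delta_n_um = if (any(ok)) max(prof$delta_n_um[ok]) else NA,
               mean_delta_n_px = if (any(ok))
                 mean(prof$delta_n_px[ok]) else NA,
               n_valid = sum(ok))
  })
  do.call(rbind, rows)
}
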