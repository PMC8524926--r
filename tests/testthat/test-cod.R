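grid_cod <- seq(0, 252, by = 4)

vertical_crack_field <- function(opening = 0.5, slip = 0, rot_B = 0,
                                 noise = 0) {
  path <- cbind(126, c(0, 252))
  spec <- deformation_spec("crack", path = path, opening = opening,
                           slip = slip, rotation_B = rot_B)
  f <- analytic_displacement_field(spec, grid_cod, grid_cod)
  if (noise > 0) {
    set.seed(17)
    f$u <- f$u + matrix(rnorm(length(f$u), sd = noise), nrow(f$u))
    f$v <- f$v + matrix(rnorm(length(f$v), sd = noise), nrow(f$v))
  }
  list(field = f, path = path, spec = spec)
}

test_that("face splitting respects the signed distance to the crack", {
  vc <- vertical_crack_field()
  faces <- split_faces(c(126, 126), pi / 2, vc$field, window = 7)
  expect_gt(nrow(faces$A), 3)
  expect_gt(nrow(faces$B), 3)
  # vertical crack with tangent +y: normal points toward -x, so face B
  # (positive side) is the left half-plane
  expect_true(all(faces$B$x < 126))
  expect_true(all(faces$A$x > 126))
  # exclusion band drops points straddling the crack
  expect_true(all(abs(faces$A$x - 126) >= vc$field$step / 2))

  # oblique tangent: partition equals hand-computed signed distances
  faces45 <- split_faces(c(126, 126), pi / 4, vc$field, window = 5,
                         exclusion_band = 3)
  nv <- c(-sin(pi / 4), cos(pi / 4))
  for (s in list(list(d = faces45$A, sgn = -1),
                 list(d = faces45$B, sgn = 1))) {
    across <- (s$d$x - 126) * nv[1] + (s$d$y - 126) * nv[2]
    expect_true(all(s$sgn * across > 3))
  }
})

test_that("an empty face side leaves the point unflagged", {
  vc <- vertical_crack_field()
  # point at the left border: face B (left of the crack... here the
  # window at x=6 has no room beyond the field edge on one side)
  faces <- split_faces(c(6, 126), pi / 2, vc$field, window = 2,
                       exclusion_band = 20)
  expect_true(nrow(faces$A) == 0 || nrow(faces$B) == 0)
})

test_that("rigid face fits recover translations and rotations", {
  pts <- expand.grid(x = seq(10, 50, 10), y = seq(10, 50, 10))
  tr <- data.frame(x = pts$x, y = pts$y, u = 2, v = 0)
  fit <- fit_face_motion(tr)
  expect_equal(fit$lip_displacement, c(2, 0))
  expect_equal(fit$rotation, 0)

  th <- 0.004
  rot <- data.frame(x = pts$x, y = pts$y,
                    u = -th * (pts$y - 30), v = th * (pts$x - 30))
  fit2 <- fit_face_motion(rot, reference_point = c(30, 30))
  expect_equal(fit2$rotation, th)
  expect_equal(fit2$lip_displacement, c(0, 0))

  set.seed(4)
  noisy <- data.frame(x = pts$x, y = pts$y,
                      u = 1 - th * (pts$y - 30) + rnorm(25, sd = 0.01),
                      v = -2 + th * (pts$x - 30) + rnorm(25, sd = 0.01))
  fit3 <- fit_face_motion(noisy, reference_point = c(30, 30))
  want <- rigid_fit_oracle(noisy$x, noisy$y, noisy$u, noisy$v, c(30, 30))
  expect_equal(unname(c(fit3$lip_displacement, fit3$rotation)),
               as.vector(want), tolerance = 1e-10)
})

test_that("degenerate face samples are rejected", {
  two <- data.frame(x = c(1, 2), y = c(1, 2), u = 0, v = 0)
  expect_null(fit_face_motion(two))
  coll <- data.frame(x = 1:6, y = 2 * (1:6) + 1, u = 0.1, v = 0)
  expect_null(fit_face_motion(coll))
})

test_that("relative displacement follows the face kinematics", {
  mk <- function(lip, rot, ref) structure(
    list(lip_displacement = lip, rotation = rot, reference_point = ref,
         n_points = 5L), class = "face_motion")
  a <- mk(c(0, 0), 0, c(10, 10))
  expect_equal(relative_displacement(a, a, c(20, 20)), c(0, 0))
  b <- mk(c(0.5, 0), 0, c(40, 10))
  expect_equal(relative_displacement(a, b, c(20, 20)), c(0.5, 0))
  # rotation about an offset reference point, evaluated by hand with the
  # same small-angle linearization the estimator uses
  th <- 0.01
  rotb <- mk(c(0, 0), th, c(30, 40))
  p <- c(20, 20); d <- p - c(30, 40)
  want <- c(-th * d[2], th * d[1])
  expect_equal(relative_displacement(a, rotb, p), want)
})

test_that("the opening/slip decomposition follows the inclination angle", {
  d <- decompose_cod(c(1, 0), pi / 2) # delta perpendicular to crack
  expect_equal(d$alpha_r, pi / 2)
  expect_equal(d$delta_n, 1)
  expect_equal(d$delta_t, 0)
  d2 <- decompose_cod(c(0, 2), pi / 2) # delta parallel
  expect_equal(d2$delta_n, 0)
  expect_equal(d2$delta_t, 2)
  d3 <- decompose_cod(c(cos(pi / 6), sin(pi / 6)), 0) # 30 degrees
  expect_equal(d3$delta_n, 0.5)
  expect_equal(d3$alpha_r, pi / 6)
  expect_true(is.na(decompose_cod(c(1, 1), NA_real_)$delta_n))
})

test_that("cod profiles recover prescribed openings on analytic cracks", {
  vc <- vertical_crack_field(opening = 0.5)
  prof <- cod_profile(vc$field, vc$path, window = 7)
  expect_true(any(prof$valid))
  mx <- max(prof$delta_n_px[prof$valid])
  expect_gte(mx, 0.45)
  expect_lte(mx, 0.55)
  expect_lt(max(prof$delta_t_px[prof$valid]), 0.05)
  # micrometre reporting uses the pixel scale
  expect_equal(prof$delta_n_um, prof$delta_n_px * 20)
})

test_that("pure slip produces slip, not opening", {
  vc <- vertical_crack_field(opening = 0, slip = 0.5)
  prof <- cod_profile(vc$field, vc$path, window = 7)
  expect_lte(max(prof$delta_n_px[prof$valid]), 0.05)
  mx <- max(prof$delta_t_px[prof$valid])
  expect_gte(mx, 0.45)
  expect_lte(mx, 0.55)
})

test_that("openings across the dynamic range are recovered within bounds", {
  for (op in c(0.25, 0.5, 1, 2, 5)) {
    vc <- vertical_crack_field(opening = op)
    prof <- cod_profile(vc$field, vc$path, window = 7)
    mx <- max(prof$delta_n_px[prof$valid])
    rel <- abs(mx - op) / op
    expect_lte(rel, if (op >= 1) 0.10 else 0.20)
  }
})

test_that("a crack-free field yields no spurious opening", {
  fake_path <- cbind(126, seq(0, 252, 2))
  # rigid motion (translation + small rotation): rigid face fits are
  # exact, so the relative displacement vanishes identically
  th <- 0.001
  rigid <- analytic_displacement_field(
    deformation_spec("composite", components = list(
      deformation_spec("translation", translation = c(1.5, -0.5)),
      deformation_spec("affine", dudy = -th, dvdx = th))),
    grid_cod, grid_cod)
  prof <- cod_profile(rigid, fake_path, window = 7, exclusion_band = 10)
  expect_lt(max(prof$delta_n_px[prof$valid]), 1e-9)

  # homogeneous strain: the apparent opening is bounded by the strain
  # times the gauge length (face-centroid separation), a documented
  # limitation of rigid-body face fits
  eps <- 0.002
  strained <- analytic_displacement_field(
    deformation_spec("affine", dudx = eps), grid_cod, grid_cod)
  prof2 <- cod_profile(strained, fake_path, window = 7,
                       exclusion_band = 10)
  gauge <- 2 * (10 + 7 * 4) # both faces span band..band + w*step
  expect_lt(max(prof2$delta_n_px[prof2$valid]), eps * gauge)
})

test_that("per-face rotations enter the relative displacement", {
  th <- 0.002
  vc <- vertical_crack_field(opening = 0.5, rot_B = th)
  prof <- cod_profile(vc$field, vc$path, window = 7)
  ok <- prof$valid
  # ground truth at each skeleton point from the generating kinematics
  truthf <- displacement_function(vc$spec)
  for (i in which(ok)[c(10, 30)]) {
    p <- c(prof$x[i], prof$y[i])
    jump <- truthf(p[1] + 1e-6, p[2]) - truthf(p[1] - 1e-6, p[2])
    got <- c(prof$delta_x[i], prof$delta_y[i])
    # sign of delta depends on face labelling; compare magnitudes and axis
    expect_equal(abs(got), abs(as.vector(jump)), tolerance = 0.02)
  }
})

test_that("the decomposition identity holds at every emitted point", {
  vc <- vertical_crack_field(opening = 0.3, slip = 0.2, noise = 0.005)
  prof <- cod_profile(vc$field, vc$path, window = 7)
  ok <- prof$valid
  lhs <- prof$delta_x[ok]^2 + prof$delta_y[ok]^2
  rhs <- prof$delta_n_px[ok]^2 + prof$delta_t_px[ok]^2
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("a global translation leaves the opening unchanged", {
  vc <- vertical_crack_field(opening = 0.5)
  comp <- deformation_spec("composite", components = list(
    vc$spec, deformation_spec("translation", translation = c(2, -1))))
  f2 <- analytic_displacement_field(comp, grid_cod, grid_cod)
  p1 <- cod_profile(vc$field, vc$path, window = 7)
  p2 <- cod_profile(f2, vc$path, window = 7)
  expect_equal(p2$delta_n_px[p2$valid], p1$delta_n_px[p1$valid],
               tolerance = 1e-9)
})

test_that("window sweeps report the convergence curve", {
  vc <- vertical_crack_field(opening = 0.5)
  sw <- cod_window_sweep(vc$field, vc$path, windows = c(3, 5, 7))
  expect_equal(sw$w, c(3, 5, 7))
  expect_true(all(is.finite(sw$max_delta_n_px)))
  expect_true(all(abs(sw$max_delta_n_px - 0.5) < 0.06))
})
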