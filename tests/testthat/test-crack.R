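test_that("hysteresis binarization handles the degenerate cases", {
  zero <- matrix(0, 10, 10)
  expect_warning(m <- binarize_iterative(zero, high = 0.01, low = 0.005),
                 "empty")
  expect_false(any(m$pixels))

  set.seed(2)
  noisy <- matrix(runif(100), 10, 10)
  eq <- binarize_iterative(noisy, high = 0.6, low = 0.6)
  expect_identical(eq$pixels, noisy >= 0.6) # degenerate hysteresis
  expect_error(binarize_iterative(noisy, high = 0.2, low = 0.6), "exceed")
})

test_that("region growing adds connected flanks but not isolated blobs", {
  m <- matrix(0, 10, 10)
  m[3:8, 5] <- 1.0            # high ridge
  m[3:8, 4] <- 0.5            # flank between the thresholds
  m[3:8, 6] <- 0.5            # flank
  m[1, 9:10] <- 0.5           # isolated mid-level blob
  mask <- binarize_iterative(m, high = 0.8, low = 0.4)
  want <- m >= 0.8
  want[3:8, 4] <- TRUE
  want[3:8, 6] <- TRUE        # hand-evaluated region growing
  expect_identical(mask$pixels, want)
  expect_false(any(mask$pixels[1, 9:10]))
})

test_that("hysteresis masks nest between the two simple thresholds", {
  set.seed(7)
  for (i in 1:4) {
    m <- matrix(runif(400), 20, 20)
    m <- (m + shift_smooth(m)) / 2 # mild spatial correlation
    hi <- quantile(m, 0.95); lo <- quantile(m, 0.7)
    mask <- suppressWarnings(binarize_iterative(m, high = hi, low = lo))
    expect_true(all(mask$pixels[m >= hi]))          # contains seeds
    expect_true(all(m[mask$pixels] >= lo))          # within low mask
    # raising the low threshold never grows the mask
    tighter <- suppressWarnings(
      binarize_iterative(m, high = hi, low = quantile(m, 0.8)))
    expect_true(all(mask$pixels[tighter$pixels]))
  }
})

test_that("morphological cleaning keeps only large components", {
  empty <- matrix(FALSE, 12, 12)
  expect_false(any(morphological_clean(empty)$pixels))

  solid <- matrix(FALSE, 20, 20); solid[5:15, 5:15] <- TRUE
  expect_identical(morphological_clean(solid, min_component = 5,
                                       closing_radius = 1)$pixels, solid)

  two <- matrix(FALSE, 30, 40)
  two[2:4, 2] <- TRUE             # 3 px component
  two[10:24, 10:29] <- TRUE       # 300 px component
  out <- morphological_clean(two, min_component = 20, closing_radius = 0)
  expect_false(any(out$pixels[2:4, 2]))
  expect_true(all(out$pixels[10:24, 10:29]))
})

test_that("skeletonization thins a band to its one-pixel midline", {
  band <- matrix(FALSE, 100, 20)
  band[, 8:12] <- TRUE
  sk <- skeletonize_mask(band, prune = 0)
  expect_length(sk$paths, 1)
  mp <- main_path(sk)
  expect_gte(nrow(mp), 90)
  expect_true(all(abs(mp[, 1] - 9) <= 1)) # midline of columns 7..11 (0-based)
  # one-pixel wide: no skeleton pixel has a full 3x3 neighbourhood
  skm <- matrix(FALSE, 100, 20)
  for (p in sk$paths) skm[cbind(p[, 2] + 1, p[, 1] + 1)] <- TRUE
  full <- skm
  for (dy in -1:1) for (dx in -1:1)
    full <- full & crackdic:::shift_mat(skm, dy, dx)
  expect_false(any(full))
})

test_that("short branches are pruned and the longest path is the main one", {
  plus <- matrix(FALSE, 30, 30)
  plus[15, 3:28] <- TRUE  # long horizontal arm
  plus[12:14, 15] <- TRUE # short vertical stub (3 px)
  sk <- skeletonize_mask(plus, prune = 5)
  expect_length(sk$paths, 1)
  mp <- main_path(sk)
  expect_true(all(mp[, 2] == 14)) # purely horizontal after pruning
  expect_equal(sk$branch_count, 0)
})

test_that("single pixels and empty masks give minimal skeletons", {
  dot <- matrix(FALSE, 9, 9); dot[5, 5] <- TRUE
  sk <- skeletonize_mask(dot)
  expect_length(sk$paths, 1)
  expect_equal(nrow(main_path(sk)), 1)
  empty <- skeletonize_mask(matrix(FALSE, 5, 5))
  expect_length(empty$paths, 0)
})

test_that("thinning is idempotent on skeletons", {
  set.seed(5)
  m <- matrix(FALSE, 60, 60)
  m[10:50, 20:30] <- TRUE
  m[30:40, 5:55] <- TRUE
  once <- crackdic:::thin_mask(m)
  twice <- crackdic:::thin_mask(once)
  expect_identical(once, twice)
})

test_that("skeleton agreement matches a brute-force oracle", {
  mk <- function(path) structure(list(paths = list(path), main_path = 1L,
                                      branch_count = 0L, step = 1),
                                 class = "crack_skeleton")
  a <- mk(cbind(5, 0:20))
  expect_equal(skeleton_agreement(a, a), list(mean = 0, max = 0))
  b <- mk(cbind(8, 0:20))
  ab <- skeleton_agreement(a, b)
  expect_equal(ab$mean, 3)
  expect_equal(ab$max, 3)
  set.seed(11)
  c1 <- mk(cbind(cumsum(runif(12)), cumsum(runif(12))))
  c2 <- mk(cbind(3 + cumsum(runif(9)), cumsum(runif(9))))
  got <- skeleton_agreement(c1, c2)
  want <- agreement_oracle(main_path(c1), main_path(c2))
  expect_equal(got$mean, want$mean, tolerance = 1e-12)
  expect_equal(got$max, want$max, tolerance = 1e-12)
  expect_error(skeleton_agreement(a, skeletonize_mask(matrix(FALSE, 3, 3))),
               "nonempty")
})

test_that("a dark curve on a noisy background is skeletonized faithfully", {
  set.seed(21)
  H <- 120; W <- 120
  img <- matrix(0.8 + rnorm(H * W, sd = 0.03), H, W)
  # true curve: gentle slanted line x = 50 + 0.2 * y
  ys <- 0:(H - 1)
  xs <- round(50 + 0.2 * ys)
  for (i in seq_along(ys))
    img[ys[i] + 1, (xs[i]:(xs[i] + 2)) + 1] <- 0.15
  img <- pmin(pmax(img, 0), 1)
  sk <- skeletonize_reference_image(speckle_image(img), min_component = 30)
  mp <- main_path(sk)
  expect_gt(nrow(mp), 80)
  truth <- cbind(50 + 0.2 * ys + 1, ys)
  d <- crackdic:::polyline_distance(mp[, 1], mp[, 2], truth)
  expect_lt(max(d), 2.5)

  # inverted contrast with the polarity flag gives the same skeleton
  sk2 <- skeletonize_reference_image(speckle_image(1 - img),
                                     polarity = "light",
                                     min_component = 30)
  expect_equal(main_path(sk2), mp)

  # constant image: no crack
  flat <- skeletonize_reference_image(speckle_image(matrix(0.5, 50, 50)))
  expect_length(flat$paths, 0)
})

test_that("end-to-end extraction follows the true crack path", {
  gx <- seq(0, 252, 4)
  path <- cbind(110 + 14 * sin(seq(0, 252, 2) * pi / 252), seq(0, 252, 2))
  f <- analytic_displacement_field(
    deformation_spec("crack", path = path, opening = 0.6), gx, gx)
  s <- strain_from_displacement(f, window = 5)
  peak <- max(s$eps_1[s$valid])
  sk <- extract_crack(s, high = 0.5 * peak, low = 0.1 * peak)
  mp <- main_path(sk)
  d <- crackdic:::polyline_distance(mp[, 1], mp[, 2], path)
  expect_gte(mean(d <= 8), 0.95) # within 2 grid steps
})
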