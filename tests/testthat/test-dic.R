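test_that("ncc matches its definition and its invariances", {
  set.seed(1)
  for (i in 1:5) {
    p <- matrix(runif(49), 7, 7)
    expect_equal(ncc(p, p), 1)                       # perfect match
    expect_equal(ncc(p, 3.7 * p), 1)                 # scale invariance
    q <- matrix(runif(49), 7, 7)
    expect_equal(ncc(p, q), ncc_oracle(p, q))        # definition
    expect_true(ncc(p, q) >= 0 && ncc(p, q) <= 1)
  }
  expect_equal(ncc(matrix(c(1, 0, 0, 0), 2), matrix(c(0, 0, 0, 1), 2)), 0)
  expect_equal(ncc(matrix(1, 2, 2), matrix(2, 2, 2)), 1)
  expect_true(is.na(ncc(matrix(0, 2, 2), matrix(1, 2, 2))))
  expect_error(ncc(matrix(1, 2, 2), matrix(1, 3, 3)), "dimensions")
})

test_that("dic_config validates its parameters", {
  expect_error(dic_config(subset_size = 40), "odd")
  expect_error(dic_config(subset_size = 69, search_size = 39), "smaller")
  expect_error(dic_config(step = 0), "step")
  expect_error(dic_config(correlation_floor = 1.2), "correlation_floor")
})

test_that("subset matching recovers identity and integer shifts exactly", {
  ref <- generate_speckle(96, 96, seed = 4)
  cfg <- test_config()
  m0 <- match_subset(ref, ref, c(48, 48), cfg)
  expect_equal(m0$u, 0)
  expect_equal(m0$v, 0)
  expect_equal(m0$c, 1)
  def <- warp_image(ref, deformation_spec("translation",
                                          translation = c(3, 2)))
  m <- match_subset(ref, def, c(48, 48), cfg)
  expect_equal(m$u, 3)
  expect_equal(m$v, 2)
  expect_equal(m$c, 1)
})

test_that("degenerate and out-of-bounds subsets are flagged invalid", {
  flat <- speckle_image(matrix(0.5, 96, 96))
  cfg <- test_config()
  m <- match_subset(flat, flat, c(48, 48), cfg)
  expect_false(m$valid)
  ref <- generate_speckle(96, 96, seed = 4)
  edge <- match_subset(ref, ref, c(3, 48), cfg)
  expect_false(edge$valid)
  expect_true(is.na(edge$u))
})

test_that("the coarse stage equals exhaustive integer search", {
  set.seed(8)
  ref <- generate_speckle(72, 72, seed = 8)
  cfg <- dic_config(subset_size = 15, search_size = 25, step = 4,
                    subpixel = FALSE, prefilter_sigma = 0)
  def <- warp_image(ref, deformation_spec("translation",
                                          translation = c(-2, 4)))
  for (cx in c(30, 36, 42)) {
    got <- match_subset(ref, def, c(cx, 36), cfg)
    want <- match_oracle_integer(ref$pixels, def$pixels, cx, 36, 15, 25)
    expect_equal(got$u, want$u)
    expect_equal(got$v, want$v)
    expect_equal(got$c, want$c)
  }
})

test_that("subpixel refinement agrees with a dense fractional oracle", {
  ref <- generate_speckle(72, 72, seed = 13)
  cfg <- dic_config(subset_size = 21, search_size = 27, step = 4,
                    granularity = 0.01, prefilter_sigma = 0)
  def <- warp_image(ref, deformation_spec("translation",
                                          translation = c(0.5, 0)))
  got <- match_subset(ref, def, c(36, 36), cfg)
  want <- match_oracle_fractional(ref$pixels, def$pixels, 36, 36, 21,
                                  shifts = seq(-1, 1, by = 0.05))
  expect_lt(abs(got$u - want$u), 0.06)
  expect_lt(abs(got$v - want$v), 0.06)
  expect_lt(abs(got$u - 0.5), 0.1)
  expect_lt(abs(got$v), 0.1)
})

test_that("the lattice placement rule gives the documented grid size", {
  lat <- dic_lattice(c(0, 0, 1168, 876), 39, 4)
  expect_length(lat$grid_x, floor((1168 - 39) / 4) + 1)
  expect_length(lat$grid_y, floor((876 - 39) / 4) + 1)
  expect_equal(lat$grid_x[1], 19)
  expect_equal(unique(diff(lat$grid_x)), 4)
  expect_error(dic_lattice(c(0, 0, 30, 30), 39, 4), "too small")
})

test_that("field computation handles static and translated pairs", {
  ref <- generate_speckle(96, 96, seed = 6)
  cfg <- test_config()
  stat <- compute_displacement_field(ref, ref, config = cfg)
  expect_true(any(stat$valid))
  expect_true(all(stat$u[stat$valid] == 0))
  expect_true(all(stat$v[stat$valid] == 0))
  expect_true(all(stat$c[stat$valid] == 1))
  expect_equal(unique(diff(stat$grid_x)), cfg$step)

  def <- warp_image(ref, deformation_spec("translation",
                                          translation = c(3, 2)))
  f <- compute_displacement_field(ref, def, config = cfg)
  expect_true(all(f$u[f$valid] == 3))
  expect_true(all(f$v[f$valid] == 2))
})

test_that("displacements never exceed the search radius", {
  ref <- generate_speckle(96, 96, seed = 10)
  cfg <- test_config()
  r <- (cfg$search_size - cfg$subset_size) / 2
  for (t in list(c(4, -3), c(-5, 5))) {
    def <- warp_image(ref, deformation_spec("translation",
                                            translation = t,
                                            noise_sigma = 0.05,
                                            seed = 3))
    f <- compute_displacement_field(ref, def, config = cfg)
    expect_true(all(abs(f$u[f$valid]) <= r + 0.5))
    expect_true(all(abs(f$v[f$valid]) <= r + 0.5))
  }
})

test_that("median filtering is the identity for kernel 1 and constants", {
  ref <- generate_speckle(96, 96, seed = 6)
  f <- compute_displacement_field(ref, ref, config = test_config())
  expect_identical(median_filter_field(f, 1), f)
  g <- median_filter_field(f, 3)
  expect_true(all(g$u[g$valid] == 0))
  expect_error(median_filter_field(f, 2), "odd")
})

test_that("median filtering removes an isolated spike", {
  u <- matrix(1, 7, 7); v <- matrix(2, 7, 7)
  u[4, 4] <- 50; v[4, 4] <- -50
  f <- displacement_field(seq(0, 24, 4), seq(0, 24, 4), u, v)
  g <- median_filter_field(f, 3)
  expect_equal(g$u[4, 4], 1) # median of the 3x3 window by hand
  expect_equal(g$v[4, 4], 2)
  expect_equal(g$u[1, 1], 1)
})

test_that("median filtering skips invalid points in every window", {
  u <- matrix(1, 5, 5); u[3, 3] <- NA
  valid <- matrix(TRUE, 5, 5); valid[3, 3] <- FALSE
  f <- displacement_field(seq(0, 16, 4), seq(0, 16, 4), u, u,
                          valid = valid)
  g <- median_filter_field(f, 3)
  expect_true(all(g$u[g$valid] == 1))
  expect_false(g$valid[3, 3])
})

test_that("static-series error equals the displacement magnitude mean", {
  gx <- seq(0, 36, 4)
  zero <- displacement_field(gx, gx, matrix(0, 10, 10), matrix(0, 10, 10))
  expect_equal(static_series_error(zero)$g, 0)
  pyth <- displacement_field(gx, gx, matrix(3, 10, 10), matrix(4, 10, 10))
  expect_equal(static_series_error(pyth)$g, 5)
  set.seed(42)
  flds <- lapply(1:4, function(i)
    displacement_field(gx, gx, matrix(rnorm(100), 10),
                       matrix(rnorm(100), 10)))
  res <- static_series_error(flds)
  brute <- vapply(flds, function(f)
    mean(sqrt(as.vector(f$u)^2 + as.vector(f$v)^2)), numeric(1))
  expect_equal(res$g, brute)
  expect_equal(res$mean, mean(brute))
  expect_equal(res$variance, var(brute))
  expect_equal(res$sd, sd(brute))
  expect_error(static_series_error(list()), "at least one")
})
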