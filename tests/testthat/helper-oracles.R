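# Independent oracles, deliberately written in plain R so they share no
# code path with the package internals they check.

# Eq.-1 style normalized cross-correlation, direct transcription
ncc_oracle <- function(tmpl, region) {
  sum(tmpl * region) / sqrt(sum(tmpl^2) * sum(region^2))
}

# exhaustive integer-offset search over the full search window
match_oracle_integer <- function(ref, def, cx, cy, subset, search) {
  h <- subset %/% 2
  r <- (search - subset) %/% 2
  tmpl <- ref[(cy - h):(cy + h) + 1, (cx - h):(cx + h) + 1]
  best <- -Inf; bu <- NA; bv <- NA
  for (dv in -r:r) {
    for (du in -r:r) {
      patch <- def[(cy + dv - h):(cy + dv + h) + 1,
                   (cx + du - h):(cx + du + h) + 1]
      cc <- ncc_oracle(tmpl, patch)
      better <- cc > best + 1e-12 ||
        (abs(cc - best) <= 1e-12 && du^2 + dv^2 < bu^2 + bv^2)
      if (is.na(better)) better <- FALSE
      if (better) { best <- cc; bu <- du; bv <- dv }
    }
  }
  list(u = bu, v = bv, c = best)
}

# scalar bilinear interpolation, independent of the package's sampler
bilinear_oracle <- function(m, x, y) {
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  m[y0 + 1, x0 + 1] * (1 - fx) * (1 - fy) +
    m[y0 + 1, x0 + 2] * fx * (1 - fy) +
    m[y0 + 2, x0 + 1] * (1 - fx) * fy +
    m[y0 + 2, x0 + 2] * fx * fy
}

# dense fractional-offset NCC search around an integer start
match_oracle_fractional <- function(ref, def, cx, cy, subset, shifts) {
  h <- subset %/% 2
  tmpl <- ref[(cy - h):(cy + h) + 1, (cx - h):(cx + h) + 1]
  dxs <- rep((-h):h, each = subset)  # x slowest: column-major like tmpl
  dys <- rep((-h):h, times = subset)
  best <- -Inf; bu <- NA; bv <- NA
  for (v in shifts) {
    for (u in shifts) {
      patch <- mapply(function(dx, dy)
        bilinear_oracle(def, cx + dx + u, cy + dy + v), dxs, dys)
      cc <- ncc_oracle(as.vector(tmpl), patch)
      if (!is.na(cc) && cc > best) { best <- cc; bu <- u; bv <- v }
    }
  }
  list(u = bu, v = bv, c = best)
}

# least-squares plane fit via explicit normal equations
plane_fit_oracle <- function(x, y, z) {
  P <- cbind(1, x, y)
  solve(t(P) %*% P, t(P) %*% z)
}

# rigid-motion (tx, ty, theta) fit via explicit normal equations
rigid_fit_oracle <- function(x, y, u, v, ref) {
  dx <- x - ref[1]; dy <- y - ref[2]
  A <- rbind(cbind(1, 0, -dy), cbind(0, 1, dx))
  b <- c(u, v)
  solve(t(A) %*% A, t(A) %*% b)
}

# brute-force symmetric point-to-segment distances between two polylines
agreement_oracle <- function(pa, pb) {
  seg_dist <- function(q, p1, p2) {
    d <- p2 - p1
    l2 <- sum(d^2)
    if (l2 == 0) return(sqrt(sum((q - p1)^2)))
    t <- max(0, min(1, sum((q - p1) * d) / l2))
    sqrt(sum((q - p1 - t * d)^2))
  }
  pt_to_path <- function(q, path) {
    if (nrow(path) == 1) return(sqrt(sum((q - path[1, ])^2)))
    min(vapply(seq_len(nrow(path) - 1), function(i)
      seg_dist(q, path[i, ], path[i + 1, ]), numeric(1)))
  }
  da <- vapply(seq_len(nrow(pa)), function(i) pt_to_path(pa[i, ], pb),
               numeric(1))
  db <- vapply(seq_len(nrow(pb)), function(i) pt_to_path(pb[i, ], pa),
               numeric(1))
  list(mean = mean(c(da, db)), max = max(c(da, db)))
}

# four-neighbour average, used to give random test maps mild spatial
# correlation
shift_smooth <- function(m) {
  (crackdic:::shift_mat(m, 0, 1, fill = 0) +
   crackdic:::shift_mat(m, 1, 0, fill = 0) +
   crackdic:::shift_mat(m, 0, -1, fill = 0) +
   crackdic:::shift_mat(m, -1, 0, fill = 0)) / 4
}

# small matcher configuration used throughout the unit tests
test_config <- function(...) {
  dic_config(subset_size = 21, search_size = 31, step = 8, ...)
}
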