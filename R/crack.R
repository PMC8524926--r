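#' Binarize a principal-strain map by iterative high/low thresholding
#'
#' The crack shows up as a ridge of large maximum principal strain, but a
#' single threshold either misses parts of the crack or lets noise in.
#' Instead the high-strain area is grown iteratively: pixels at or above
#' the high threshold seed the mask, and each iteration adds 8-connected
#' neighbours at or above the low threshold until convergence (hysteresis
#' region growing). Isolated mid-level blobs never connected to a seed
#' stay out.
#'
#' Thresholds default to quantiles of the positive `eps_1` distribution
#' so they transfer across load levels; absolute strain values can be
#' given instead via `high`/`low`.
#'
#' @param strain a `strain_field` (the `eps_1` channel is used) or a
#'   plain numeric matrix.
#' @param high,low absolute strain thresholds; when `NULL` they are taken
#'   as the `high_quantile`/`low_quantile` quantiles of the positive
#'   values.
#' @param high_quantile,low_quantile quantile defaults (0.99 / 0.90).
#' @param max_iterations cap on growth iterations (default effectively
#'   unlimited; growth converges once no neighbour qualifies).
#' @return An object of class `crack_mask`: logical `pixels` aligned with
#'   the strain lattice, the thresholds used, and `iterations_used`. When
#'   no pixel reaches the high threshold an empty mask is returned with a
#'   warning.
#' @export
binarize_iterative <- function(strain, high = NULL, low = NULL,
                               high_quantile = 0.99, low_quantile = 0.90,
                               max_iterations = 10000L) {
  if (inherits(strain, "strain_field")) {
    m <- strain$eps_1
    m[!strain$valid] <- NA
    gx <- strain$grid_x; gy <- strain$grid_y; step <- strain$step
  } else {
    m <- as.matrix(strain)
    gx <- seq_len(ncol(m)) - 1; gy <- seq_len(nrow(m)) - 1; step <- 1
  }
  if (is.null(high) || is.null(low)) {
    # quantiles of the meaningfully positive strains; a relative floor
    # keeps numerical dust (~1e-16 on analytically exact fields) out of
    # the population
    floor_eps <- 1e-6 * max(m, 0, na.rm = TRUE)
    pos <- m[is.finite(m) & m > floor_eps]
    if (!length(pos)) pos <- 0
    if (is.null(high)) high <- quantile(pos, high_quantile, names = FALSE)
    if (is.null(low)) low <- quantile(pos, low_quantile, names = FALSE)
  }
  if (low > high) stop("low threshold must not exceed high threshold")
  seed <- !is.na(m) & m >= high
  allowed <- !is.na(m) & m >= low
  iter <- 0L
  mask <- seed
  if (!any(seed)) {
    warning("no pixel reaches the high threshold; mask is empty")
  } else {
    repeat {
      grown <- mask | (dilate8(mask) & allowed)
      if (identical(grown, mask) || iter >= max_iterations) break
      mask <- grown
      iter <- iter + 1L
    }
  }
  structure(list(pixels = mask, high_threshold = high, low_threshold = low,
                 iterations_used = iter, grid_x = gx, grid_y = gy,
                 step = step),
            class = "crack_mask")
}

# one 8-connected dilation step via shifted copies
dilate8 <- function(m) {
  out <- m
  for (dy in -1:1)
    for (dx in -1:1) {
      if (dx == 0 && dy == 0) next
      out <- out | shift_mat(m, dy, dx)
    }
  out
}

shift_mat <- function(m, dy, dx, fill = FALSE) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
  oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

#' @export
print.crack_mask <- function(x, ...) {
  cat(sprintf(paste0("<crack_mask> %d/%d pixels set, thresholds ",
                     "[%.4g, %.4g], %d growth iteration(s)\n"),
              sum(x$pixels), length(x$pixels), x$low_threshold,
              x$high_threshold, x$iterations_used))
  invisible(x)
}

#' @export
plot.crack_mask <- function(x, ...) {
  image(x = x$grid_x, y = x$grid_y, z = t(x$pixels * 1),
        col = c("black", "white"), asp = 1, xlab = "x (px)",
        ylab = "y (px)", main = "crack mask", useRaster = TRUE, ...)
  invisible(x)
}

#' Clean a binary crack mask morphologically
#'
#' Morphological closing (disc structuring element) bridges small gaps in
#' the crack region, then connected components smaller than
#' `min_component` pixels are removed.
#'
#' @param mask a `crack_mask` (or logical matrix).
#' @param min_component minimum surviving component area in mask pixels.
#' @param closing_radius disc radius (px of the mask lattice); 0 skips
#'   closing.
#' @return The cleaned `crack_mask`.
#' @export
morphological_clean <- function(mask, min_component = 20,
                                closing_radius = 1) {
  is_obj <- inherits(mask, "crack_mask")
  m <- if (is_obj) mask$pixels else as.matrix(mask) > 0
  if (any(m) && closing_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L,
                                shape = "disc")
    m <- EBImage::closing(m * 1, brush) > 0
  }
  if (any(m) && min_component > 0) {
    lab <- EBImage::bwlabel(m * 1)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_component)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  if (is_obj) {
    mask$pixels <- m
    mask
  } else {
    structure(list(pixels = m, high_threshold = NA_real_,
                   low_threshold = NA_real_, iterations_used = 0L,
                   grid_x = seq_len(ncol(m)) - 1,
                   grid_y = seq_len(nrow(m)) - 1, step = 1),
              class = "crack_mask")
  }
}

# Zhang-Suen morphological thinning to a one-pixel-wide skeleton.
# No installed package offers topology-preserving thinning, so it is
# implemented here with vectorized neighbour shifts.
thin_mask <- function(m) {
  m <- m > 0
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);  p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);  p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      cond <- m & b >= 2 & b <= 6 & a == 1
      if (phase == 1)
        cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      else
        cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# build the 8-connectivity pixel graph of a skeleton mask; vertices are
# named by linear index into the mask matrix
skeleton_graph <- function(m) {
  idx <- which(m)
  if (!length(idx)) return(NULL)
  ny <- nrow(m)
  iy <- (idx - 1) %% ny + 1
  ix <- (idx - 1) %/% ny + 1
  key <- function(y, x) (x - 1) * ny + y
  edges <- integer(0)
  weights <- numeric(0)
  # edges to E, S, SE, SW neighbours (each undirected edge once)
  for (d in list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)),
                 c(1, -1, sqrt(2)))) {
    ny2 <- iy + d[1]; nx2 <- ix + d[2]
    ok <- ny2 >= 1 & ny2 <= ny & nx2 >= 1 & nx2 <= ncol(m)
    ok[ok] <- m[cbind(ny2[ok], nx2[ok])]
    if (any(ok)) {
      edges <- c(edges, rbind(idx[ok], key(ny2[ok], nx2[ok])))
      weights <- c(weights, rep(d[3], sum(ok)))
    }
  }
  g <- igraph::graph_from_edgelist(
    matrix(as.character(edges), ncol = 2, byrow = TRUE), directed = FALSE)
  isolated <- setdiff(as.character(idx), igraph::V(g)$name)
  g <- igraph::add_vertices(g, length(isolated), name = isolated)
  igraph::E(g)$weight <- weights
  g
}

#' Skeletonize a binary crack mask into ordered paths
#'
#' Thins the mask to one-pixel width (Zhang-Suen thinning), prunes side
#' branches shorter than `prune` skeleton pixels (these are the
#' bifurcation artefacts a too-low threshold produces), then orders each
#' connected component into a pixel path along its longest geodesic. The
#' longest path overall is the main crack; ties are broken by the higher
#' mean of `values` (e.g. `eps_1`) along the path when supplied.
#'
#' @param mask a `crack_mask` or logical matrix.
#' @param prune minimum surviving branch length in skeleton pixels.
#' @param values optional numeric matrix aligned with the mask used for
#'   tie-breaking between equally long paths.
#' @return An object of class `crack_skeleton`: `paths` (list of ordered
#'   two-column (x, y) matrices in the mask's coordinate units),
#'   `main_path` (index), `branch_count`, and the lattice `step`.
#' @export
skeletonize_mask <- function(mask, prune = 5, values = NULL) {
  is_obj <- inherits(mask, "crack_mask")
  m <- if (is_obj) mask$pixels else as.matrix(mask) > 0
  gx <- if (is_obj) mask$grid_x else seq_len(ncol(m)) - 1
  gy <- if (is_obj) mask$grid_y else seq_len(nrow(m)) - 1
  step <- if (is_obj) mask$step else 1
  empty <- structure(list(paths = list(), main_path = NA_integer_,
                          branch_count = 0L, step = step),
                     class = "crack_skeleton")
  if (!any(m)) return(empty)
  sk <- thin_mask(m)
  g <- skeleton_graph(sk)
  if (is.null(g)) return(empty)
  # prune short side branches: remove leaf-to-junction chains < prune px
  repeat {
    deg <- igraph::degree(g)
    junctions <- names(deg)[deg >= 3]
    leaves <- names(deg)[deg == 1]
    if (!length(junctions) || !length(leaves)) break
    removed <- character(0)
    for (lf in leaves) {
      path <- lf
      cur <- lf; prev <- NA_character_
      repeat {
        nb <- setdiff(names(igraph::neighbors(g, cur)), prev)
        if (length(nb) != 1) break # junction or dead end reached
        prev <- cur; cur <- nb[1]
        if (deg[cur] >= 3) break
        path <- c(path, cur)
      }
      if (deg[cur] >= 3 && length(path) < prune)
        removed <- union(removed, path)
    }
    if (!length(removed)) break
    g <- igraph::delete_vertices(g, removed)
  }
  comps <- igraph::components(g)
  ny <- nrow(sk)
  to_xy <- function(keys) {
    idx <- as.integer(keys)
    iy <- (idx - 1) %% ny + 1
    ix <- (idx - 1) %/% ny + 1
    cbind(x = gx[ix], y = gy[iy])
  }
  paths <- list()
  lens <- numeric(0)
  scores <- numeric(0)
  for (ci in seq_len(comps$no)) {
    members <- names(comps$membership)[comps$membership == ci]
    sub <- igraph::induced_subgraph(g, members)
    if (length(members) == 1) {
      ordered <- members
    } else {
      dia <- igraph::get_diameter(sub, weights = igraph::E(sub)$weight)
      ordered <- igraph::V(sub)$name[dia]
    }
    xy <- to_xy(ordered)
    paths[[ci]] <- xy
    lens[ci] <- if (nrow(xy) > 1)
      sum(sqrt(rowSums(diff(xy)^2))) else 0
    scores[ci] <- if (!is.null(values)) {
      idx <- as.integer(ordered)
      mean(values[idx], na.rm = TRUE)
    } else 0
  }
  main <- order(-lens, -scores)[1]
  deg_main <- igraph::degree(igraph::induced_subgraph(
    g, names(comps$membership)[comps$membership == main]))
  structure(list(paths = paths, main_path = main,
                 branch_count = max(0L, sum(deg_main == 1) - 2L),
                 step = step),
            class = "crack_skeleton")
}

#' @export
print.crack_skeleton <- function(x, ...) {
  if (!length(x$paths)) {
    cat("<crack_skeleton> empty\n")
    return(invisible(x))
  }
  mp <- x$paths[[x$main_path]]
  cat(sprintf(paste0("<crack_skeleton> %d path(s); main path: %d points, ",
                     "%d residual branch tip(s)\n"),
              length(x$paths), nrow(mp), x$branch_count))
  invisible(x)
}

#' @export
plot.crack_skeleton <- function(x, add = FALSE, col = "red", ...) {
  if (!length(x$paths)) return(invisible(x))
  all_xy <- do.call(rbind, x$paths)
  if (!add)
    plot(all_xy[, 1], all_xy[, 2], type = "n", asp = 1,
         xlab = "x (px)", ylab = "y (px)", ylim = rev(range(all_xy[, 2])),
         ...)
  for (i in seq_along(x$paths))
    lines(x$paths[[i]][, 1], x$paths[[i]][, 2],
          col = if (i == x$main_path) col else "grey60",
          lwd = if (i == x$main_path) 2 else 1)
  invisible(x)
}

#' Main crack path of a skeleton
#' @param skeleton a `crack_skeleton`.
#' @return two-column (x, y) matrix, or `NULL` when empty.
#' @export
main_path <- function(skeleton) {
  if (!length(skeleton$paths)) return(NULL)
  skeleton$paths[[skeleton$main_path]]
}

#' Extract the crack from a principal-strain field
#'
#' Convenience chain: [binarize_iterative()] then [morphological_clean()]
#' then [skeletonize_mask()], returning the skeleton (the mask is
#' attached as attribute `"mask"`).
#'
#' @inheritParams binarize_iterative
#' @inheritParams morphological_clean
#' @inheritParams skeletonize_mask
#' @return A `crack_skeleton`.
#' @export
extract_crack <- function(strain, high = NULL, low = NULL,
                          high_quantile = 0.99, low_quantile = 0.90,
                          min_component = 20, closing_radius = 1,
                          prune = 5) {
  mask <- binarize_iterative(strain, high = high, low = low,
                             high_quantile = high_quantile,
                             low_quantile = low_quantile)
  mask <- morphological_clean(mask, min_component = min_component,
                              closing_radius = closing_radius)
  vals <- if (inherits(strain, "strain_field")) strain$eps_1 else NULL
  sk <- skeletonize_mask(mask, prune = prune, values = vals)
  attr(sk, "mask") <- mask
  sk
}

#' Skeletonize a crack directly visible in a grayscale image
#'
#' For a reference modality in which the crack itself is visible (e.g. a
#' tomography slice), the image is contrast-enhanced and the dark crack
#' curve is thresholded and skeletonized: contrast-limited adaptive
#' histogram equalization, median filtering, Laplacian sharpening, Otsu
#' thresholding of the dark phase, morphological cleaning, then
#' [skeletonize_mask()]. The result is directly comparable (via
#' [skeleton_agreement()]) with a strain-derived skeleton.
#'
#' @param image a [speckle_image()] or matrix in `[0, 1]`.
#' @param polarity `"dark"` if the crack is darker than the background
#'   (default), `"light"` if brighter (the image is inverted first).
#' @param median_radius median filter radius in px.
#' @param sharpen_weight weight of the subtracted Laplacian.
#' @param min_component,closing_radius,prune cleaning parameters, as in
#'   [morphological_clean()] and [skeletonize_mask()].
#' @param clahe_tiles number of CLAHE tiles per dimension.
#' @return A `crack_skeleton` in image px coordinates.
#' @export
skeletonize_reference_image <- function(image, polarity = c("dark", "light"),
                                        median_radius = 2,
                                        sharpen_weight = 0.5,
                                        min_component = 20,
                                        closing_radius = 1, prune = 5,
                                        clahe_tiles = 4) {
  polarity <- match.arg(polarity)
  m <- image_pixels(image)
  m <- pmin(pmax(m, 0), 1)
  if (polarity == "light") m <- 1 - m
  if (sd(m) == 0) {
    return(structure(list(paths = list(), main_path = NA_integer_,
                          branch_count = 0L, step = 1),
                     class = "crack_skeleton"))
  }
  img <- EBImage::Image(m)
  img <- EBImage::clahe(img, nx = clahe_tiles, ny = clahe_tiles)
  img <- EBImage::medianFilter(img, size = as.integer(median_radius))
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  sharp <- img - sharpen_weight * EBImage::filter2(img, lap)
  sharp <- pmin(pmax(as.matrix(EBImage::imageData(sharp)), 0), 1)
  thr <- EBImage::otsu(EBImage::Image(sharp), range = c(0, 1))
  mask <- sharp < thr # the crack is the dark phase
  mask <- morphological_clean(mask, min_component = min_component,
                              closing_radius = closing_radius)
  skeletonize_mask(mask, prune = prune)
}

#' Agreement between two crack skeletons
#'
#' Symmetric point-to-path distances between the main paths: each point
#' of one skeleton is measured against the other skeleton's polyline and
#' vice versa. Reported are the mean and the maximum (the symmetric
#' Hausdorff distance), in the skeletons' coordinate units.
#'
#' @param a,b `crack_skeleton`s with nonempty main paths.
#' @return list with `mean` and `max` distances (px).
#' @export
skeleton_agreement <- function(a, b) {
  pa <- main_path(a); pb <- main_path(b)
  if (is.null(pa) || is.null(pb))
    stop("both skeletons must be nonempty")
  da <- points_to_path_distance(pa, pb)
  db <- points_to_path_distance(pb, pa)
  list(mean = mean(c(da, db)), max = max(c(da, db)))
}

points_to_path_distance <- function(points, path) {
  if (nrow(path) == 1)
    return(sqrt((points[, 1] - path[1, 1])^2 +
                (points[, 2] - path[1, 2])^2))
  polyline_distance(points[, 1], points[, 2], path)
}
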