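#' Full pipeline configuration
#'
#' Collects every stage's parameters with defaults appropriate for
#' speckle imaging of a tooth crown at ~20 um/pixel: subset 39 px, search
#' 69 px, lattice step 4 px, COD fitting window 7 grid points.
#' Serializes losslessly to YAML via [write_pipeline_config()].
#'
#' @param subset_size,search_size,step,subpixel,granularity,correlation_floor,prefilter_sigma
#'   matcher parameters, see [dic_config()].
#' @param median_kernel displacement median-filter window (grid points).
#' @param strain_window plane-fit window (grid points).
#' @param high_quantile,low_quantile hysteresis thresholds as quantiles
#'   of positive `eps_1`; overridden by absolute `high`/`low` when not
#'   `NA`.
#' @param high,low absolute strain thresholds (`NA` = use quantiles).
#' @param min_component,closing_radius,prune mask cleaning and skeleton
#'   pruning parameters.
#' @param cod_window COD fitting window `w` (grid points).
#' @param exclusion_band COD exclusion half-band in px (`NA` = half the
#'   subset size).
#' @param pixel_scale um per pixel.
#' @param seed RNG seed used by synthetic stages.
#' @param verbose print per-stage progress lines.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(subset_size = 39, search_size = 69, step = 4,
                            subpixel = TRUE, granularity = 0.005,
                            correlation_floor = 0.5, prefilter_sigma = 1.5,
                            median_kernel = 3,
                            strain_window = 5, high_quantile = 0.99,
                            low_quantile = 0.90, high = NA_real_,
                            low = NA_real_, min_component = 20,
                            closing_radius = 1, prune = 5, cod_window = 7,
                            exclusion_band = NA_real_, pixel_scale = 20,
                            seed = 1L, verbose = FALSE) {
  # validate matcher parameters up front
  dc <- dic_config(subset_size, search_size, step, subpixel, granularity,
                   correlation_floor, prefilter_sigma)
  cfg <- list(subset_size = dc$subset_size, search_size = dc$search_size,
              step = dc$step, subpixel = dc$subpixel,
              granularity = granularity,
              correlation_floor = correlation_floor,
              prefilter_sigma = prefilter_sigma,
              median_kernel = as.integer(median_kernel),
              strain_window = as.integer(strain_window),
              high_quantile = high_quantile, low_quantile = low_quantile,
              high = high, low = low,
              min_component = min_component,
              closing_radius = closing_radius, prune = prune,
              cod_window = as.integer(cod_window),
              exclusion_band = exclusion_band,
              pixel_scale = pixel_scale, seed = as.integer(seed),
              verbose = isTRUE(verbose))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

as_dic_config <- function(cfg) {
  dic_config(cfg$subset_size, cfg$search_size, cfg$step, cfg$subpixel,
             cfg$granularity, cfg$correlation_floor, cfg$prefilter_sigma)
}

#' Run the full crack-detection pipeline on an image pair
#'
#' Chains displacement matching, median filtering, strain estimation,
#' crack extraction and COD quantification. When `output_dir` is given,
#' every stage's intermediate is written (CSV for tables, PNG for mask
#' and skeleton, JSON for the summary) so downstream use is
#' language-neutral; partial outputs are retained if a later stage fails.
#'
#' @param reference,deformed [speckle_image()]s or image file paths.
#' @param config a [pipeline_config()].
#' @param output_dir optional output directory (created if needed).
#' @return list of class `pipeline_result` with `field` (filtered
#'   displacement), `strain`, `skeleton`, `cod` (NULL when no crack was
#'   found) and `summary`.
#' @export
run_pipeline <- function(reference, deformed, config = pipeline_config(),
                         output_dir = NULL) {
  t_all <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    t_all[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    if (config$verbose)
      message(sprintf("[%s] done in %.2fs", name, t_all[[name]]))
    res
  }
  if (is.character(reference))
    reference <- read_gray_image(reference, config$pixel_scale)
  if (is.character(deformed))
    deformed <- read_gray_image(deformed, config$pixel_scale)
  if (!is.null(output_dir) &&
      !dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  emit <- function(name, writer) {
    if (!is.null(output_dir)) writer(file.path(output_dir, name))
  }

  dc <- as_dic_config(config)
  field <- stage("match", compute_displacement_field(reference, deformed,
                                                     config = dc))
  field$pixel_scale <- config$pixel_scale
  emit("displacement.csv", function(p)
    write.csv(as.data.frame(field), p, row.names = FALSE))
  field <- stage("median_filter",
                 median_filter_field(field, config$median_kernel))
  g <- static_series_error(list(field))$g

  strain <- stage("strain",
                  strain_from_displacement(field,
                                           window = config$strain_window))
  emit("strain.csv", function(p)
    write.csv(as.data.frame(strain), p, row.names = FALSE))

  high <- if (is.na(config$high)) NULL else config$high
  low <- if (is.na(config$low)) NULL else config$low
  skeleton <- stage("extract", suppressWarnings(
    extract_crack(strain, high = high, low = low,
                  high_quantile = config$high_quantile,
                  low_quantile = config$low_quantile,
                  min_component = config$min_component,
                  closing_radius = config$closing_radius,
                  prune = config$prune)))
  mask <- attr(skeleton, "mask")
  emit("mask.png", function(p) png::writePNG(mask$pixels * 1, p))
  mp <- main_path(skeleton)
  if (!is.null(mp))
    emit("skeleton.csv", function(p)
      write.csv(data.frame(x = mp[, 1], y = mp[, 2]), p,
                row.names = FALSE))

  cod <- NULL
  if (!is.null(mp) && nrow(mp) >= 2) {
    band <- if (is.na(config$exclusion_band)) NULL else
      config$exclusion_band
    cod <- stage("cod", suppressWarnings(
      cod_profile(field, skeleton, window = config$cod_window,
                  pixel_scale = config$pixel_scale,
                  exclusion_band = band)))
    emit("cod.csv", function(p)
      write.csv(as.data.frame(unclass(cod)), p, row.names = FALSE))
  }

  crack_len <- if (is.null(mp) || nrow(mp) < 2) 0 else
    sum(sqrt(rowSums(diff(mp)^2)))
  cod_ok <- !is.null(cod) && any(cod$valid)
  summary <- list(
    config = unclass(config),
    grid = c(nx = length(field$grid_x), ny = length(field$grid_y)),
    n_valid = sum(field$valid),
    mean_displacement_px = g,
    max_eps_1 = if (any(strain$valid))
      max(strain$eps_1[strain$valid]) else NA,
    main_crack_length_px = crack_len,
    max_delta_n_px = if (cod_ok) max(cod$delta_n_px[cod$valid]) else NA,
    max_delta_n_um = if (cod_ok) max(cod$delta_n_um[cod$valid]) else NA,
    mean_delta_n_px = if (cod_ok) mean(cod$delta_n_px[cod$valid]) else NA,
    mean_delta_n_um = if (cod_ok) mean(cod$delta_n_um[cod$valid]) else NA,
    timings_s = t_all)
  emit("summary.json", function(p)
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null"))
  emit("config.yaml", function(p) write_pipeline_config(config, p))

  structure(list(field = field, strain = strain, skeleton = skeleton,
                 cod = cod, summary = summary),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_result>\n")
  cat(sprintf("  grid %d x %d, %d valid points, mean |d| %.4f px\n",
              s$grid[["nx"]], s$grid[["ny"]], s$n_valid,
              s$mean_displacement_px))
  cat(sprintf("  max eps_1 %.4g, main crack length %.1f px\n",
              s$max_eps_1, s$main_crack_length_px))
  if (is.finite(s$max_delta_n_px))
    cat(sprintf("  COD: max %.3f px (%.2f um), mean %.3f px\n",
                s$max_delta_n_px, s$max_delta_n_um, s$mean_delta_n_px))
  else cat("  no COD estimate (no crack found)\n")
  invisible(x)
}

#' Installation smoke test
#'
#' Generates small synthetic cases end-to-end and asserts the key
#' invariants: exact recovery of an integer translation, subpixel
#' recovery of a fractional translation within 0.1 px, machine-precision
#' strain on an exactly affine field, and recovery of a prescribed crack
#' opening within 10% from an analytic crack field.
#'
#' @param seed RNG seed for the synthetic images.
#' @param verbose print one line per check.
#' @return list with `pass` (logical) and `checks` (data frame of name,
#'   measured, expected, tolerance, pass), invisibly printed.
#' @export
self_test <- function(seed = 1L, verbose = TRUE) {
  checks <- list()
  add <- function(name, measured, expected, tol) {
    ok <- is.finite(measured) && abs(measured - expected) <= tol
    checks[[length(checks) + 1]] <<- data.frame(
      check = name, measured = measured, expected = expected,
      tolerance = tol, pass = ok)
    if (verbose)
      message(sprintf("%-34s %s (measured %.4g, expected %.4g +/- %.2g)",
                      name, if (ok) "PASS" else "FAIL", measured,
                      expected, tol))
  }
  cfg <- dic_config(subset_size = 21, search_size = 31, step = 8,
                    granularity = 0.01)
  ref <- generate_speckle(96, 96, speckle_diameter = 3, density = 600,
                          seed = seed)
  def_i <- warp_image(ref, deformation_spec("translation",
                                            translation = c(2, 1)))
  f <- compute_displacement_field(ref, def_i, config = cfg)
  add("integer translation u", mean(f$u[f$valid]), 2, 0)
  add("integer translation v", mean(f$v[f$valid]), 1, 0)
  def_s <- warp_image(ref, deformation_spec("translation",
                                            translation = c(0.5, 0)))
  fs <- compute_displacement_field(ref, def_s, config = cfg)
  add("subpixel translation u", max(abs(fs$u[fs$valid] - 0.5)), 0, 0.1)

  gx <- seq(0, 120, by = 4)
  af <- analytic_displacement_field(
    deformation_spec("affine", dudx = 0.005, dudy = 0.001, dvdx = 0.001),
    gx, gx)
  st <- strain_from_displacement(af)
  add("affine strain eps_x", max(abs(st$eps_x[st$valid] - 0.005)), 0, 1e-10)
  add("affine strain gamma_xy", max(abs(st$gamma_xy[st$valid] - 0.002)),
      0, 1e-10)

  path <- cbind(60, seq(0, 120, by = 2))
  cf <- analytic_displacement_field(
    deformation_spec("crack", path = path, opening = 0.5), gx, gx)
  prof <- suppressWarnings(cod_profile(cf, path, window = 7))
  add("crack opening recovery", max(prof$delta_n_px[prof$valid]), 0.5,
      0.05)
  checks <- do.call(rbind, checks)
  res <- list(pass = all(checks$pass), checks = checks)
  if (verbose)
    message(if (res$pass) "self-test PASSED" else "self-test FAILED")
  invisible(res)
}
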