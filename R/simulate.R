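#' Generate a ground-truth speckle image pair
#'
#' Convenience wrapper producing a reference speckle image and its warped
#' deformed counterpart for a given deformation, with the exact
#' displacement field available as ground truth.
#'
#' @param height,width image size in px.
#' @param spec a [deformation_spec()].
#' @param speckle_diameter,density,seed speckle texture parameters, see
#'   [generate_speckle()].
#' @param pixel_scale um per pixel.
#' @return list of class `speckle_pair` with `reference`, `deformed`,
#'   `spec`, and `truth`, a function `(x, y) -> cbind(u, v)`.
#' @examples
#' pair <- simulate_speckle_pair(96, 96,
#'   deformation_spec("translation", translation = c(1, 2)), seed = 7)
#' pair$truth(10, 10)
#' @export
simulate_speckle_pair <- function(height, width, spec,
                                  speckle_diameter = 4, density = 40,
                                  seed = 1L, pixel_scale = 20) {
  ref <- generate_speckle(height, width,
                          speckle_diameter = speckle_diameter,
                          density = density, seed = seed,
                          pixel_scale = pixel_scale)
  def <- warp_image(ref, spec)
  structure(list(reference = ref, deformed = def, spec = spec,
                 truth = displacement_function(spec)),
            class = "speckle_pair")
}

#' @export
print.speckle_pair <- function(x, ...) {
  cat(sprintf("<speckle_pair> %d x %d px, deformation '%s'\n",
              ncol(x$reference$pixels), nrow(x$reference$pixels),
              x$spec$kind))
  invisible(x)
}

#' Serialize a deformation spec to JSON (and back)
#'
#' @param spec a [deformation_spec()].
#' @param path JSON file path.
#' @return `write_deformation_spec()` returns `path` invisibly;
#'   `read_deformation_spec()` the reconstructed [deformation_spec()].
#' @export
write_deformation_spec <- function(spec, path) {
  p <- spec$parameters
  if (spec$kind == "crack")
    p$path <- apply(p$path, 2, identity) # keep matrix as array of rows
  if (spec$kind == "composite")
    stop("composite specs cannot be serialized to a flat JSON file")
  jsonlite::write_json(list(kind = spec$kind, parameters = p,
                            noise_sigma = spec$noise_sigma,
                            seed = spec$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_deformation_spec
#' @export
read_deformation_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- as.list(x$parameters)
  if (x$kind == "crack") p$path <- as.matrix(p$path)
  do.call(deformation_spec,
          c(list(kind = x$kind), p,
            list(noise_sigma = x$noise_sigma, seed = x$seed)))
}
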