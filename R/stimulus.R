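#' Centre-surround grating stimulus specification
#'
#' Geometry and contrast of the stimuli: a striped circular centre of 0.7
#' degrees diameter (small enough to fall entirely inside the rod-free
#' central fovea) inside a striped surround of 6 degrees exterior diameter.
#' The stripes are a sinusoid of 1.4 cycles/degree — chosen so that about one
#' full cycle fits inside the centre — at Michelson contrast 0.99 and phase
#' 0. The centre-surround border is sharp; the exterior edge is smoothed over
#' 0.25 degrees. The display resolution was 40 pixels/degree.
#'
#' A stimulus is continuous (type C) when centre and surround share the same
#' orientation and discontinuous (type D) when they are orthogonal.
#'
#' @param center_orientation,surround_orientation `"vertical"` or
#'   `"horizontal"`.
#' @param center_diameter,surround_diameter,spatial_frequency,contrast,phase,edge_smoothing,pixels_per_degree
#'   Geometry and contrast parameters; defaults as above.
#' @return A list of class `stimulus_spec`.
#' @export
stimulus_spec <- function(center_orientation = "vertical",
                          surround_orientation = "vertical",
                          center_diameter = 0.7,
                          surround_diameter = 6,
                          spatial_frequency = 1.4,
                          contrast = 0.99,
                          phase = 0,
                          edge_smoothing = 0.25,
                          pixels_per_degree = 40) {
  center_orientation <- match.arg(center_orientation,
                                  c("vertical", "horizontal"))
  surround_orientation <- match.arg(surround_orientation,
                                    c("vertical", "horizontal"))
  stopifnot(pixels_per_degree > 0, contrast >= 0, contrast <= 1,
            center_diameter > 0, surround_diameter > center_diameter)
  structure(
    list(center_orientation = center_orientation,
         surround_orientation = surround_orientation,
         center_diameter = center_diameter,
         surround_diameter = surround_diameter,
         spatial_frequency = spatial_frequency,
         contrast = contrast, phase = phase,
         edge_smoothing = edge_smoothing,
         pixels_per_degree = pixels_per_degree,
         type = if (center_orientation == surround_orientation) "C" else "D"),
    class = "stimulus_spec"
  )
}

#' Render a stimulus to a grayscale image
#'
#' Renders the surround disc on a mean-gray background (the background equals
#' the grating mean, so the smoothed edge is luminance-neutral). The centre
#' region carries the centre orientation with a sharp border; the exterior
#' edge ramps to the background over the smoothing width with a raised-cosine
#' profile. Warns when fewer than about one full grating cycle fits inside
#' the centre.
#'
#' @param spec A [stimulus_spec()].
#' @return A list of class `stimulus`: `image` (numeric matrix in \[0, 1\],
#'   rows = vertical) and `spec`.
#' @export
render_stimulus <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (spec$spatial_frequency * spec$center_diameter < 0.95) {
    warning("fewer than about one full cycle inside the stimulus centre (",
            signif(spec$spatial_frequency * spec$center_diameter, 3),
            " cycles)")
  }
  ppd <- spec$pixels_per_degree
  npx <- round(spec$surround_diameter * ppd)
  coord <- (seq_len(npx) - (npx + 1) / 2) / ppd  # degrees, centred
  X <- matrix(coord, npx, npx, byrow = TRUE)
  Y <- matrix(coord, npx, npx)
  R <- sqrt(X^2 + Y^2)

  grating <- function(orientation) {
    u <- if (orientation == "vertical") X else Y
    0.5 + 0.5 * spec$contrast *
      sin(2 * pi * spec$spatial_frequency * u + spec$phase)
  }
  img <- matrix(0.5, npx, npx)
  half <- spec$surround_diameter / 2
  inside <- R <= half
  sur <- grating(spec$surround_orientation)
  img[inside] <- sur[inside]
  # raised-cosine ramp to background over the smoothing width
  if (spec$edge_smoothing > 0) {
    t <- pmin(pmax((half - R) / spec$edge_smoothing, 0), 1)
    w <- 0.5 - 0.5 * cos(pi * t)
    img <- 0.5 + w * (img - 0.5)
  }
  centre <- R <= spec$center_diameter / 2
  cen <- grating(spec$center_orientation)
  img[centre] <- cen[centre]
  structure(list(image = img, spec = spec), class = "stimulus")
}

#' Write a rendered stimulus as PNG with a JSON sidecar
#'
#' The image is written at 8-bit depth under a linearized-luminance
#' assumption; the sidecar echoes the specification and the nominal display
#' luminances of black, gray and white pixels per lighting condition (the
#' physical photometry is metadata only).
#'
#' @param stimulus A rendered stimulus from [render_stimulus()].
#' @param path PNG output path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stimulus <- function(stimulus, path) {
  stopifnot(inherits(stimulus, "stimulus"))
  png::writePNG(stimulus$image, path)
  meta <- c(unclass(stimulus$spec),
            list(bit_depth = 8,
                 luminance_assumption = "linearized",
                 nominal_luminance_cd_m2 = lapply(DISPLAY_LUMINANCE, as.list)))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
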