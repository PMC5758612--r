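#' Render a single Gabor patch onto a uniform field
#'
#' Evaluates the standard Gabor: a cosine carrier under an isotropic Gaussian
#' envelope, as a luminance modulation of the mean-luminance field,
#' \deqn{L(x, y) = L_m (1 + c\, e^{-(x^2+y^2)/2\sigma^2} \cos(2\pi f u + \phi))}
#' where `u` is the spatial coordinate along the modulation direction (the
#' axis perpendicular to the carrier stripes) and all spatial quantities are
#' in degrees of visual angle.
#'
#' @param contrast Michelson contrast of the patch, in `[0, 1]`; 0 renders a
#'   uniform field at mean luminance.
#' @param sf Carrier spatial frequency, cycles/deg.
#' @param orientation Carrier stripe orientation in degrees; 0 means vertical
#'   stripes (luminance modulates horizontally), 90 horizontal stripes.
#' @param sigma Gaussian envelope standard deviation, deg.
#' @param phase Carrier phase, radians.
#' @param geometry A [display_geometry()].
#' @param center Patch centre as `(row, col)` in pixel units; defaults to the
#'   display centre `((h+1)/2, (w+1)/2)` (a half-integer on even-sized
#'   displays, which keeps the rendered field mirror symmetric).
#'
#' @return A `stimulus_image`: list with `luminance` (rows x cols matrix of
#'   cd/m^2), `element_centers` (matrix of `(row, col)`), and `geometry`.
#' @export
#' @examples
#' img <- render_gabor(0.5, sf = 1, orientation = 0, sigma = 0.5,
#'                     geometry = display_geometry(129, 129))
#' max(img$luminance)  # 47.6 * 1.5 at the envelope centre
render_gabor <- function(contrast, sf, orientation = 0, sigma = 0.5,
                         phase = 0, geometry = display_geometry(),
                         center = NULL) {
  check_patch_params(contrast, sf, sigma)
  field <- matrix(geometry$mean_luminance,
                  nrow = geometry$height_px, ncol = geometry$width_px)
  if (is.null(center))
    center <- c((geometry$height_px + 1) / 2, (geometry$width_px + 1) / 2)
  field <- add_gabor(field, contrast, sf, orientation, sigma, phase,
                     geometry, center)
  structure(list(luminance = field,
                 element_centers = matrix(center, nrow = 1,
                                          dimnames = list("target", c("row", "col"))),
                 geometry = geometry),
            class = "stimulus_image")
}

check_patch_params <- function(contrast, sf, sigma) {
  if (sf <= 0) stop("spatial frequency must be positive", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (contrast < 0 || contrast > 1)
    stop("contrast must be a Michelson value in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

# Add one Gabor modulation to a luminance field, in place. Coordinates are
# degrees relative to the patch centre; only a +/- 5 sigma window is touched.
add_gabor <- function(field, contrast, sf, orientation, sigma, phase,
                      geometry, center) {
  if (contrast == 0) return(field)
  deg_per_px <- geometry$arcmin_per_pixel / 60
  half <- ceiling(5 * sigma / deg_per_px)
  rows <- max(1, floor(center[1] - half)):min(nrow(field), ceiling(center[1] + half))
  cols <- max(1, floor(center[2] - half)):min(ncol(field), ceiling(center[2] + half))
  y <- (rows - center[1]) * deg_per_px
  x <- (cols - center[2]) * deg_per_px
  th <- orientation * pi / 180
  # u = x cos(theta) + y sin(theta): theta = 0 modulates along x
  u <- outer(y * sin(th), x * cos(th), `+`)
  env <- outer(y^2, x^2, `+`)
  mod <- contrast * exp(-env / (2 * sigma^2)) * cos(2 * pi * sf * u + phase)
  field[rows, cols] <- field[rows, cols] +
    geometry$mean_luminance * mod
  field
}

#' Render the three-Gabor lateral-masking triplet
#'
#' Places the target Gabor at the display centre and the two flankers at
#' `+/- separation_lambda * lambda` along the global axis. Collinear flankers
#' share the target's carrier orientation; orthogonal flankers are rotated by
#' 90 degrees. Pixel offsets are computed in degrees and rounded to the
#' nearest integer pixel.
#'
#' @param config A [stimulus_config()].
#' @return A `stimulus_image` with `element_centers` rows named
#'   `flanker_above`/`flanker_left`, `target`, `flanker_below`/`flanker_right`.
#' @export
render_triplet <- function(config) {
  stopifnot(inherits(config, "stimulus_config"))
  geom <- config$geometry
  deg_per_px <- geom$arcmin_per_pixel / 60
  offset_px <- round(config$separation_lambda * config$wavelength_lambda / deg_per_px)
  center <- c((geom$height_px + 1) / 2, (geom$width_px + 1) / 2)

  vertical <- config$global_axis == "vertical"
  step <- if (vertical) c(offset_px, 0) else c(0, offset_px)
  centers <- rbind(center - step, center, center + step)
  rownames(centers) <- if (vertical)
    c("flanker_above", "target", "flanker_below")
  else c("flanker_left", "target", "flanker_right")
  colnames(centers) <- c("row", "col")

  out_of_bounds <- centers[, 1] < 1 | centers[, 1] > geom$height_px |
    centers[, 2] < 1 | centers[, 2] > geom$width_px
  if (any(out_of_bounds))
    stop(sprintf("flanker centre falls outside the display at separation %g lambda",
                 config$separation_lambda), call. = FALSE)

  # stripe orientation: vertical arrangement pairs with vertical stripes so
  # that collinear flankers continue the target's orientation axis
  target_ori <- if (vertical) 0 else 90
  flank_ori <- if (config$orientation_condition == "collinear")
    target_ori else target_ori + 90

  field <- matrix(geom$mean_luminance, nrow = geom$height_px, ncol = geom$width_px)
  field <- add_gabor(field, config$target_contrast, config$spatial_frequency,
                     target_ori, config$gabor_sigma, config$phase, geom, centers[2, ])
  for (i in c(1, 3))
    field <- add_gabor(field, config$flanker_contrast, config$spatial_frequency,
                       flank_ori, config$gabor_sigma, config$phase, geom, centers[i, ])

  structure(list(luminance = field, element_centers = centers, geometry = geom),
            class = "stimulus_image")
}

#' Measure the Michelson contrast of a rendered patch
#'
#' Recovers the Michelson contrast of the carrier grating from the peak
#' luminance excursion about the mean within a square window (half-width
#' `radius_px`) around a centre: with peak excursion `A = max|L - L_m|`,
#' the carrier's `(Lmax - Lmin) / (Lmax + Lmin)` is `A / L_m`. The raw
#' max/min ratio of the windowed region itself would underestimate the
#' carrier contrast, because the Gaussian envelope attenuates the troughs
#' nearest the envelope peak. Exact for even-symmetric (cosine-phase)
#' patches, the default rendering; used to verify contrast fidelity of the
#' continuous (pre-quantisation) image.
#'
#' @param image A `stimulus_image`.
#' @param center `(row, col)` centre of the region; defaults to the target.
#' @param radius_px Half-width of the measurement window in pixels.
#' @return Michelson contrast of the carrier within the region.
#' @export
measure_michelson <- function(image, center = NULL, radius_px = NULL) {
  stopifnot(inherits(image, "stimulus_image"))
  if (is.null(center)) center <- image$element_centers["target", ]
  if (is.null(radius_px))
    radius_px <- ceiling(1.5 * 60 / image$geometry$arcmin_per_pixel)
  rows <- max(1, floor(center[1] - radius_px)):min(nrow(image$luminance),
                                                   ceiling(center[1] + radius_px))
  cols <- max(1, floor(center[2] - radius_px)):min(ncol(image$luminance),
                                                   ceiling(center[2] + radius_px))
  region <- image$luminance[rows, cols]
  lm <- image$geometry$mean_luminance
  max(abs(region - lm)) / lm
}

#' Export a stimulus image
#'
#' `write_stimulus_png()` maps luminance linearly so that mean luminance is
#' mid-gray (`L / (2 L_m)`, clamped to `[0, 1]`), quantises to the geometry's
#' bit depth and writes an 8-bit grayscale PNG. `write_stimulus_matrix()`
#' writes the continuous luminance values as a plain-text matrix for
#' inspection and testing.
#'
#' @param image A `stimulus_image`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_stimulus_png <- function(image, path) {
  stopifnot(inherits(image, "stimulus_image"))
  g <- image$luminance / (2 * image$geometry$mean_luminance)
  g <- pmin(pmax(g, 0), 1)
  levels <- 2^image$geometry$bit_depth - 1
  g <- round(g * levels) / levels
  png::writePNG(g, target = path)
  invisible(path)
}

#' @rdname write_stimulus_png
#' @export
write_stimulus_matrix <- function(image, path) {
  stopifnot(inherits(image, "stimulus_image"))
  utils::write.table(format(image$luminance, digits = 8), file = path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
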