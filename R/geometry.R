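#' Display geometry for a lateral-masking experiment
#'
#' Bundles the geometric and photometric description of the display on which
#' stimuli are rendered. The defaults describe a 1024 x 768 CRT with a pixel
#' pitch of 2.14 arcmin and a mean luminance of 47.6 cd/m^2, the setup used
#' for the packaged threshold tables.
#'
#' @param width_px,height_px Display size in pixels.
#' @param arcmin_per_pixel Angular subtense of one pixel, in arcmin.
#' @param mean_luminance Mean (background) luminance in cd/m^2.
#' @param bit_depth Luminance quantisation depth used on export only; the
#'   internal luminance representation is continuous.
#'
#' @return An object of class `display_geometry`.
#' @export
#' @examples
#' geom <- display_geometry()
#' geom$arcmin_per_pixel
display_geometry <- function(width_px = 1024L, height_px = 768L,
                             arcmin_per_pixel = 2.14,
                             mean_luminance = 47.6,
                             bit_depth = 8L) {
  if (width_px <= 0 || height_px <= 0)
    stop("display dimensions must be positive", call. = FALSE)
  if (arcmin_per_pixel <= 0)
    stop("arcmin_per_pixel must be positive", call. = FALSE)
  if (mean_luminance <= 0)
    stop("mean_luminance must be positive", call. = FALSE)
  if (bit_depth < 1)
    stop("bit_depth must be at least 1", call. = FALSE)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 arcmin_per_pixel = arcmin_per_pixel,
                 mean_luminance = mean_luminance,
                 bit_depth = as.integer(bit_depth)),
            class = "display_geometry")
}

#' Configuration of one three-Gabor lateral-masking display
#'
#' Describes a single trial display: a central target Gabor flanked above and
#' below (or left and right) by two Gabors at a given multiple of the carrier
#' wavelength lambda. In the collinear configuration the flankers share the
#' target's local orientation; in the orthogonal configuration they are
#' rotated by 90 degrees and serve as the baseline controlling for spatial
#' uncertainty.
#'
#' The Gaussian envelope width `gabor_sigma` defaults to half a wavelength
#' (0.5 deg at 1 cycle/deg), a common choice that keeps the three elements
#' non-overlapping at the shortest standard separation of 3 lambda. The
#' carrier phase defaults to 0 (even-symmetric cosine phase).
#'
#' @param separation_lambda Centre-to-centre target-to-flanker separation in
#'   multiples of the carrier wavelength; standard values are 3, 4, 6, 8.
#' @param orientation_condition `"collinear"` or `"orthogonal"`.
#' @param target_contrast,flanker_contrast Michelson contrasts in (0, 1].
#' @param spatial_frequency Carrier spatial frequency in cycles/deg.
#' @param global_axis Axis along which the three elements are arranged,
#'   `"vertical"` or `"horizontal"`. The target's carrier stripes are
#'   perpendicular to this axis, so collinear flankers continue the target's
#'   orientation along the arrangement axis.
#' @param gabor_sigma Gaussian envelope standard deviation in deg;
#'   default `0.5 / spatial_frequency` wavelengths, i.e. lambda/2.
#' @param phase Carrier phase in radians.
#' @param geometry A [display_geometry()].
#'
#' @return An object of class `stimulus_config`.
#' @export
stimulus_config <- function(separation_lambda,
                            orientation_condition = c("collinear", "orthogonal"),
                            target_contrast = 0.2,
                            flanker_contrast = 0.6,
                            spatial_frequency = 1,
                            global_axis = c("vertical", "horizontal"),
                            gabor_sigma = 0.5 / spatial_frequency,
                            phase = 0,
                            geometry = display_geometry()) {
  orientation_condition <- match.arg(orientation_condition)
  global_axis <- match.arg(global_axis)
  if (spatial_frequency <= 0)
    stop("spatial_frequency must be positive", call. = FALSE)
  if (separation_lambda <= 0)
    stop("separation_lambda must be positive (flankers may not coincide with the target)",
         call. = FALSE)
  for (c_ in c(target = target_contrast, flanker = flanker_contrast))
    if (c_ <= 0 || c_ > 1)
      stop("contrasts must be Michelson values in (0, 1]", call. = FALSE)
  if (gabor_sigma <= 0) stop("gabor_sigma must be positive", call. = FALSE)
  stopifnot(inherits(geometry, "display_geometry"))
  structure(list(spatial_frequency = spatial_frequency,
                 wavelength_lambda = 1 / spatial_frequency,
                 separation_lambda = separation_lambda,
                 orientation_condition = orientation_condition,
                 global_axis = global_axis,
                 target_contrast = target_contrast,
                 flanker_contrast = flanker_contrast,
                 gabor_sigma = gabor_sigma,
                 phase = phase,
                 geometry = geometry),
            class = "stimulus_config")
}
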