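#' Acquisition geometry and illumination configuration
#'
#' Describes the lensless in-line geometry: a coherent multi-wavelength
#' source illuminates the specimen with a plane wave and a bare sensor at
#' distance `z_nominal` records one intensity frame per wavelength. The
#' simulation grid (at `grid_pitch`) oversamples the sensor grid (at
#' `sensor_pitch`) by an integer block-averaging factor.
#'
#' @param wavelengths vacuum wavelengths in micrometres. Defaults to three
#'   visible channels (0.45, 0.52, 0.63) spanning blue/green/red so that
#'   amplitude reconstructions compose directly into an RGB image.
#' @param grid_shape integer `(rows, cols)` of the sample-plane simulation
#'   grid; both must be even.
#' @param grid_pitch sample-plane sampling in micrometres per pixel.
#' @param sensor_pitch sensor sampling in micrometres per pixel; must be an
#'   integer multiple of `grid_pitch`.
#' @param z_nominal nominal sample-to-sensor distance (micrometres).
#' @param z_jitter maximal random offset of the true distance from
#'   `z_nominal` (micrometres); the true distance is drawn uniformly in
#'   `z_nominal +/- z_jitter` at acquisition time.
#' @param well_depth sensor saturation level in ADU (analog-digital units).
#' @param illum_level mean intensity (ADU) recorded through a clear field;
#'   the simulated exposure is set so an empty slide sits well below
#'   saturation.
#' @param tile_area nominal specimen area covered by one acquisition tile
#'   (mm^2); metadata only, carried through to hologram records.
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config(grid_shape = c(256, 256))
#' cfg
#' @export
optical_config <- function(wavelengths = c(0.45, 0.52, 0.63),
                           grid_shape = c(1024L, 1024L),
                           grid_pitch = 0.25,
                           sensor_pitch = 1.0,
                           z_nominal = 500,
                           z_jitter = 20,
                           well_depth = 4095,
                           illum_level = 0.45 * well_depth,
                           tile_area = 100) {
  wavelengths <- as.numeric(wavelengths)
  grid_shape <- as.integer(grid_shape)
  if (anyDuplicated(wavelengths)) stop("wavelengths must be distinct")
  if (any(wavelengths < 0.3 | wavelengths > 0.8))
    stop("wavelengths must lie in [0.3, 0.8] um (visible band)")
  if (length(grid_shape) != 2 || any(grid_shape <= 0) || any(grid_shape %% 2 != 0))
    stop("grid_shape must be two positive even integers")
  if (grid_pitch <= 0) stop("grid_pitch must be positive")
  ratio <- sensor_pitch / grid_pitch
  if (abs(ratio - round(ratio)) > 1e-9 || round(ratio) < 1)
    stop("sensor_pitch must be a positive integer multiple of grid_pitch")
  if (z_nominal <= 10 * max(wavelengths))
    stop("z_nominal must exceed 10x the longest wavelength")
  if (z_jitter < 0) stop("z_jitter must be non-negative")
  if (well_depth <= 0 || illum_level <= 0 || illum_level > well_depth)
    stop("need 0 < illum_level <= well_depth")
  structure(list(
    wavelengths = wavelengths,
    grid_shape = grid_shape,
    grid_pitch = grid_pitch,
    sensor_pitch = sensor_pitch,
    z_nominal = z_nominal,
    z_jitter = z_jitter,
    well_depth = well_depth,
    illum_level = illum_level,
    tile_area = tile_area
  ), class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Lensless acquisition configuration\n")
  cat(sprintf("  wavelengths : %s um\n", paste(x$wavelengths, collapse = ", ")))
  cat(sprintf("  grid        : %d x %d at %.3g um/px\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_pitch))
  cat(sprintf("  sensor pitch: %.3g um/px (%dx binning)\n", x$sensor_pitch,
              as.integer(round(x$sensor_pitch / x$grid_pitch))))
  cat(sprintf("  z           : %g um (+/- %g um jitter)\n", x$z_nominal, x$z_jitter))
  cat(sprintf("  well depth  : %g ADU, clear-field level %g ADU\n",
              x$well_depth, x$illum_level))
  invisible(x)
}

# Physical field extent (width, height) in micrometres.
field_extent <- function(config) {
  c(config$grid_shape[2] * config$grid_pitch,
    config$grid_shape[1] * config$grid_pitch)
}

# Tile area implied by the grid, in mm^2.
grid_area_mm2 <- function(config) {
  ex <- field_extent(config)
  ex[1] * ex[2] * 1e-6
}

#' Two-chromophore Gram stain color model
#'
#' A minimal spectral model of the Gram stain: a crystal-violet-like
#' chromophore (absorbs green strongly and red moderately, transmitting a
#' violet/purple hue) and a safranin-like counterstain (absorbs green and
#' blue, transmitting pink). Each bacterium carries a linear mix of the two
#' controlled by its Gram reaction and the slide's stain quality:
#' over-decolorization (`stain_quality < 0`) moves Gram positives toward the
#' counterstain, under-decolorization (`> 0`) leaves crystal violet on Gram
#' negatives. The conversion only engages beyond `|stain_quality| = 0.3`, so
#' moderately imperfect stains keep their nominal color separation.
#'
#' The hue bands are the interpretation-side counterpart of the same model:
#' the purple and pink band centers are the asymptotic hues of the two pure
#' chromophores under this renderer, so generator and classifier form a
#' linked pair.
#'
#' @param extinction_cv,extinction_sf per-wavelength extinction coefficients
#'   of the two chromophores, ordered from shortest to longest configured
#'   wavelength.
#' @param stain_strength peak optical density of a fully stained cell at the
#'   most absorbed wavelength.
#' @param purple_center,purple_halfwidth,pink_center,pink_halfwidth hue band
#'   parameters in circular degrees.
#' @return An object of class `gram_color_model`.
#' @export
gram_color_model <- function(extinction_cv = c(0.30, 1.00, 0.60),
                             extinction_sf = c(0.70, 1.00, 0.15),
                             stain_strength = 1.0,
                             purple_center = 272, purple_halfwidth = 48,
                             pink_center = 342, pink_halfwidth = 22) {
  structure(list(
    extinction_cv = extinction_cv,
    extinction_sf = extinction_sf,
    stain_strength = stain_strength,
    purple_center = purple_center,
    purple_halfwidth = purple_halfwidth,
    pink_center = pink_center,
    pink_halfwidth = pink_halfwidth
  ), class = "gram_color_model")
}

# Extinction vector for one object given its Gram reaction and the slide's
# stain quality. Conversion fraction ramps from 0 at |q|=0.3 to 1 at |q|=1.
object_extinction <- function(model, gram_reaction, stain_quality) {
  if (gram_reaction == "not_applicable") {
    # red cells / debris: weak, nearly neutral absorption (low saturation)
    return(c(0.35, 0.42, 0.33) * 0.9)
  }
  conv <- min(1, max(0, (abs(stain_quality) - 0.3) / 0.7))
  if (gram_reaction == "positive") {
    # over-decolorized positives pick up counterstain
    f <- if (stain_quality < 0) conv else 0
    (1 - f) * model$extinction_cv + f * model$extinction_sf
  } else {
    # under-decolorized negatives retain crystal violet
    f <- if (stain_quality > 0) conv else 0
    (1 - f) * model$extinction_sf + f * model$extinction_cv
  }
}
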