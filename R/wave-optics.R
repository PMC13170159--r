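#' Complex optical field
#'
#' A monochromatic scalar field sampled on a uniform grid.
#'
#' @param values 2D complex (or numeric) matrix of field values.
#' @param pitch sampling pitch in micrometres per pixel.
#' @param wavelength vacuum wavelength in micrometres.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(values, pitch, wavelength) {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stop("field values must be finite")
  if (pitch <= 0) stop("pitch must be positive")
  if (wavelength <= 0) stop("wavelength must be positive")
  structure(list(values = values + 0i, pitch = pitch, wavelength = wavelength),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("complex_field: %d x %d, pitch %.4g um, lambda %.3g um\n",
              nrow(x$values), ncol(x$values), x$pitch, x$wavelength))
  invisible(x)
}

# Angular-spectrum transfer function phase kernel, cached per geometry.
asm_kernel <- local({
  cache <- new.env(parent = emptyenv())
  function(nr, nc, pitch, wavelength, band_limit, z_for_limit = 0) {
    key <- paste(nr, nc, pitch, wavelength, band_limit, z_for_limit, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    fx <- fft_freq(nc, pitch)
    fy <- fft_freq(nr, pitch)
    f2 <- outer(fy^2, fx^2, `+`)
    arg <- 1 / wavelength^2 - f2
    prop <- arg > 0
    kz <- matrix(0, nr, nc)
    kz[prop] <- 2 * pi * sqrt(arg[prop])
    mask <- prop
    if (band_limit && z_for_limit != 0) {
      # Matsushima-Shimobaba anti-aliasing limit for the sampled chirp
      dfx <- 1 / (nc * pitch); dfy <- 1 / (nr * pitch)
      fxl <- 1 / (wavelength * sqrt((2 * dfx * abs(z_for_limit))^2 + 1))
      fyl <- 1 / (wavelength * sqrt((2 * dfy * abs(z_for_limit))^2 + 1))
      mask <- mask & outer(abs(fy) <= fyl, abs(fx) <= fxl, `&`)
    }
    out <- list(kz = kz, mask = mask)
    if (length(cache) > 64) rm(list = ls(cache), envir = cache)
    cache[[key]] <- out
    out
  }
})

#' Angular-spectrum free-space propagation
#'
#' Propagates a complex field a distance `z` by multiplying its spatial
#' spectrum with the exact scalar transfer function
#' `exp(i 2 pi z sqrt(1/lambda^2 - fx^2 - fy^2))`. Evanescent components
#' (`fx^2 + fy^2 > 1/lambda^2`) are set to zero, so the operator is unitary
#' on the propagating band and `propagate(propagate(f, z), -z)` recovers any
#' band-limited field to numerical precision. With `band_limit = TRUE` the
#' transfer function is additionally truncated where its sampled chirp
#' aliases (useful for very large `z` relative to the field size); the
#' default keeps the full propagating band, treating the simulation as
#' periodic in the transverse plane.
#'
#' @param field a [complex_field()].
#' @param z propagation distance in micrometres (positive: toward the
#'   sensor; negative: back-propagation).
#' @param band_limit apply the anti-aliasing frequency limit.
#' @return The propagated [complex_field()].
#' @examples
#' f <- complex_field(matrix(1 + 0i, 64, 64), pitch = 0.5, wavelength = 0.52)
#' g <- propagate(f, 100)      # a plane wave stays plane
#' max(Mod(g$values - f$values[1, 1]))
#' @export
propagate <- function(field, z, band_limit = FALSE) {
  stopifnot(inherits(field, "complex_field"))
  if (!is.finite(z)) stop("z must be finite")
  if (z == 0 && !band_limit) return(field)
  v <- field$values
  k <- asm_kernel(nrow(v), ncol(v), field$pitch, field$wavelength,
                  band_limit, if (band_limit) z else 0)
  spec <- stats::fft(v)
  H <- exp(1i * z * k$kz)
  H[!k$mask] <- 0i
  out <- stats::fft(spec * H, inverse = TRUE) / length(v)
  complex_field(out, field$pitch, field$wavelength)
}

#' Record a multi-wavelength intensity hologram of a phantom
#'
#' Simulates one acquisition: for each configured wavelength a unit plane
#' wave passes through the phantom's transmittance (objects at distinct
#' axial offsets are applied as successive multiply-and-propagate planes),
#' travels the true sample-to-sensor distance
#' `z_true = z_nominal + U(-z_jitter, z_jitter)`, and its squared modulus is
#' scaled to the clear-field exposure level, block-averaged to the sensor
#' pitch, degraded by Poisson-like shot noise and Gaussian read noise,
#' clipped to the sensor well depth and quantized to integer ADU.
#'
#' @param phantom a `specimen_phantom` rendered on the same grid as
#'   `config`.
#' @param config an [optical_config()]; defaults to the phantom's own.
#' @param seed integer seed controlling distance jitter and noise; the same
#'   seed reproduces the frames bit-exactly.
#' @param noise list with `shot_scale` (>= 0; 1 means photon counts equal
#'   ADU counts, 0 disables shot noise) and `read_sigma` (Gaussian read
#'   noise sd in ADU, 0 disables).
#' @return An object of class `hologram`: list of per-wavelength integer
#'   intensity `frames`, the `config`, hidden ground-truth `z_true`
#'   (test-only metadata), `well_depth`, `illum_level`, `tile_area`.
#' @export
record_hologram <- function(phantom, config = phantom$config, seed = 1L,
                            noise = list(shot_scale = 1, read_sigma = 5)) {
  stopifnot(inherits(phantom, "specimen_phantom"))
  if (!identical(dim(phantom$transmittance[[1]]),
                 c(config$grid_shape[1], config$grid_shape[2])))
    stop("phantom grid does not match the configuration grid")
  if (length(phantom$transmittance) != length(config$wavelengths))
    stop("phantom wavelength count does not match the configuration")
  shot <- noise$shot_scale %||% 1
  read <- noise$read_sigma %||% 5
  bin <- as.integer(round(config$sensor_pitch / config$grid_pitch))

  with_seed(seed, {
    z_true <- config$z_nominal +
      if (config$z_jitter > 0) runif(1, -config$z_jitter, config$z_jitter) else 0
    frames <- vector("list", length(config$wavelengths))
    # planes sorted by decreasing distance to the sensor (increasing z_offset
    # means closer to the sensor)
    ord <- order(vapply(phantom$planes, `[[`, numeric(1), "z_offset"))
    for (w in seq_along(config$wavelengths)) {
      lam <- config$wavelengths[w]
      u <- NULL
      z_at <- NULL
      for (k in ord) {
        pl <- phantom$planes[[k]]
        if (is.null(u)) {
          u <- complex_field(pl$fields[[w]], config$grid_pitch, lam)
        } else {
          u <- propagate(u, pl$z_offset - z_at)
          u <- complex_field(u$values * pl$fields[[w]], config$grid_pitch, lam)
        }
        z_at <- pl$z_offset
      }
      u <- propagate(u, z_true - z_at)
      intens <- Mod(u$values)^2 * config$illum_level
      intens <- block_average(intens, bin)
      if (shot > 0)
        intens <- rpois(length(intens), lambda = as.vector(intens) * shot) / shot
      if (read > 0)
        intens <- intens + rnorm(length(intens), 0, read)
      intens <- matrix(pmin(pmax(round(intens), 0), config$well_depth),
                       config$grid_shape[1] %/% bin,
                       config$grid_shape[2] %/% bin)
      frames[[w]] <- intens
    }
    structure(list(frames = frames, config = config, z_true = z_true,
                   well_depth = config$well_depth,
                   illum_level = config$illum_level,
                   tile_area = config$tile_area,
                   noise = list(shot_scale = shot, read_sigma = read)),
              class = "hologram")
  })
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("hologram: %d frames of %d x %d at %.3g um/px\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$config$sensor_pitch))
  invisible(x)
}

#' Write and read holograms
#'
#' Frames are stored as a multi-page uint16 TIFF (one page per wavelength,
#' ADU counts) with a JSON sidecar holding the configuration, noise
#' settings and (optionally redacted) true distance. Because frames are
#' integer ADU, the round trip is bit-exact.
#'
#' @param holo a `hologram`.
#' @param path base path without extension.
#' @param redact_z drop the ground-truth distance from the sidecar.
#' @return `write_hologram()` the base path, invisibly; `read_hologram()`
#'   the restored `hologram` (with `z_true = NA` if redacted).
#' @export
write_hologram <- function(holo, path, redact_z = FALSE) {
  stopifnot(inherits(holo, "hologram"))
  pages <- lapply(holo$frames, function(f) f / 65535)
  tiff::writeTIFF(pages, paste0(path, ".tif"), bits.per.sample = 16L,
                  reduce = FALSE)
  side <- list(schema_version = 1L,
               config = unclass(holo$config),
               z_true = if (redact_z) NULL else holo$z_true,
               well_depth = holo$well_depth,
               illum_level = holo$illum_level,
               tile_area = holo$tile_area,
               noise = holo$noise)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_hologram
#' @export
read_hologram <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- do.call(optical_config, side$config[names(side$config) != "tile_area"])
  cfg$tile_area <- side$config$tile_area
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  frames <- lapply(pages, function(p) matrix(round(p * 65535), nrow(p), ncol(p)))
  zt <- side$z_true
  if (is.null(zt) || !length(zt)) zt <- NA_real_
  structure(list(frames = frames, config = cfg,
                 z_true = zt,
                 well_depth = side$well_depth,
                 illum_level = side$illum_level,
                 tile_area = side$tile_area,
                 noise = side$noise),
            class = "hologram")
}
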