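#' Hologram tile quality features
#'
#' Computes the feature vector driving the rule-based quality triage of a
#' single hologram frame. When the acquisition geometry is supplied, the
#' content features are measured on a coarsely focused low-resolution
#' amplitude image (the frame's square-root intensity back-propagated to a
#' handful of candidate distances around the nominal one, keeping the
#' sharpest), because at these field sizes the raw interference fringes of
#' even a single organism cover the whole tile; without a geometry the raw
#' frame is used.
#'
#' \describe{
#'   \item{fringe_energy}{fraction of non-DC spectral energy above a radial
#'     frequency cutoff (micron-scale organisms diffract into this band;
#'     coarse debris does not).}
#'   \item{occupancy}{fraction of pixels deviating by more than a relative
#'     contrast from the clear-field background level (90th percentile,
#'     floored at a quarter of the clear-field level so a fully
#'     extinguished frame reads as occupied).}
#'   \item{saturation_frac}{fraction of raw pixels at the well depth.}
#'   \item{dead_frac}{fraction of raw pixels at zero.}
#'   \item{texture_entropy}{Shannon entropy (bits) of a 32-bin intensity
#'     histogram of the raw frame.}
#' }
#'
#' @param frame 2D intensity matrix (ADU).
#' @param config optional [optical_config()]; enables the focused-amplitude
#'   content features.
#' @param channel wavelength index used when `config` is given. The default
#'   picks the middle (green) channel, where both stain chromophores absorb
#'   most strongly, so occupancy is insensitive to the Gram reaction.
#' @param occ_contrast relative deviation from background counted as
#'   occupied.
#' @param fringe_cut radial frequency cutoff in cycles/pixel (of the
#'   feature image).
#' @param downsample block-averaging factor for the focused feature image.
#' @return named numeric feature vector.
#' @export
extract_features <- function(frame, config = NULL, channel = 2L,
                             occ_contrast = 0.15, fringe_cut = 0.06,
                             downsample = 2L) {
  if (!is.matrix(frame) || length(frame) == 0)
    stop("extract_features: need a non-empty frame")
  well <- if (is.null(config)) 4095 else config$well_depth
  saturation_frac <- mean(frame >= well)
  dead_frac <- mean(frame <= 0)
  h <- tabulate(pmin(pmax(floor(frame / well * 32) + 1, 1), 32), 32)
  ph <- h[h > 0] / sum(h)
  texture_entropy <- -sum(ph * log2(ph))

  if (is.null(config)) {
    img <- frame
    bg <- max(quantile(img, 0.9), 0.25 * well)
  } else {
    a <- pmax(frame, 0) / config$illum_level
    if (downsample > 1L) a <- block_average(a, as.integer(downsample))
    pitch <- config$sensor_pitch * max(downsample, 1L)
    lam <- config$wavelengths[min(channel, length(config$wavelengths))]
    f <- complex_field(sqrt(a) + 0i, pitch, lam)
    span <- max(config$z_jitter, 1)
    zs <- config$z_nominal + seq(-span, span, length.out = 5)
    sharp <- focus_metric("edge_sparsity")
    amps <- lapply(zs, function(z) Mod(propagate(f, -z)$values))
    img <- amps[[which.max(vapply(amps, sharp, numeric(1)))]]
    # clear-field amplitude is ~1; the floor keeps a fully extinguished
    # frame (amplitude everywhere far below 1) reading as occupied
    bg <- max(quantile(img, 0.9), 0.5)
  }
  occupancy <- mean(abs(img - bg) > occ_contrast * bg)
  ac <- img - mean(img)
  spec <- Mod(stats::fft(ac))^2
  tot <- sum(spec)
  if (tot > 0) {
    fr <- sqrt(outer(fft_freq(nrow(img))^2, fft_freq(ncol(img))^2, `+`))
    fringe_energy <- sum(spec[fr > fringe_cut]) / tot
  } else fringe_energy <- 0

  c(fringe_energy = fringe_energy, occupancy = occupancy,
    saturation_frac = saturation_frac, dead_frac = dead_frac,
    texture_entropy = texture_entropy)
}

#' Triage decision thresholds
#'
#' Defaults were calibrated once on the seeded synthetic tile suite
#' (`scripts/calibrate_triage.R`). The sparse/dense occupancy cut must sit
#' below the too-thick cut, and the hardware cuts must lie in (0, 1].
#'
#' @param sat_cut,dead_cut saturated / dead pixel fractions above which a
#'   frame is a hardware failure.
#' @param thick_cut occupancy above which the specimen is too thick.
#' @param fringe_collapse fringe-energy level below which a heavily
#'   occupied frame (occupancy above `(thick_cut + dense_cut) / 2`) counts
#'   as extinguished, hence too thick.
#' @param occ_floor occupancy below which no sample is present.
#' @param fringe_floor minimal fringe-energy fraction compatible with
#'   micron-scale organisms; occupied frames below it are undefined debris.
#' @param dense_cut occupancy separating valid sparse from valid dense.
#' @return named list of thresholds.
#' @export
triage_thresholds <- function(sat_cut = 0.2, dead_cut = 0.2,
                              thick_cut = 0.75, fringe_collapse = 0.05,
                              occ_floor = 1e-4, fringe_floor = 0.10,
                              dense_cut = 0.15) {
  th <- list(sat_cut = sat_cut, dead_cut = dead_cut, thick_cut = thick_cut,
             fringe_collapse = fringe_collapse, occ_floor = occ_floor,
             fringe_floor = fringe_floor, dense_cut = dense_cut)
  if (!(dense_cut < thick_cut))
    stop("triage thresholds: dense_cut must lie below thick_cut")
  if (!(occ_floor < dense_cut))
    stop("triage thresholds: occ_floor must lie below dense_cut")
  if (sat_cut <= 0 || sat_cut > 1 || dead_cut <= 0 || dead_cut > 1)
    stop("triage thresholds: saturation/dead cuts must lie in (0, 1]")
  th
}

#' Six-category quality vocabulary
#' @return character vector of the triage categories.
#' @export
quality_categories <- function() {
  c("no_sample", "valid_sparse", "valid_dense", "invalid_too_thick",
    "hardware_failure", "undefined_debris")
}

#' Classify a feature vector into a quality category
#'
#' Fixed-order decision list: hardware failure (saturated or dead) first,
#' then too thick (occupancy above the thick cut, or heavy occupancy with
#' collapsed fringes), then no sample (occupancy below the floor), then
#' undefined debris (occupied but without the high-frequency fringe energy
#' micron-scale organisms produce), and finally valid dense vs valid
#' sparse by occupancy. Exactly one category always results; only the two
#' valid categories gate a tile into reconstruction.
#'
#' @param features named vector from [extract_features()].
#' @param thresholds a [triage_thresholds()] list.
#' @return An object of class `quality_label`: `category`, `is_valid`,
#'   `features`.
#' @export
classify_quality <- function(features, thresholds = triage_thresholds()) {
  th <- do.call(triage_thresholds, thresholds)  # re-validate ordering
  f <- as.list(features)
  heavy <- (th$thick_cut + th$dense_cut) / 2
  category <-
    if (f$saturation_frac > th$sat_cut || f$dead_frac > th$dead_cut)
      "hardware_failure"
    else if (f$occupancy > th$thick_cut ||
             (f$occupancy > heavy && f$fringe_energy < th$fringe_collapse))
      "invalid_too_thick"
    else if (f$occupancy < th$occ_floor)
      "no_sample"
    else if (f$fringe_energy < th$fringe_floor)
      "undefined_debris"
    else if (f$occupancy > th$dense_cut)
      "valid_dense"
    else
      "valid_sparse"
  structure(list(category = category,
                 is_valid = category %in% c("valid_sparse", "valid_dense"),
                 features = features),
            class = "quality_label")
}

#' @export
print.quality_label <- function(x, ...) {
  cat(sprintf("quality_label: %s (%s)\n", x$category,
              if (x$is_valid) "valid" else "invalid"))
  invisible(x)
}

#' Triage all tiles of a slide
#'
#' Applies [classify_quality()] to each hologram tile, returns the valid
#' subset and the valid fraction, and records a per-tile quality map. A
#' slide with no valid tile is flagged rejected and excluded from
#' downstream interpretation.
#'
#' @param holograms list of `hologram` objects (the slide's tiles).
#' @param thresholds a [triage_thresholds()] list.
#' @param channel wavelength channel used for feature extraction.
#' @return list with `labels` (per-tile `quality_label`), `quality_map`
#'   (character vector of categories), `valid` (indices of valid tiles),
#'   `valid_fraction`, `rejected` (TRUE when no tile is valid).
#' @export
triage_slide <- function(holograms, thresholds = triage_thresholds(),
                         channel = 2L) {
  if (length(holograms) < 1) stop("triage_slide: need at least one hologram")
  labels <- lapply(holograms, function(h) {
    stopifnot(inherits(h, "hologram"))
    ch <- min(channel, length(h$frames))
    classify_quality(extract_features(h$frames[[ch]], config = h$config,
                                      channel = ch),
                     thresholds)
  })
  cats <- vapply(labels, `[[`, character(1), "category")
  valid <- which(vapply(labels, `[[`, logical(1), "is_valid"))
  list(labels = labels,
       quality_map = cats,
       valid = valid,
       valid_fraction = length(valid) / length(holograms),
       rejected = length(valid) == 0)
}

#' Seeded synthetic tile suite for triage calibration and testing
#'
#' Builds `n` tiles with known construction labels covering all six
#' categories. Empty, sparse and dense tiles are physically simulated
#' phantom acquisitions; the red-cell background scales with bacterial
#' density, since a thickly smeared specimen is dense in all of its
#' content, not only organisms. Sparse/dense tiles are regenerated until
#' they contain at least three bacteria, so every construction label is
#' truthful. Hardware failures are saturated or dead frames; too-thick
#' tiles carry nearly extinguished transmitted light; debris tiles carry
#' only coarse blob structure without micron-scale fringes.
#'
#' @param n number of tiles.
#' @param seed integer seed.
#' @param config an [optical_config()] used for the simulated tiles.
#' @return list with `frames` (intensity matrices), `labels` (construction
#'   categories), `config`.
#' @export
triage_suite <- function(n = 200, seed = 1,
                         config = optical_config(grid_shape = c(192, 192),
                                                 grid_pitch = 0.25,
                                                 sensor_pitch = 0.25,
                                                 z_nominal = 300,
                                                 z_jitter = 30)) {
  wd <- config$well_depth
  probs <- c(no_sample = 0.2, valid_sparse = 0.2, valid_dense = 0.2,
             invalid_too_thick = 0.125, hardware_failure = 0.125,
             undefined_debris = 0.15)
  gen_content <- function(dens_range, rc_factor, s) {
    repeat {
      lab <- sample(slide_classes(), 1)
      dens <- runif(1, dens_range[1], dens_range[2])
      ph <- generate_phantom(config, lab, density = dens, seed = s,
                             red_cell_density = dens * rc_factor,
                             max_attempts = 50000L)
      if (sum(ph$objects$kind %in% c("coccus", "bacillus")) >= 3) break
      s <- s + 7919L
    }
    record_hologram(ph, config, seed = s)$frames[[2]]
  }
  with_seed(seed, {
    labels <- sample(names(probs), n, replace = TRUE, prob = probs)
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      s <- sample.int(1e8, 1)
      frames[[i]] <- switch(labels[i],
        no_sample = {
          ph <- phantom_from_objects(config, NULL, "GNB")
          record_hologram(ph, config, seed = s)$frames[[2]]
        },
        valid_sparse = gen_content(c(1200, 3500), 0.10, s),
        valid_dense = gen_content(c(15000, 30000), 0.12, s),
        invalid_too_thick = {
          # heavy smear: transmitted light nearly extinguished everywhere
          lvl <- runif(1, 0.01, 0.06) * wd
          matrix(pmin(pmax(round(lvl * runif(config$grid_shape[1] *
                                              config$grid_shape[2],
                                             0.4, 1.6)), 0), wd),
                 config$grid_shape[1], config$grid_shape[2])
        },
        hardware_failure = {
          if (runif(1) < 0.5) matrix(wd, config$grid_shape[1], config$grid_shape[2])
          else matrix(0, config$grid_shape[1], config$grid_shape[2])
        },
        undefined_debris = {
          # coarse blobs only: no micron-scale diffraction structure
          nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
          base <- matrix(config$illum_level, nr, nc)
          for (b in seq_len(sample(2:5, 1))) {
            cx <- runif(1, 0.2, 0.8) * nc; cy <- runif(1, 0.2, 0.8) * nr
            sg <- runif(1, 8, 20)
            blob <- outer(seq_len(nr) - cy, seq_len(nc) - cx,
                          function(a, b) exp(-(a^2 + b^2) / (2 * sg^2)))
            base <- base * (1 - runif(1, 0.5, 0.9) * blob)
          }
          matrix(pmin(pmax(round(base + rnorm(nr * nc, 0, 5)), 0), wd), nr, nc)
        })
    }
    list(frames = frames, labels = labels, config = config)
  })
}
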