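#' Image sharpness by Tenengrad contrast
#'
#' Mean squared centred-difference gradient magnitude of an amplitude
#' image. Invariant to adding a constant, zero for constant images and
#' strictly positive otherwise; used as the autofocus contrast score.
#'
#' @param amplitude non-negative 2D array.
#' @return scalar score (>= 0).
#' @export
focus_score <- function(amplitude) tenengrad(amplitude)

# Named focus metrics. Tenengrad (mean squared gradient) is maximal at
# focus for absorption-dominated scenes; edge sparsity (negated gradient
# l1 norm) is maximal at focus for amplitude AND phase objects, because a
# focused field has the sparsest edges, while defocus spreads phase
# structure into amplitude ripples. Both are invariant to adding a
# constant.
focus_metric <- function(name = c("edge_sparsity", "tenengrad")) {
  name <- match.arg(name)
  switch(name,
    tenengrad = tenengrad,
    edge_sparsity = function(a) {
      if (all(is.na(a))) stop("focus metric: all-NaN input")
      n <- nrow(a); m <- ncol(a)
      if (n < 3 || m < 3) return(0)
      gx <- (a[, 3:m, drop = FALSE] - a[, 1:(m - 2), drop = FALSE]) / 2
      gy <- (a[3:n, , drop = FALSE] - a[1:(n - 2), , drop = FALSE]) / 2
      -(mean(abs(gx)) + mean(abs(gy)))
    })
}

#' Coarse computational autofocus
#'
#' Estimates the sample-to-sensor distance by back-propagating the square
#' root of a single wavelength channel's intensity to a uniform grid of at
#' least 30 candidate distances spanning at least 200 micrometres, scoring
#' each amplitude image with [focus_score()] at reduced resolution, and
#' taking the argmax (ties broken toward the smaller distance).
#'
#' @param hologram a `hologram`.
#' @param z_min,z_max scan range in micrometres; `z_max - z_min` must be at
#'   least 200.
#' @param n_slices number of candidate distances, at least 30.
#' @param channel wavelength index used for the scan.
#' @param downsample integer block-averaging factor applied to the frame
#'   before propagation (low-resolution scan).
#' @param metric named focus metric: `"edge_sparsity"` (default; maximal at
#'   focus for amplitude and phase objects alike) or `"tenengrad"` (the
#'   classical contrast score, suited to absorption-dominated scenes).
#' @return An object of class `focus_curve`: data frame `samples` with
#'   columns `z` and `score`, the estimate `z_hat`, and `at_boundary`
#'   (TRUE when the argmax sits on the scan edge, signalling that the true
#'   focus may lie outside the range).
#' @export
coarse_focus <- function(hologram, z_min, z_max, n_slices = 30L,
                         channel = 1L, downsample = 2L,
                         metric = c("edge_sparsity", "tenengrad")) {
  stopifnot(inherits(hologram, "hologram"))
  if (z_max - z_min < 200)
    stop("coarse_focus: scan span must be at least 200 um")
  if (n_slices < 30) stop("coarse_focus: need at least 30 slices")
  cfg <- hologram$config
  a <- sqrt(pmax(hologram$frames[[channel]], 0) / hologram$illum_level)
  pitch <- cfg$sensor_pitch
  if (downsample > 1L) {
    a <- sqrt(block_average(a^2, as.integer(downsample)))
    pitch <- pitch * downsample
  }
  score_fun <- focus_metric(match.arg(metric))
  f <- complex_field(a + 0i, pitch, cfg$wavelengths[channel])
  zs <- seq(z_min, z_max, length.out = n_slices)
  scores <- vapply(zs, function(z) score_fun(Mod(propagate(f, -z)$values)),
                   numeric(1))
  # report scores on a non-negative scale (argmax unchanged)
  if (min(scores) < 0) scores <- scores - min(scores)
  idx <- which.max(scores)          # which.max takes the first (smaller z) tie
  structure(list(samples = data.frame(z = zs, score = scores),
                 z_hat = zs[idx],
                 at_boundary = idx == 1L || idx == n_slices),
            class = "focus_curve")
}

#' @export
print.focus_curve <- function(x, ...) {
  cat(sprintf("focus_curve: %d slices over [%.4g, %.4g] um, z_hat = %.4g um%s\n",
              nrow(x$samples), min(x$samples$z), max(x$samples$z), x$z_hat,
              if (x$at_boundary) " (at range boundary)" else ""))
  invisible(x)
}

#' Fine autofocus refinement
#'
#' Scans a narrow window around a coarse distance estimate at full sensor
#' resolution and sub-micrometre steps, scoring back-propagated amplitude
#' images with the chosen focus metric. Because the reconstruction's depth
#' of field is below a micrometre at these numerical apertures, phase
#' retrieval needs the sample plane localized much better than the coarse
#' 200-micrometre scan provides.
#'
#' @param hologram a `hologram`.
#' @param z0 coarse distance estimate (micrometres), e.g. from
#'   [coarse_focus()].
#' @param span half-width of the refinement window (micrometres).
#' @param step scan step (micrometres).
#' @param channel wavelength index.
#' @param metric focus metric name, as in [coarse_focus()].
#' @return refined z estimate (micrometres).
#' @export
refine_focus <- function(hologram, z0, span = 8, step = 0.5, channel = 2L,
                         metric = c("edge_sparsity", "tenengrad")) {
  stopifnot(inherits(hologram, "hologram"))
  cfg <- hologram$config
  a <- sqrt(pmax(hologram$frames[[channel]], 0) / hologram$illum_level)
  f <- complex_field(a + 0i, cfg$sensor_pitch, cfg$wavelengths[channel])
  score_fun <- focus_metric(match.arg(metric))
  zs <- seq(z0 - span, z0 + span, by = step)
  scores <- vapply(zs, function(z) score_fun(Mod(propagate(f, -z)$values)),
                   numeric(1))
  zs[which.max(scores)]
}

#' Multi-wavelength Gerchberg-Saxton phase retrieval
#'
#' Recovers the complex specimen field from intensity-only holograms by
#' alternating projections between the sensor and sample planes, cycling
#' over wavelength channels in ascending order. At the sensor plane the
#' amplitude is replaced by the measured square-root intensity while the
#' current phase is kept; the field is then back-propagated to the sample
#' plane, where the channels are coupled through a thin-object
#' optical-path-length model: the retrieved phase of channel c is converted
#' to a shared optical path length map (`OPL = phase * lambda / 2 pi`) that
#' seeds the phase of the next channel, while each channel keeps its own
#' amplitude (stain absorption is wavelength dependent). Iteration stops at
#' `max_iters` or when the relative change of the sensor-plane amplitude
#' residual drops below `tol`. The converged sample-plane field is finally
#' propagated to 30 axial slices at 1 micrometre steps centred on `z_hat`
#' (offsets -15..+14).
#'
#' @param hologram a `hologram`; multi-spectral mode needs >= 2 wavelengths
#'   (a single channel is allowed and flagged in the result).
#' @param z_hat estimated sample-to-sensor distance (micrometres),
#'   typically from [coarse_focus()].
#' @param max_iters maximum full channel cycles (>= 1).
#' @param tol relative residual-change stopping threshold.
#' @param init `"flat"` (default) starts from a clear slide (unit
#'   amplitude, zero phase), which avoids the stagnation the
#'   hologram-back-propagation start exhibits at some distances;
#'   `"backprop"` starts from the measured first-channel amplitude with
#'   zero phase, back-propagated to the sample plane.
#' @param amp_max object-domain amplitude bound applied at the sample
#'   plane. A stained smear is a passive absorber, so its transmittance
#'   amplitude cannot exceed 1; clamping the sample-plane amplitude to this
#'   bound is the constraint that suppresses the in-line twin image. Set to
#'   `NULL` to disable.
#' @param out_na numerical aperture of the output slices: each slice is
#'   low-passed to spatial frequencies below `out_na / lambda`, giving all
#'   channels the same optical resolution and a depth of field
#'   (~lambda/NA^2) compatible with the 1-micrometre slice spacing. The
#'   retrieval itself always runs at the full sensor band. `NULL` disables
#'   the limit.
#' @return An object of class `recon_stack`: `z_grid` (30 sensor distances),
#'   `amplitude` and `phase` (lists over wavelengths of
#'   rows x cols x 30 arrays), `sample_field` (converged per-channel
#'   complex sample-plane fields), `gs_residuals` (per-cycle RMS sensor
#'   amplitude mismatch, recorded before each projection), `converged`,
#'   `pitch`, `z_hat`, `multispectral`.
#' @export
gs_reconstruct <- function(hologram, z_hat, max_iters = 100L, tol = 1e-4,
                           init = c("flat", "backprop"), amp_max = 1,
                           out_na = 0.7) {
  stopifnot(inherits(hologram, "hologram"))
  if (max_iters < 1) stop("max_iters must be at least 1")
  cfg <- hologram$config
  lam <- cfg$wavelengths
  nw <- length(lam)
  pitch <- cfg$sensor_pitch
  meas <- lapply(hologram$frames, function(f)
    sqrt(pmax(f, 0) / hologram$illum_level))
  nr <- nrow(meas[[1]]); nc <- ncol(meas[[1]])

  init <- match.arg(init)
  amp <- vector("list", nw)
  if (init == "backprop") {
    u0 <- propagate(complex_field(meas[[1]] + 0i, pitch, lam[1]), -z_hat)
    for (w in seq_len(nw)) amp[[w]] <- Mod(u0$values)
    opl <- Arg(u0$values) * lam[1] / (2 * pi)
  } else {
    for (w in seq_len(nw)) amp[[w]] <- matrix(1, nr, nc)
    opl <- matrix(0, nr, nc)
  }

  residuals <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    res2 <- 0
    for (w in seq_len(nw)) {
      u <- complex_field(amp[[w]] * exp(1i * 2 * pi * opl / lam[w]), pitch, lam[w])
      v <- propagate(u, z_hat)
      res2 <- res2 + mean((Mod(v$values) - meas[[w]])^2)
      vproj <- meas[[w]] * exp(1i * Arg(v$values))
      b <- propagate(complex_field(vproj, pitch, lam[w]), -z_hat)
      a <- Mod(b$values)
      if (!is.null(amp_max)) a <- pmin(a, amp_max)
      amp[[w]] <- a
      opl <- Arg(b$values) * lam[w] / (2 * pi)
    }
    residuals <- c(residuals, sqrt(res2 / nw))
    if (it > 1) {
      prev <- residuals[it - 1]
      if (prev > 0 && abs(prev - residuals[it]) / prev < tol) {
        converged <- TRUE
        break
      }
      if (prev == 0) { converged <- TRUE; break }
    }
  }

  sample_field <- lapply(seq_len(nw), function(w)
    amp[[w]] * exp(1i * 2 * pi * opl / lam[w]))

  offsets <- seq(-15L, 14L)
  z_grid <- z_hat + offsets
  amplitude <- vector("list", nw)
  phase <- vector("list", nw)
  fr2 <- outer(fft_freq(nr, pitch)^2, fft_freq(nc, pitch)^2, `+`)
  for (w in seq_len(nw)) {
    A <- array(0, dim = c(nr, nc, length(offsets)))
    P <- array(0, dim = c(nr, nc, length(offsets)))
    fld <- sample_field[[w]]
    if (!is.null(out_na)) {
      keep <- fr2 <= (out_na / lam[w])^2
      fld <- stats::fft(stats::fft(fld) * keep, inverse = TRUE) / length(fld)
    }
    f <- complex_field(fld, pitch, lam[w])
    for (k in seq_along(offsets)) {
      # slice at sensor distance z_grid[k]: move the sample-plane estimate
      # forward by (z_hat - z_grid[k])
      s <- propagate(f, z_hat - z_grid[k])
      A[, , k] <- Mod(s$values)
      P[, , k] <- Arg(s$values)
    }
    amplitude[[w]] <- A
    phase[[w]] <- P
  }

  structure(list(z_grid = z_grid, amplitude = amplitude, phase = phase,
                 sample_field = sample_field, gs_residuals = residuals,
                 converged = converged, pitch = pitch, z_hat = z_hat,
                 wavelengths = lam, multispectral = nw >= 2),
            class = "recon_stack")
}

#' @export
print.recon_stack <- function(x, ...) {
  cat(sprintf("recon_stack: %d wavelengths, 30 slices over [%.4g, %.4g] um\n",
              length(x$amplitude), min(x$z_grid), max(x$z_grid)))
  cat(sprintf("  %d GS cycles, final residual %.3g, converged: %s\n",
              length(x$gs_residuals), tail(x$gs_residuals, 1), x$converged))
  invisible(x)
}

# Mean-over-wavelengths amplitude of slice k.
slice_amplitude <- function(stack, k) {
  a <- stack$amplitude[[1]][, , k]
  nw <- length(stack$amplitude)
  if (nw > 1) {
    for (w in 2:nw) a <- a + stack$amplitude[[w]][, , k]
    a <- a / nw
  }
  a
}

#' Per-object focal selection
#'
#' For each object mask, selects the axial slice of the reconstruction
#' stack maximizing the focus metric restricted to the mask (per-pixel
#' gradient scores of the wavelength-averaged amplitude, averaged over the
#' mask). Ties are broken toward the slice nearest the stack centre.
#' Background pixels take the globally best slice.
#'
#' @param stack a `recon_stack`.
#' @param masks list of logical matrices (object masks) matching the slice
#'   shape; empty masks are skipped with a warning.
#' @param metric per-object score: `"absorption"` (default) selects the
#'   slice where the masked mean amplitude is lowest — a stained organism
#'   absorbs most strongly exactly in focus, and unlike gradient scores
#'   this is immune to the contrast ringing its phase structure creates at
#'   sub-micrometre defocus; `"edge_sparsity"` and `"tenengrad"` score
#'   masked gradients as in [coarse_focus()]. The background/global slice
#'   is always chosen by whole-frame edge sparsity.
#' @return list with `object_z` (numeric vector, NA for skipped masks),
#'   `object_slice` (slice indices), `focus_map` (matrix of selected z per
#'   pixel), `global_z`.
#' @export
per_object_focus <- function(stack, masks,
                             metric = c("absorption", "edge_sparsity",
                                        "tenengrad")) {
  metric <- match.arg(metric)
  stopifnot(inherits(stack, "recon_stack"))
  nslice <- length(stack$z_grid)
  dims <- dim(stack$amplitude[[1]])[1:2]
  centre <- (nslice + 1) / 2
  # precompute per-slice squared gradient fields and global scores
  g2 <- vector("list", nslice)
  global_scores <- numeric(nslice)
  for (k in seq_len(nslice)) {
    a <- slice_amplitude(stack, k)
    n <- nrow(a); m <- ncol(a)
    gx <- matrix(0, n, m); gy <- matrix(0, n, m)
    gx[, 2:(m - 1)] <- (a[, 3:m] - a[, 1:(m - 2)]) / 2
    gy[2:(n - 1), ] <- (a[3:n, ] - a[1:(n - 2), ]) / 2
    g2[[k]] <- switch(metric,
      tenengrad = gx^2 + gy^2,
      edge_sparsity = -(abs(gx) + abs(gy)),
      absorption = -a)
    global_scores[k] <- -mean(abs(gx) + abs(gy))  # whole-frame sharpness
  }
  pick <- function(scores) {
    best <- which(scores == max(scores))
    best[which.min(abs(best - centre))]
  }
  g_idx <- pick(global_scores)
  focus_map <- matrix(stack$z_grid[g_idx], dims[1], dims[2])
  object_z <- rep(NA_real_, length(masks))
  object_slice <- rep(NA_integer_, length(masks))
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (!any(m)) {
      warning("per_object_focus: empty mask ", i, " skipped")
      next
    }
    if (!all(dim(m) == dims)) stop("mask ", i, " does not match slice shape")
    sc <- vapply(seq_len(nslice), function(k) mean(g2[[k]][m]), numeric(1))
    k <- pick(sc)
    object_slice[i] <- k
    object_z[i] <- stack$z_grid[k]
    focus_map[m] <- stack$z_grid[k]
  }
  list(object_z = object_z, object_slice = object_slice,
       focus_map = focus_map, global_z = stack$z_grid[g_idx])
}

#' Compose a color image from a reconstruction stack
#'
#' Per pixel, takes each wavelength's amplitude at the slice selected by
#' `focus_map`, maps wavelengths to RGB primaries by spectral order
#' (longest wavelength to red, shortest to blue), applies a display gamma
#' and clips to `[0, 1]`. Amplitudes are relative to unit illumination, so
#' an empty scene composes to a near-uniform bright image.
#'
#' @param stack a `recon_stack`.
#' @param focus_map matrix of per-pixel z (micrometres, within the stack's
#'   z range) or NULL for the globally best slice everywhere.
#' @param gamma display gamma.
#' @param provenance identifier carried along (source hologram id).
#' @return An object of class `color_image`: `rgb` (rows x cols x 3 array in
#'   `[0,1]`), `focus_map`, `pitch`, `provenance`.
#' @export
compose_color <- function(stack, focus_map = NULL, gamma = 2.2,
                          provenance = NA_character_) {
  stopifnot(inherits(stack, "recon_stack"))
  dims <- dim(stack$amplitude[[1]])[1:2]
  if (is.null(focus_map)) {
    pf <- per_object_focus(stack, list())
    focus_map <- pf$focus_map
  }
  if (!all(dim(focus_map) == dims))
    stop("focus_map shape does not match the stack")
  ki <- match(round(focus_map - stack$z_grid[1]) + 1L,
              seq_along(stack$z_grid))
  if (anyNA(ki)) stop("focus_map values outside the stack z range")
  ord <- order(stack$wavelengths, decreasing = TRUE)  # R, G, B
  rgb <- array(0, dim = c(dims[1], dims[2], 3))
  idx <- cbind(rep(seq_len(dims[1]), dims[2]),
               rep(seq_len(dims[2]), each = dims[1]),
               as.vector(ki))
  for (ch in 1:3) {
    w <- ord[ch]
    rgb[, , ch] <- matrix(stack$amplitude[[w]][idx], dims[1], dims[2])
  }
  rgb <- pmin(pmax(rgb, 0), 1)^(1 / gamma)
  structure(list(rgb = rgb, focus_map = focus_map, pitch = stack$pitch,
                 provenance = provenance),
            class = "color_image")
}

#' @export
print.color_image <- function(x, ...) {
  cat(sprintf("color_image: %d x %d at %.3g um/px\n",
              dim(x$rgb)[1], dim(x$rgb)[2], x$pitch))
  invisible(x)
}

#' Write a color image to PNG and/or float TIFF
#'
#' @param image a `color_image`.
#' @param path base path without extension.
#' @param formats subset of `c("png", "tiff")`.
#' @return base path, invisibly.
#' @export
write_color_image <- function(image, path, formats = c("png", "tiff")) {
  stopifnot(inherits(image, "color_image"))
  if ("tiff" %in% formats)
    tiff::writeTIFF(image$rgb, paste0(path, ".tif"), bits.per.sample = 32L,
                    reduce = FALSE)
  if ("png" %in% formats && requireNamespace("png", quietly = TRUE))
    png::writePNG(image$rgb, paste0(path, ".png"))
  invisible(path)
}
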