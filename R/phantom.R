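#' Synthetic Gram-stained blood-culture smear phantoms
#'
#' `generate_phantom()` builds a seeded synthetic smear for one of the three
#' slide classes seen in monomicrobial positive blood cultures:
#' Gram-negative bacilli (`"GNB"`), Gram-positive cocci in clusters
#' (`"GPC_clusters"`), and Gram-positive cocci in pairs and chains
#' (`"GPC_pairs_chains"`). Bacteria are placed by a seeded point process
#' that respects the class arrangement (independent rods; Gaussian clumps
#' of at least four cocci; collinear runs of 2-12 touching cocci), a
#' red-cell background is added, and the scene is rendered as one complex
#' transmittance field per configured wavelength under the two-chromophore
#' stain model (see [gram_color_model()]): absorption encodes the stain
#' color, a phase delay proportional to object thickness encodes optical
#' path length.
#'
#' @param config an [optical_config()].
#' @param label slide class, one of `"GNB"`, `"GPC_clusters"`,
#'   `"GPC_pairs_chains"`.
#' @param density target bacterial density in objects per mm^2 (individual
#'   cells, not groups). Positive blood-culture broth smears are organism
#'   rich; the default reflects several organisms per high-power field.
#' @param stain_quality scalar in `[-1, 1]`; negative values emulate
#'   over-decolorization (positives drift pink), positive values
#'   under-decolorization (negatives drift purple). 0 is a nominal stain.
#' @param seed integer seed; the same `(config, arguments, seed)` always
#'   reproduces the phantom bit-exactly.
#' @param red_cell_density red blood cell background density per mm^2.
#' @param z_spread half-range (micrometres) of per-group axial offsets;
#'   0 (the default) places every object on the slide plane.
#' @param color_model a [gram_color_model()].
#' @param dn refractive-index contrast of the dried specimen against its
#'   surround; sets the phase delay per micrometre of thickness. `dn = 0`
#'   renders a pure-amplitude (absorption only) phantom.
#' @param max_attempts bound on rejection-sampling retries while placing
#'   arrangement groups; exceeding it raises a "specimen too dense" error.
#' @return An object of class `specimen_phantom` with fields `objects`
#'   (data frame of scene objects), `true_label`, `density`,
#'   `stain_quality`, `transmittance` (list of complex matrices, one per
#'   wavelength), `planes` (per-axial-plane transmittance used by the
#'   multi-plane forward model), `seed`, `config`, `color_model`.
#' @examples
#' cfg <- optical_config(grid_shape = c(256, 256))
#' ph <- generate_phantom(cfg, "GNB", density = 2000, seed = 1)
#' ph
#' @export
generate_phantom <- function(config, label,
                             density = 4000,
                             stain_quality = 0,
                             seed = 1L,
                             red_cell_density = 400,
                             z_spread = 0,
                             color_model = gram_color_model(),
                             dn = 0.08,
                             max_attempts = 4000L) {
  stopifnot(inherits(config, "optical_config"))
  label <- match.arg(label, slide_classes())
  if (density <= 0) stop("density must be positive")
  if (abs(stain_quality) > 1) stop("stain_quality must lie in [-1, 1]")
  if (z_spread < 0 || z_spread > 15)
    stop("z_spread must lie in [0, 15] um (half the reconstruction span)")

  objects <- with_seed(seed, place_objects(config, label, density,
                                           red_cell_density, z_spread,
                                           max_attempts))
  phantom_from_objects(config, objects, label,
                       density = density, stain_quality = stain_quality,
                       seed = seed, color_model = color_model, dn = dn)
}

#' Slide class vocabulary
#' @return character vector of the three slide classes.
#' @export
slide_classes <- function() c("GNB", "GPC_clusters", "GPC_pairs_chains")

#' Build a phantom from an explicit object table
#'
#' Lower-level constructor used by [generate_phantom()] and useful for
#' controlled experiments (e.g. two objects at known axial offsets).
#'
#' @param config an [optical_config()].
#' @param objects data frame with columns `kind` (coccus, bacillus,
#'   red_cell, debris), `x`, `y` (centre, micrometres), `size1`, `size2`
#'   (diameter for round kinds; length and width for bacilli),
#'   `orientation` (radians), `gram` (positive, negative, not_applicable),
#'   `group_id` (integer), `z_offset` (micrometres, |z| <= 15).
#' @param label slide class label recorded as ground truth.
#' @param density,stain_quality,seed,color_model,dn as in
#'   [generate_phantom()].
#' @return A `specimen_phantom`.
#' @export
phantom_from_objects <- function(config, objects, label,
                                 density = NA_real_, stain_quality = 0,
                                 seed = NA_integer_,
                                 color_model = gram_color_model(),
                                 dn = 0.08) {
  stopifnot(inherits(config, "optical_config"))
  objects <- validate_objects(objects, config)
  rend <- render_transmittance(config, objects, stain_quality, color_model, dn)
  structure(list(
    objects = objects,
    true_label = label,
    density = density,
    stain_quality = stain_quality,
    transmittance = rend$projected,
    planes = rend$planes,
    seed = seed,
    config = config,
    color_model = color_model,
    dn = dn
  ), class = "specimen_phantom")
}

#' @export
print.specimen_phantom <- function(x, ...) {
  nb <- sum(x$objects$kind %in% c("coccus", "bacillus"))
  cat(sprintf("Synthetic smear phantom: %s\n", x$true_label))
  cat(sprintf("  %d bacteria, %d red cells on a %d x %d grid (%.3g um/px)\n",
              nb, sum(x$objects$kind == "red_cell"),
              x$config$grid_shape[1], x$config$grid_shape[2],
              x$config$grid_pitch))
  cat(sprintf("  stain_quality %.2f, seed %s\n", x$stain_quality,
              format(x$seed)))
  invisible(x)
}

empty_objects <- function() {
  data.frame(kind = character(), x = numeric(), y = numeric(),
             size1 = numeric(), size2 = numeric(), orientation = numeric(),
             gram = character(), group_id = integer(), z_offset = numeric(),
             stringsAsFactors = FALSE)
}

validate_objects <- function(objects, config) {
  if (is.null(objects) || nrow(objects) == 0) return(empty_objects())
  need <- c("kind", "x", "y", "size1", "size2", "orientation", "gram",
            "group_id", "z_offset")
  miss <- setdiff(need, names(objects))
  if (length(miss)) stop("objects missing columns: ", paste(miss, collapse = ", "))
  ex <- field_extent(config)
  if (any(objects$x < 0 | objects$x > ex[1] | objects$y < 0 | objects$y > ex[2]))
    stop("object centre outside the field extent")
  if (any(objects$size1 <= 0) || any(objects$size2 <= 0))
    stop("object sizes must be positive")
  cc <- objects$kind == "coccus"
  if (any(cc & (objects$size1 < 0.5 | objects$size1 > 1.5)))
    stop("coccus diameters must lie in [0.5, 1.5] um")
  bb <- objects$kind == "bacillus"
  if (any(bb & objects$size1 <= objects$size2))
    stop("bacillus length must exceed width")
  if (any(abs(objects$z_offset) > 15))
    stop("|z_offset| must not exceed 15 um")
  objects
}

# ---- seeded placement ------------------------------------------------------

place_objects <- function(config, label, density, red_cell_density,
                          z_spread, max_attempts) {
  ex <- field_extent(config)
  area <- grid_area_mm2(config)
  margin <- 1.5
  n_target <- rpois(1, density * area)
  rejects <- 0L
  placed <- empty_objects()
  group_id <- 0L

  propose_anchor <- function() c(runif(1, margin, ex[1] - margin),
                                 runif(1, margin, ex[2] - margin))

  group_ok <- function(g) {
    if (any(g$x < margin | g$x > ex[1] - margin |
            g$y < margin | g$y > ex[2] - margin)) return(FALSE)
    if (nrow(placed) == 0) return(TRUE)
    prev <- placed[placed$kind %in% c("coccus", "bacillus"), , drop = FALSE]
    if (nrow(prev) == 0) return(TRUE)
    # clearance keeps distinct arrangement groups resolvable: different
    # groups stay further apart than the within-group touching distance
    rp <- (prev$size1 + prev$size2) / 4
    for (i in seq_len(nrow(g))) {
      ri <- (g$size1[i] + g$size2[i]) / 4
      d2 <- (prev$x - g$x[i])^2 + (prev$y - g$y[i])^2
      if (any(d2 < (1.8 * (ri + rp))^2)) return(FALSE)
    }
    TRUE
  }

  n_placed <- 0L
  while (n_placed < n_target) {
    group_id <- group_id + 1L
    zg <- if (z_spread > 0) round(runif(1, -z_spread, z_spread)) else 0
    g <- switch(label,
      GNB = make_rod_group(group_id, zg),
      GPC_clusters = make_cluster_group(group_id, zg),
      GPC_pairs_chains = make_chain_group(group_id, zg))
    ok <- FALSE
    while (!ok) {
      a <- propose_anchor()
      cand <- g
      cand$x <- g$x + a[1]
      cand$y <- g$y + a[2]
      if (group_ok(cand)) {
        placed <- rbind(placed, cand)
        n_placed <- n_placed + nrow(cand)
        ok <- TRUE
      } else {
        rejects <- rejects + 1L
        if (rejects > max_attempts)
          stop("specimen too dense: object placement failed after ",
               max_attempts, " attempts")
      }
    }
  }

  n_rbc <- rpois(1, red_cell_density * area)
  rbc_placed <- 0L
  tries <- 0L
  while (rbc_placed < n_rbc && tries < 40L * max(n_rbc, 1L)) {
    tries <- tries + 1L
    d <- runif(1, 6, 8)
    a <- c(runif(1, margin, ex[1] - margin), runif(1, margin, ex[2] - margin))
    bact <- placed[placed$kind %in% c("coccus", "bacillus"), , drop = FALSE]
    clash <- FALSE
    if (nrow(bact)) {
      rb <- pmax(bact$size1, bact$size2) / 2
      clash <- any((bact$x - a[1])^2 + (bact$y - a[2])^2 < (0.6 * (d / 2 + rb))^2)
    }
    if (!clash) {
      placed <- rbind(placed, data.frame(
        kind = "red_cell", x = a[1], y = a[2], size1 = d, size2 = d,
        orientation = 0, gram = "not_applicable", group_id = 0L,
        z_offset = 0, stringsAsFactors = FALSE))
      rbc_placed <- rbc_placed + 1L
    }
  }
  rownames(placed) <- NULL
  placed
}

# Independent rod, its own arrangement group; aspect ratio >= 2.1.
make_rod_group <- function(group_id, z_offset) {
  len <- runif(1, 2.2, 4.5)
  wid <- min(runif(1, 0.6, 0.95), len / 2.1)
  data.frame(kind = "bacillus", x = 0, y = 0, size1 = len, size2 = wid,
             orientation = runif(1, 0, pi), gram = "negative",
             group_id = group_id, z_offset = z_offset,
             stringsAsFactors = FALSE)
}

# Gaussian clump of >= 4 mutually proximal cocci.
make_cluster_group <- function(group_id, z_offset) {
  m <- min(4L + rpois(1, 4), 18L)
  d <- runif(1, 0.8, 1.2)
  xs <- 0; ys <- 0
  for (i in seq_len(m - 1)) {
    placed_ok <- FALSE
    best <- NULL
    for (try in 1:60) {
      j <- sample.int(length(xs), 1)
      th <- runif(1, 0, 2 * pi)
      r <- d * runif(1, 0.95, 1.25)
      px <- xs[j] + r * cos(th); py <- ys[j] + r * sin(th)
      dmin <- sqrt(min((xs - px)^2 + (ys - py)^2))
      if (is.null(best) || dmin > best$dmin) best <- list(x = px, y = py, dmin = dmin)
      if (dmin >= 0.85 * d) { placed_ok <- TRUE; break }
    }
    xs <- c(xs, best$x); ys <- c(ys, best$y)
  }
  data.frame(kind = "coccus", x = xs - mean(xs), y = ys - mean(ys),
             size1 = d * runif(m, 0.95, 1.05), size2 = d,
             orientation = 0, gram = "positive", group_id = group_id,
             z_offset = z_offset, stringsAsFactors = FALSE)
}

# Collinear run of 2-12 cocci at touching spacing (pairs and chains).
make_chain_group <- function(group_id, z_offset) {
  m <- sample(2:12, 1, prob = c(6, 5, 4, 3, 2.5, 2, 1.5, 1.2, 1, 0.8, 0.6))
  d <- runif(1, 0.8, 1.2)
  th <- runif(1, 0, pi)
  s <- 1.05 * d
  t <- (seq_len(m) - (m + 1) / 2) * s
  perp <- rnorm(m, 0, 0.03 * d)
  data.frame(kind = "coccus",
             x = t * cos(th) - perp * sin(th),
             y = t * sin(th) + perp * cos(th),
             size1 = d * runif(m, 0.97, 1.03), size2 = d,
             orientation = th, gram = "positive", group_id = group_id,
             z_offset = z_offset, stringsAsFactors = FALSE)
}

# ---- rendering -------------------------------------------------------------

# Render objects into per-plane and projected per-wavelength complex
# transmittance. Returns list(planes = list of list(z_offset, fields),
# projected = list of complex matrices).
render_transmittance <- function(config, objects, stain_quality, color_model,
                                 dn = 0.08) {
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  p <- config$grid_pitch
  nw <- length(config$wavelengths)
  zs <- if (nrow(objects)) sort(unique(objects$z_offset)) else 0
  planes <- lapply(zs, function(z) {
    list(z_offset = z,
         od = replicate(nw, matrix(0, nr, nc), simplify = FALSE),
         opl = matrix(0, nr, nc))
  })
  names(planes) <- as.character(zs)

  if (nrow(objects)) {
    xc <- (seq_len(nc) - 1) * p  # x along columns
    yc <- (seq_len(nr) - 1) * p  # y along rows
    for (i in seq_len(nrow(objects))) {
      ob <- objects[i, ]
      key <- as.character(ob$z_offset)
      pl <- planes[[key]]
      ext <- object_extinction(color_model, ob$gram, stain_quality)
      strength <- if (ob$kind == "red_cell") 1 else color_model$stain_strength
      rad <- max(ob$size1, ob$size2) / 2 + p
      ci <- which(xc >= ob$x - rad & xc <= ob$x + rad)
      ri <- which(yc >= ob$y - rad & yc <= ob$y + rad)
      if (!length(ci) || !length(ri)) next
      dx <- xc[ci] - ob$x
      dy <- yc[ri] - ob$y
      if (ob$kind == "bacillus") {
        # capsule: distance to the central segment of half-length (L-W)/2
        h <- (ob$size1 - ob$size2) / 2
        r <- ob$size2 / 2
        co <- cos(ob$orientation); si <- sin(ob$orientation)
        u <- outer(dy, dx, function(a, b) b * co + a * si)
        v <- outer(dy, dx, function(a, b) -b * si + a * co)
        uu <- pmax(abs(u) - h, 0)
        rho2 <- uu^2 + v^2
        t <- 2 * sqrt(pmax(r^2 - rho2, 0))
        tmax <- 2 * r
      } else {
        r <- ob$size1 / 2
        rho2 <- outer(dy^2, dx^2, `+`)
        if (ob$kind == "red_cell") {
          # thin disc-like cell, ~2 um maximal thickness
          t <- 2.0 * sqrt(pmax(1 - rho2 / r^2, 0))
          tmax <- 2.0
        } else {
          t <- 2 * sqrt(pmax(r^2 - rho2, 0))
          tmax <- 2 * r
        }
      }
      tau <- t / tmax
      for (w in seq_len(nw))
        pl$od[[w]][ri, ci] <- pl$od[[w]][ri, ci] + strength * ext[w] * tau
      pl$opl[ri, ci] <- pl$opl[ri, ci] + dn * t
      planes[[key]] <- pl
    }
  }

  lam <- config$wavelengths
  plane_fields <- lapply(planes, function(pl) {
    lapply(seq_len(nw), function(w)
      exp(-pl$od[[w]]) * exp(1i * 2 * pi * pl$opl / lam[w]))
  })
  projected <- lapply(seq_len(nw), function(w) {
    f <- plane_fields[[1]][[w]]
    if (length(plane_fields) > 1)
      for (k in 2:length(plane_fields)) f <- f * plane_fields[[k]][[w]]
    f
  })
  list(planes = lapply(seq_along(planes), function(k)
         list(z_offset = planes[[k]]$z_offset, fields = plane_fields[[k]])),
       projected = projected)
}

# Boolean mask of pixels covered by one object (by row index of objects).
object_mask <- function(phantom, index, grow = 0) {
  ob <- phantom$objects[index, ]
  cfg <- phantom$config
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]; p <- cfg$grid_pitch
  xc <- (seq_len(nc) - 1) * p
  yc <- (seq_len(nr) - 1) * p
  m <- matrix(FALSE, nr, nc)
  if (ob$kind == "bacillus") {
    h <- (ob$size1 - ob$size2) / 2
    r <- ob$size2 / 2 + grow
    co <- cos(ob$orientation); si <- sin(ob$orientation)
    dx <- xc - ob$x; dy <- yc - ob$y
    u <- outer(dy, dx, function(a, b) b * co + a * si)
    v <- outer(dy, dx, function(a, b) -b * si + a * co)
    m <- (pmax(abs(u) - h, 0)^2 + v^2) <= r^2
  } else {
    r <- ob$size1 / 2 + grow
    m <- outer((yc - ob$y)^2, (xc - ob$x)^2, `+`) <= r^2
  }
  m
}

# Boolean mask of all bacterial pixels (tau above a small floor).
bacteria_mask <- function(phantom, min_tau = 0.15) {
  cfg <- phantom$config
  m <- matrix(FALSE, cfg$grid_shape[1], cfg$grid_shape[2])
  ob <- phantom$objects
  for (i in seq_len(nrow(ob))) {
    if (!ob$kind[i] %in% c("coccus", "bacillus")) next
    r <- max(ob$size1[i], ob$size2[i]) / 2
    m <- m | object_mask(phantom, i, grow = -min_tau * r * 0.5)
  }
  m
}

# ---- persistence -----------------------------------------------------------

#' Save and load a phantom
#'
#' `save_phantom()` writes the per-wavelength transmittance as a multi-page
#' float32 TIFF stack (one amplitude page then one phase page per
#' wavelength, phase scaled to `[0, 1]` over `[-pi, pi]`) and a JSON
#' manifest with a schema version, the full object table, labels, seed and
#' configuration at full double precision. `load_phantom()` reads the
#' manifest and re-renders the transmittance with the deterministic
#' renderer, so a save/load round trip reproduces every field bit-exactly;
#' the TIFF stack is a derived interchange view for external tools.
#'
#' @param phantom a `specimen_phantom`.
#' @param path base path (without extension); `<path>.tif` and
#'   `<path>.json` are written.
#' @return `save_phantom()` returns the manifest (invisibly);
#'   `load_phantom()` returns the restored `specimen_phantom`.
#' @export
save_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "specimen_phantom"))
  pages <- list()
  for (w in seq_along(phantom$transmittance)) {
    f <- phantom$transmittance[[w]]
    pages[[length(pages) + 1L]] <- Mod(f)
    pages[[length(pages) + 1L]] <- (Arg(f) + pi) / (2 * pi)
  }
  tiff_path <- paste0(path, ".tif")
  json_path <- paste0(path, ".json")
  ok <- try(tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L,
                            reduce = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("save_phantom: cannot write ", tiff_path)
  manifest <- list(
    schema_version = 1L,
    true_label = phantom$true_label,
    density = phantom$density,
    stain_quality = phantom$stain_quality,
    seed = phantom$seed,
    dn = phantom$dn,
    n_objects = nrow(phantom$objects),
    objects = phantom$objects,
    config = unclass(phantom$config),
    color_model = unclass(phantom$color_model)
  )
  jsonlite::write_json(manifest, json_path, auto_unbox = TRUE,
                       digits = I(17), dataframe = "columns")
  invisible(manifest)
}

#' @rdname save_phantom
#' @export
load_phantom <- function(path) {
  json_path <- paste0(path, ".json")
  if (!file.exists(json_path)) stop("load_phantom: no manifest at ", json_path)
  man <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  cfg <- do.call(optical_config, man$config[names(man$config) != "tile_area"])
  cfg$tile_area <- man$config$tile_area
  cm <- do.call(gram_color_model, man$color_model)
  objects <- if (man$n_objects > 0) as.data.frame(man$objects) else empty_objects()
  ph <- phantom_from_objects(cfg, objects, man$true_label,
                             density = man$density %||% NA_real_,
                             stain_quality = man$stain_quality,
                             seed = man$seed %||% NA_integer_,
                             color_model = cm, dn = man$dn %||% 0.08)
  ph
}
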