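#' Segment candidate organisms in a reconstructed color image
#'
#' Classical object evidence extraction: the bright clear field is taken as
#' background, absorbing structures are thresholded on optical density
#' (Otsu's threshold, floored so empty fields yield no detections),
#' touching cells are split by an intensity watershed on the optical
#' density image (each cell is a density peak; saddles between touching
#' cocci separate basins), and components are filtered by area. Red blood cells are
#' excluded by an upper area cut combined with their low color saturation.
#'
#' @param image a `color_image`.
#' @param params list of segmentation parameters (micrometre units):
#'   `min_area`, `max_area` area window for bacteria; `sat_floor` and
#'   `rbc_od`: an object larger than `blob_area` whose mean saturation
#'   falls below `sat_floor` and whose peak optical density stays below
#'   `rbc_od` is an unstained weak absorber (red cell) and is dropped;
#'   `od_floor` minimal optical density contrast for any detection;
#'   `watershed_tol` watershed tolerance in optical-density units (basins
#'   separated by a saddle shallower than this merge); `blob_area` area
#'   above which a detection is treated as an unresolved multi-cell clump;
#'   `cell_area` nominal single-cell area used to estimate how many cells
#'   a detection represents.
#' @return list of detections; each is a list with `id`, `pixels` (matrix
#'   indices), `mask` dimensions, `centroid` (x, y in micrometres), `area`
#'   (um^2), `circularity` (4 pi A / P^2, capped at 1), `aspect_ratio`,
#'   `hue_mean`, `hue_dispersion`, `saturation`, `focus_z`, and placeholder
#'   `gram_call` / `shape_call` (filled by [gram_and_shape()]).
#' @export
segment_objects <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "color_image"))
  rgb <- image$rgb
  p <- image$pitch
  V <- pmax(rgb[, , 1], rgb[, , 2], rgb[, , 3])
  mn <- pmin(rgb[, , 1], rgb[, , 2], rgb[, , 3])
  sat <- ifelse(V > 0, (V - mn) / V, 0)
  # optical density against the bright clear field, on the channel mean: a
  # stained object keeps its dominant channel bright, so the max channel
  # carries almost no contrast
  lum <- (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
  bright <- quantile(lum, 0.95)
  od <- pmax(bright - lum, 0)
  if (max(od) < params$od_floor) return(list())
  thr <- max(EBImage::otsu(EBImage::Image(od / max(od))) * max(od),
             params$od_floor)
  mask <- od > thr
  if (!any(mask)) return(list())
  # split touching cells: watershed on the density image within the mask
  labels <- EBImage::watershed(EBImage::Image(od * mask),
                               tolerance = params$watershed_tol, ext = 1L)
  labels <- EBImage::imageData(labels)
  nlab <- max(labels)
  if (nlab == 0) return(list())

  hue <- rgb_hue(rgb)
  out <- list()
  shp <- EBImage::computeFeatures.shape(labels)
  mom <- EBImage::computeFeatures.moment(labels)
  if (is.null(dim(shp))) { shp <- matrix(shp, nrow = 1, dimnames = list(NULL, names(shp))) }
  if (is.null(dim(mom))) { mom <- matrix(mom, nrow = 1, dimnames = list(NULL, names(mom))) }
  for (k in seq_len(nlab)) {
    npx <- shp[k, "s.area"]
    if (is.na(npx) || npx == 0) next
    area <- npx * p^2
    if (area < params$min_area) next
    perim <- max(shp[k, "s.perimeter"], 1)
    circ <- min(4 * pi * npx / perim^2, 1)
    major <- mom[k, "m.majoraxis"]
    ecc <- mom[k, "m.eccentricity"]
    minor <- max(major * sqrt(pmax(1 - ecc^2, 0)), 1)
    ar <- major / minor
    pix <- which(labels == k, arr.ind = TRUE)
    # color is read from the stained rim: deep cores are nearly black and
    # carry no reliable hue
    w <- od[pix] * (sat[pix] + 1e-3)
    hmean <- circ_mean_deg(hue[pix], w = w)
    hdisp <- circ_dispersion(hue[pix])
    smean <- sum(sat[pix] * od[pix]) / sum(od[pix])
    od_max <- max(od[pix])
    # red cells: multi-cell-sized, nearly unstained (low saturation) and
    # weakly absorbing, unlike a deep crystal-violet clump
    if (area > params$blob_area && smean < params$sat_floor &&
        od_max < params$rbc_od) next
    if (area > params$max_area) next
    cen <- c(x = (mean(pix[, 2]) - 1) * p, y = (mean(pix[, 1]) - 1) * p)
    fz <- if (!is.null(image$focus_map)) median(image$focus_map[pix]) else NA_real_
    out[[length(out) + 1L]] <- list(
      id = length(out) + 1L,
      pixels = pix,
      dim = dim(od),
      centroid = cen,
      pitch = p,
      area = area,
      est_cells = max(1L, as.integer(round(area / params$cell_area))),
      is_blob = area >= params$blob_area,
      n_pixels = npx,
      circularity = circ,
      aspect_ratio = ar,
      hue_mean = hmean,
      hue_dispersion = hdisp,
      saturation = smean,
      od_max = od_max,
      focus_z = fz,
      degenerate = npx < 2,
      gram_call = NA_character_,
      shape_call = NA_character_,
      arrangement = NA_character_
    )
  }
  out
}

#' Default segmentation parameters
#'
#' Areas in square micrometres; tuned to cocci of 0.5-1.5 um diameter and
#' bacilli up to ~5 um length, with red cells (>= ~30 um^2, weakly
#' saturated) excluded.
#' @return named list of parameters.
#' @export
segmentation_params <- function() {
  list(min_area = 0.25, max_area = 40, rbc_od = 0.30,
       sat_floor = 0.22, od_floor = 0.12, watershed_tol = 0.01,
       blob_area = 4, cell_area = 1.0)
}

# Per-pixel HSV hue in degrees for an rgb array.
rgb_hue <- function(rgb) {
  R <- rgb[, , 1]; G <- rgb[, , 2]; B <- rgb[, , 3]
  mx <- pmax(R, G, B); mn <- pmin(R, G, B)
  d <- mx - mn
  h <- matrix(0, nrow(R), ncol(R))
  i <- d > 0 & mx == R
  h[i] <- 60 * ((G - B) / d)[i]
  i <- d > 0 & mx == G & mx != R
  h[i] <- 60 * (2 + (B - R) / d)[i]
  i <- d > 0 & mx == B & mx != R & mx != G
  h[i] <- 60 * (4 + (R - G) / d)[i]
  h %% 360
}

#' Assign Gram reaction and cell shape to a detection
#'
#' The Gram call is made by circular-hue membership: purple band means
#' Gram-positive (crystal violet retained), pink band Gram-negative
#' (safranin counterstain). A hue outside both bands, or equidistant, goes
#' to the nearer band centre. The shape call is bacillus when the
#' aspect ratio reaches `bacillus_ar`, coccus otherwise. Degenerate
#' single-pixel detections are flagged and excluded from aggregation.
#'
#' @param detection one detection from [segment_objects()].
#' @param color_model a [gram_color_model()] (band definitions).
#' @param bacillus_ar aspect-ratio threshold for the bacillus call.
#' @return the detection with `gram_call`, `shape_call` and
#'   `gram_confidence` filled in.
#' @export
gram_and_shape <- function(detection, color_model = gram_color_model(),
                           bacillus_ar = 1.8) {
  d_pur <- abs(circ_diff_deg(detection$hue_mean, color_model$purple_center))
  d_pnk <- abs(circ_diff_deg(detection$hue_mean, color_model$pink_center))
  in_pur <- d_pur <= color_model$purple_halfwidth
  in_pnk <- d_pnk <= color_model$pink_halfwidth
  positive <- if (in_pur && !in_pnk) TRUE
    else if (in_pnk && !in_pur) FALSE
    else d_pur <= d_pnk   # outside both, or in the overlap: nearer centre
  detection$gram_call <- if (positive) "positive" else "negative"
  hw <- if (positive) color_model$purple_halfwidth else color_model$pink_halfwidth
  dd <- if (positive) d_pur else d_pnk
  detection$gram_confidence <- max(0, 1 - dd / (2 * hw))
  detection$shape_call <- if (detection$aspect_ratio >= bacillus_ar)
    "bacillus" else "coccus"
  # an unresolved multi-cell clump is counted in cocci: single bacilli are
  # never large enough to trigger the blob rule
  if (isTRUE(detection$is_blob)) detection$shape_call <- "coccus"
  detection
}

#' Arrangement analysis over detections
#'
#' Groups detections into proximity components (edge when the centroid
#' distance is at most `touch_factor` times the mean equivalent diameter
#' of the pair) and labels each component by the geometry of its combined
#' pixel cloud: a principal-component line fit of all member pixels. A
#' component whose perpendicular spread stays below `line_tol` cell
#' diameters and whose axis ratio reaches `chain_ratio` is a `pair_chain`;
#' a non-linear component of at least four estimated cells is a `cluster`
#' (an unresolved clump of cocci is a single detection whose own pixel
#' cloud carries the same evidence); anything else is a `singleton`.
#'
#' @param detections list of detections with centroids, areas, pixels.
#' @param touch_factor proximity multiple of the mean diameter.
#' @param line_tol maximal perpendicular RMS spread of a chain's pixel
#'   cloud, in units of the single-cell diameter (components of >= 4
#'   cells).
#' @param chain_ratio minimal major/minor axis ratio of a chain's pixel
#'   cloud (components of >= 4 cells).
#' @param pair_line_tol,pair_ratio the analogous, tighter cuts for small
#'   components of 2-3 cells (pairs and short chains), which are less
#'   elongated overall.
#' @return the detections, each with `arrangement` set to one of
#'   `"cluster"`, `"pair_chain"`, `"singleton"`, plus the component id and
#'   component-level geometry (`comp_cells`, `comp_linear`).
#' @export
arrangement <- function(detections, touch_factor = 1.7, line_tol = 0.5,
                        chain_ratio = 3.5, pair_line_tol = 0.35,
                        pair_ratio = 2.2) {
  n <- length(detections)
  if (n == 0) return(detections)
  cx <- vapply(detections, function(d) d$centroid[["x"]], numeric(1))
  cy <- vapply(detections, function(d) d$centroid[["y"]], numeric(1))
  diam <- vapply(detections, function(d) 2 * sqrt(d$area / pi), numeric(1))
  # union-find over proximity edges
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      lim <- touch_factor * (diam[i] + diam[j]) / 2
      if ((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2 <= lim^2) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  for (g in unique(comp)) {
    idx <- which(comp == g)
    cells <- sum(vapply(detections[idx], function(d)
      as.numeric(d$est_cells %||% 1), numeric(1)))
    if (cells < 2) {
      for (i in idx) {
        detections[[i]]$arrangement <- "singleton"
        detections[[i]]$comp_cells <- cells
        detections[[i]]$comp_linear <- FALSE
      }
      next
    }
    pts <- do.call(rbind, lapply(detections[idx], function(d)
      (d$pixels - 1) * (d$pitch %||% 1)))
    area_tot <- sum(vapply(detections[idx], `[[`, numeric(1), "area"))
    dcell <- 2 * sqrt(area_tot / cells / pi)
    ctr <- colMeans(pts)
    cv <- crossprod(sweep(pts, 2, ctr)) / nrow(pts)
    ev <- eigen(cv, symmetric = TRUE)$values
    sd1 <- sqrt(max(ev[1], 0)); sd2 <- sqrt(max(ev[2], 0))
    linear <- if (cells >= 4)
      sd2 <= line_tol * dcell && sd1 / max(sd2, 1e-6) >= chain_ratio
    else
      sd2 <= pair_line_tol * dcell && sd1 / max(sd2, 1e-6) >= pair_ratio
    lab <- if (linear) "pair_chain"
           else if (cells >= 4) "cluster"
           else "singleton"
    for (i in idx) {
      detections[[i]]$arrangement <- lab
      detections[[i]]$comp_cells <- cells
      detections[[i]]$comp_linear <- linear
    }
  }
  for (i in seq_len(n)) detections[[i]]$component <- comp[i]
  detections
}

#' Slide-level Gram stain call with attention map
#'
#' Aggregates evidence across all valid images of a slide into one of the
#' four call categories: `GNB`, `GPC_clusters`, `GPC_pairs_chains`, or
#' `Undefined` when evidence is insufficient or mixed. Votes are cast per
#' proximity component (an arrangement group of touching detections),
#' weighted by the component's estimated cell count, with the Gram
#' reaction read from the cell-weighted pooled hue of its members —
#' pooling makes the color call robust where single fragmented detections
#' are not. A Gram-negative component votes `GNB` when it contains an
#' elongated member or is itself linear; a Gram-positive component votes
#' `GPC_pairs_chains` when linear and `GPC_clusters` when it is a
#' non-linear group of at least four cells. A category wins when it holds
#' more than `majority_frac` of the weighted classifiable votes and at
#' least `min_objects` cells were detected. The attention map assigns the
#' winning components' pixels weights proportional to their Gram-call
#' confidence (all classifiable components when Undefined), normalized to
#' `[0, 1]`.
#'
#' @param detections flat list of detections (with gram/shape/arrangement
#'   set), each carrying an `image_index` field when multiple images feed
#'   one slide.
#' @param min_objects minimal number of detected cells for a definite
#'   call.
#' @param majority_frac weighted vote fraction a category must exceed.
#' @param color_model a [gram_color_model()] for the pooled component hue.
#' @param bacillus_ar aspect-ratio threshold for rod-shaped members.
#' @param image_dims list of `c(rows, cols)` per image (for attention
#'   maps); defaults to the dims recorded in the detections.
#' @return An object of class `slide_call`: `category`, `evidence`
#'   (named weighted vote counts), `n_objects` (total estimated cells),
#'   `n_classifiable`, `attention` (list of per-image weight matrices).
#' @export
slide_call <- function(detections, min_objects = 10, majority_frac = 0.6,
                       color_model = gram_color_model(), bacillus_ar = 1.8,
                       image_dims = NULL) {
  usable <- Filter(function(d) !isTRUE(d$degenerate), detections)
  img_of <- vapply(usable, function(d) d$image_index %||% 1L, integer(1))
  comp_of <- vapply(usable, function(d) d$component %||% 1L, integer(1))
  key <- paste(img_of, comp_of)
  wts <- vapply(usable, function(d) as.numeric(d$est_cells %||% 1), numeric(1))
  n_objects <- sum(wts)

  comp_keys <- unique(key)
  comp_vote <- character(0)
  comp_weight <- numeric(0)
  comp_conf <- numeric(0)
  comp_members <- list()
  for (ck in comp_keys) {
    idx <- which(key == ck)
    cells <- sum(wts[idx])
    hues <- vapply(usable[idx], `[[`, numeric(1), "hue_mean")
    hue <- circ_mean_deg(hues, w = wts[idx])
    d_pur <- abs(circ_diff_deg(hue, color_model$purple_center))
    d_pnk <- abs(circ_diff_deg(hue, color_model$pink_center))
    positive <- d_pur / max(color_model$purple_halfwidth, 1) <=
                d_pnk / max(color_model$pink_halfwidth, 1)
    hw <- if (positive) color_model$purple_halfwidth else color_model$pink_halfwidth
    conf <- max(0, 1 - (if (positive) d_pur else d_pnk) / (2 * hw))
    linear <- isTRUE(usable[[idx[1]]]$comp_linear)
    elong <- max(vapply(usable[idx], `[[`, numeric(1), "aspect_ratio"))
    vote <- NA_character_
    if (!positive && (elong >= bacillus_ar || linear)) vote <- "GNB"
    if (positive && linear && cells >= 2) vote <- "GPC_pairs_chains"
    if (positive && !linear && cells >= 4) vote <- "GPC_clusters"
    comp_vote <- c(comp_vote, vote)
    comp_weight <- c(comp_weight, cells)
    comp_conf <- c(comp_conf, conf)
    comp_members[[length(comp_members) + 1L]] <- idx
  }

  classifiable <- which(!is.na(comp_vote))
  tab0 <- tapply(comp_weight[classifiable],
                 factor(comp_vote[classifiable], levels = slide_classes()), sum)
  tab <- ifelse(is.na(tab0), 0, tab0)
  category <- "Undefined"
  if (length(classifiable) > 0 && n_objects >= min_objects) {
    frac <- as.numeric(tab) / sum(comp_weight[classifiable])
    best <- which.max(frac)
    if (frac[best] > majority_frac) category <- slide_classes()[best]
  }

  n_img <- max(c(img_of, 1L))
  if (is.null(image_dims)) {
    image_dims <- vector("list", n_img)
    for (i in seq_along(usable)) image_dims[[img_of[i]]] <- usable[[i]]$dim
  }
  attention <- lapply(image_dims, function(dm)
    if (is.null(dm)) NULL else matrix(0, dm[1], dm[2]))
  sel <- if (category == "Undefined") classifiable
         else classifiable[comp_vote[classifiable] == category]
  wmax <- 0
  for (ci in sel) {
    w <- comp_conf[ci]
    for (i in comp_members[[ci]]) {
      d <- usable[[i]]
      attention[[img_of[i]]][d$pixels] <- w
    }
    wmax <- max(wmax, w)
  }
  if (wmax > 0)
    attention <- lapply(attention, function(a) if (is.null(a)) NULL else a / wmax)

  structure(list(category = category,
                 evidence = as.list(as.numeric(tab)) |>
                   stats::setNames(slide_classes()),
                 n_objects = n_objects,
                 n_classifiable = length(classifiable),
                 attention = attention),
            class = "slide_call")
}

#' @export
print.slide_call <- function(x, ...) {
  cat(sprintf("slide_call: %s (%g cells, %d classifiable components)\n",
              x$category, x$n_objects, x$n_classifiable))
  ev <- unlist(x$evidence)
  cat("  votes:", paste(sprintf("%s=%g", names(ev), ev), collapse = ", "), "\n")
  invisible(x)
}

#' Refresh detection colors from a per-object focused composition
#'
#' Keeps an existing segmentation (masks, geometry, arrangement) but
#' recomputes each detection's color statistics and Gram call from a new
#' composition of the same stack, typically one whose focus map follows
#' [per_object_focus()]: each organism's hue is then read at its own best
#' slice, where its absorption (and therefore its color) is genuine rather
#' than defocus ringing.
#'
#' @param detections list of detections from [interpret_image()].
#' @param image the recomposed `color_image`.
#' @param color_model a [gram_color_model()].
#' @return the detections with updated `hue_mean`, `saturation`,
#'   `gram_call`, `gram_confidence`.
#' @export
refresh_colors <- function(detections, image,
                           color_model = gram_color_model()) {
  if (!length(detections)) return(detections)
  rgb <- image$rgb
  hue <- rgb_hue(rgb)
  V <- pmax(rgb[, , 1], rgb[, , 2], rgb[, , 3])
  mn <- pmin(rgb[, , 1], rgb[, , 2], rgb[, , 3])
  sat <- ifelse(V > 0, (V - mn) / V, 0)
  lum <- (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
  od <- pmax(quantile(lum, 0.95) - lum, 0)
  lapply(detections, function(d) {
    pix <- d$pixels
    w <- od[pix] * (sat[pix] + 1e-3)
    d$hue_mean <- circ_mean_deg(hue[pix], w = w)
    d$hue_dispersion <- circ_dispersion(hue[pix])
    d$saturation <- sum(sat[pix] * od[pix]) / max(sum(od[pix]), 1e-9)
    d$od_max <- max(od[pix])
    gram_and_shape(d, color_model = color_model)
  })
}

#' Full interpretation of one reconstructed image
#'
#' Convenience wrapper: segment, call Gram reaction and shape per object,
#' analyse arrangement.
#'
#' @param image a `color_image`.
#' @param params segmentation parameters.
#' @param color_model a [gram_color_model()].
#' @param image_index index recorded on each detection.
#' @return list of annotated detections.
#' @export
interpret_image <- function(image, params = segmentation_params(),
                            color_model = gram_color_model(),
                            image_index = 1L) {
  dets <- segment_objects(image, params)
  dets <- lapply(dets, gram_and_shape, color_model = color_model)
  dets <- arrangement(dets)
  lapply(dets, function(d) { d$image_index <- as.integer(image_index); d })
}
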