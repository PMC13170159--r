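#' Pipeline configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]. The defaults are
#' the package's desk-scale study conditions: 320 x 320 tiles at 0.25
#' micrometre pitch (80 x 80 micrometre fields, 0.0064 mm^2), three
#' wavelengths, a 300 +/- 15 micrometre sample-to-sensor distance with a
#' 30-slice 200-400 micrometre coarse scan, sub-micrometre focus
#' refinement, 15 phase-retrieval cycles, and component-vote slide calls.
#'
#' @param optics an [optical_config()].
#' @param tiles_per_slide acquisition tiles simulated per slide.
#' @param density bacterial density (objects/mm^2) of generated slides.
#' @param red_cell_density red-cell background density (objects/mm^2).
#' @param stain_quality_range range from which each slide's stain quality
#'   is drawn.
#' @param noise sensor noise settings for [record_hologram()].
#' @param thresholds [triage_thresholds()] list.
#' @param focus list with `z_min`, `z_max`, `n_slices`, `downsample` for
#'   [coarse_focus()] plus `refine_span`, `refine_step` for
#'   [refine_focus()].
#' @param gs list with `max_iters`, `tol` for [gs_reconstruct()].
#' @param seg segmentation parameters ([segmentation_params()]).
#' @param color_model a [gram_color_model()].
#' @param min_objects,majority_frac slide-call aggregation settings
#'   ([slide_call()]).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(optics = optical_config(grid_shape = c(320, 320),
                                                    grid_pitch = 0.25,
                                                    sensor_pitch = 0.25,
                                                    z_nominal = 300,
                                                    z_jitter = 15),
                            tiles_per_slide = 2L,
                            density = 4000,
                            red_cell_density = 400,
                            stain_quality_range = c(-0.3, 0.3),
                            noise = list(shot_scale = 1, read_sigma = 5),
                            thresholds = triage_thresholds(),
                            focus = list(z_min = 200, z_max = 400,
                                         n_slices = 30L, downsample = 2L,
                                         refine_span = 8, refine_step = 0.5),
                            gs = list(max_iters = 15L, tol = 1e-3),
                            seg = segmentation_params(),
                            color_model = gram_color_model(),
                            min_objects = 10,
                            majority_frac = 0.6) {
  structure(list(optics = optics, tiles_per_slide = as.integer(tiles_per_slide),
                 density = density, red_cell_density = red_cell_density,
                 stain_quality_range = stain_quality_range, noise = noise,
                 thresholds = thresholds, focus = focus, gs = gs, seg = seg,
                 color_model = color_model, min_objects = min_objects,
                 majority_frac = majority_frac),
            class = "pipeline_config")
}

#' Process one slide's holograms into a slide call
#'
#' The per-slide inference path shared by [run_pipeline()] and usable on
#' externally acquired holograms: triage the tiles, then for each valid
#' tile autofocus (coarse scan plus sub-micrometre refinement),
#' reconstruct by multi-wavelength phase retrieval, compose a color image
#' and collect object detections; finally aggregate into a [slide_call()].
#'
#' @param holograms list of `hologram` tiles of one slide.
#' @param config a [pipeline_config()].
#' @return list with `call` (a `slide_call`), `triage`, `tiles`
#'   (per-valid-tile details: z estimates, detections, image), `rejected`.
#' @export
interpret_slide <- function(holograms, config = pipeline_config()) {
  tri <- triage_slide(holograms, config$thresholds)
  dets_all <- list()
  tiles <- list()
  if (!tri$rejected) {
    for (t in tri$valid) {
      h <- holograms[[t]]
      fc <- coarse_focus(h, config$focus$z_min, config$focus$z_max,
                         config$focus$n_slices,
                         downsample = config$focus$downsample)
      zf <- refine_focus(h, fc$z_hat, span = config$focus$refine_span,
                         step = config$focus$refine_step)
      st <- gs_reconstruct(h, zf, max_iters = config$gs$max_iters,
                           tol = config$gs$tol)
      ci <- compose_color(st, provenance = sprintf("tile%02d", t))
      dets <- interpret_image(ci, params = config$seg,
                              color_model = config$color_model,
                              image_index = t)
      tiles[[length(tiles) + 1L]] <- list(tile = t, z_hat = zf,
                                          n_detections = length(dets),
                                          image = ci)
      dets_all <- c(dets_all, dets)
    }
  }
  call <- slide_call(dets_all, min_objects = config$min_objects,
                     majority_frac = config$majority_frac,
                     color_model = config$color_model)
  list(call = call, triage = tri, tiles = tiles, rejected = tri$rejected)
}

#' Run the full synthetic pipeline over a set of slides
#'
#' For each requested slide: generate a phantom per tile (all tiles share
#' the slide's class and stain quality), record multi-wavelength
#' holograms, triage, focus, reconstruct, interpret, and record the slide
#' call. Any stage failure is caught and recorded; the run continues with
#' the remaining slides. The whole run is reproducible from the slide
#' seeds.
#'
#' @param labels character vector of true slide classes.
#' @param seeds integer vector of per-slide seeds (same length).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for `summary.csv` and
#'   `confusion.csv`.
#' @param verbose print one line per slide.
#' @return list of class `pipeline_run`: `records` (data frame with
#'   true_label, call, valid_fraction, rejected, stain_quality, error),
#'   `confusion` (a [confusion_matrix()] over non-rejected slides),
#'   `accuracy` (fraction of non-rejected slides called correctly,
#'   Undefined counting as wrong), `n_rejected`.
#' @export
run_pipeline <- function(labels, seeds, config = pipeline_config(),
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(length(labels) == length(seeds))
  labels <- match.arg(labels, slide_classes(), several.ok = TRUE)
  records <- data.frame(slide = seq_along(labels), seed = seeds,
                        true_label = labels, call = NA_character_,
                        n_objects = NA_real_, valid_fraction = NA_real_,
                        rejected = FALSE, stain_quality = NA_real_,
                        error = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(labels)) {
    res <- tryCatch({
      sq <- with_seed(seeds[i], runif(1, config$stain_quality_range[1],
                                      config$stain_quality_range[2]))
      tile_seeds <- with_seed(seeds[i] + 101L,
                              sample.int(99999999L, config$tiles_per_slide))
      holos <- lapply(tile_seeds, function(s) {
        ph <- generate_phantom(config$optics, labels[i],
                               density = config$density,
                               stain_quality = sq, seed = s,
                               red_cell_density = config$red_cell_density,
                               color_model = config$color_model)
        record_hologram(ph, config$optics, seed = s + 1L,
                        noise = config$noise)
      })
      out <- interpret_slide(holos, config)
      list(call = out$call$category, n_objects = out$call$n_objects,
           valid_fraction = out$triage$valid_fraction,
           rejected = out$rejected, sq = sq)
    }, error = function(e) list(error = conditionMessage(e)))
    if (!is.null(res$error)) {
      records$error[i] <- res$error
    } else {
      records$call[i] <- res$call
      records$n_objects[i] <- res$n_objects
      records$valid_fraction[i] <- res$valid_fraction
      records$rejected[i] <- res$rejected
      records$stain_quality[i] <- res$sq
    }
    if (verbose)
      cat(sprintf("slide %d (%s): %s\n", i, labels[i],
                  records$call[i] %||% records$error[i]))
  }
  scored <- records[!records$rejected & is.na(records$error), ]
  cm <- tabulate_calls(scored$true_label, scored$call)
  acc <- if (nrow(scored)) mean(scored$call == scored$true_label) else NA_real_
  run <- structure(list(records = records, confusion = cm, accuracy = acc,
                        n_rejected = sum(records$rejected)),
                   class = "pipeline_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(records, file.path(out_dir, "summary.csv"), row.names = FALSE)
    write_confusion(cm, file.path(out_dir, "confusion.csv"))
  }
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline_run: %d slides, accuracy %.3f, %d rejected\n",
              nrow(x$records), x$accuracy, x$n_rejected))
  print(x$confusion)
  invisible(x)
}

#' The default synthetic slide benchmark
#'
#' Thirty synthetic slides, ten per class, seeds 1-30, default noise and
#' stain-quality variation, run through the whole pipeline.
#'
#' @param n_per_class slides per class.
#' @param seed_offset added to the 1..3n slide seeds.
#' @param config a [pipeline_config()].
#' @param verbose print per-slide progress.
#' @return a `pipeline_run`.
#' @export
benchmark_slides <- function(n_per_class = 10, seed_offset = 0L,
                             config = pipeline_config(), verbose = FALSE) {
  labels <- rep(slide_classes(), each = n_per_class)
  seeds <- seq_along(labels) + as.integer(seed_offset)
  run_pipeline(labels, seeds, config, verbose = verbose)
}
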