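# Build a color image directly from a phantom's transmittance: the
# interpretation layer's behaviour isolated from reconstruction error.
phantom_image <- function(ph, gamma = 2.2) {
  cfg <- ph$config
  ord <- order(cfg$wavelengths, decreasing = TRUE)
  n <- cfg$grid_shape
  rgb <- array(0, c(n[1], n[2], 3))
  for (ch in 1:3)
    rgb[, , ch] <- pmin(pmax(Mod(ph$transmittance[[ord[ch]]]), 0), 1)^(1 / gamma)
  structure(list(rgb = rgb, focus_map = NULL, pitch = cfg$grid_pitch,
                 provenance = "direct"), class = "color_image")
}

test_that("a blank image yields no detections", {
  cfg <- test_config(grid = 128)
  ph <- phantom_from_objects(cfg, NULL, "GNB")
  expect_length(segment_objects(phantom_image(ph)), 0)
})

test_that("sparse non-touching bacteria are counted within 10%", {
  cfg <- test_config(grid = 256)
  ph <- generate_phantom(cfg, "GNB", density = 2000, seed = 31,
                         red_cell_density = 1e-6)
  k <- sum(ph$objects$kind == "bacillus")
  dets <- segment_objects(phantom_image(ph))
  expect_gte(length(dets), ceiling(0.9 * k))
  expect_lte(length(dets), floor(1.1 * k) + 1)
})

test_that("detection masks are pairwise disjoint", {
  cfg <- test_config(grid = 256)
  ph <- generate_phantom(cfg, "GPC_clusters", density = 4000, seed = 32)
  dets <- segment_objects(phantom_image(ph))
  expect_gt(length(dets), 0)
  seen <- matrix(FALSE, 256, 256)
  for (d in dets) {
    expect_false(any(seen[d$pixels]))
    seen[d$pixels] <- TRUE
  }
})

test_that("Gram and shape calls follow hue bands and aspect ratio", {
  mk <- function(hue, ar) list(hue_mean = hue, aspect_ratio = ar,
                               is_blob = FALSE)
  d <- gram_and_shape(mk(272, 1.0))
  expect_equal(d$gram_call, "positive")
  expect_equal(d$shape_call, "coccus")
  d <- gram_and_shape(mk(342, 4.0))   # safranin rod, 4 um by 1 um
  expect_equal(d$gram_call, "negative")
  expect_equal(d$shape_call, "bacillus")
  # tie region resolves to the nearer band centre
  d <- gram_and_shape(mk(200, 1.0))
  expect_equal(d$gram_call, "positive")
  d <- gram_and_shape(mk(355, 1.0))
  expect_equal(d$gram_call, "negative")
  # a generated GP coccus at nominal stain reads (positive, coccus)
  cfg <- test_config(grid = 128)
  one <- data.frame(kind = "coccus", x = 16, y = 16, size1 = 1.2,
                    size2 = 1.2, orientation = 0, gram = "positive",
                    group_id = 1L, z_offset = 0)
  ph <- phantom_from_objects(cfg, one, "GPC_clusters")
  dets <- interpret_image(phantom_image(ph))
  expect_length(dets, 1)
  expect_equal(dets[[1]]$gram_call, "positive")
  expect_equal(dets[[1]]$shape_call, "coccus")
})

test_that("arrangement separates chains, clumps and singletons", {
  mkdet <- function(x, y, d = 1) {
    r_px <- d / 2 / 0.25
    ij <- expand.grid(i = -3:3, j = -3:3)
    ij <- ij[ij$i^2 + ij$j^2 <= r_px^2, ]
    pix <- cbind(round(y / 0.25) + ij$i, round(x / 0.25) + ij$j)
    list(centroid = c(x = x, y = y), area = pi * (d / 2)^2, est_cells = 1L,
         pixels = pix, pitch = 0.25, dim = c(256L, 256L),
         aspect_ratio = 1, gram_call = "positive", shape_call = "coccus",
         hue_mean = 272, gram_confidence = 1, degenerate = FALSE)
  }
  # 6 collinear touching cocci
  chain <- lapply(0:5, function(i) mkdet(10 + i * 1.05, 10))
  chain <- arrangement(chain)
  expect_true(all(vapply(chain, `[[`, character(1), "arrangement") ==
                  "pair_chain"))
  # 10 cocci in a compact clump
  set.seed(4)
  th <- seq(0, 2 * pi, length.out = 10)
  clump <- lapply(1:10, function(i)
    mkdet(30 + 1.1 * cos(th[i]) * (1 + (i %% 2)), 30 + 1.1 * sin(th[i]) *
            (1 + (i %% 3) / 2)))
  clump <- arrangement(clump)
  expect_true(all(vapply(clump, `[[`, character(1), "arrangement") ==
                  "cluster"))
  # isolated coccus
  single <- arrangement(list(mkdet(55, 55)))
  expect_equal(single[[1]]$arrangement, "singleton")
})

test_that("slide calls follow weighted component majority with fallback", {
  expect_equal(slide_call(list())$category, "Undefined")
  cfg <- test_config(grid = 256)
  # a definite GNB slide from the generator
  ph <- generate_phantom(cfg, "GNB", density = 4000, seed = 33)
  dets <- interpret_image(phantom_image(ph))
  sc <- slide_call(dets)
  expect_equal(sc$category, "GNB")
  expect_gte(sc$n_objects, 10)
  # an even split cannot reach a 0.6 majority
  phc <- generate_phantom(cfg, "GPC_clusters", density = 4000, seed = 34)
  dc <- interpret_image(phantom_image(phc))
  dg <- lapply(interpret_image(phantom_image(ph)), function(d) {
    d$image_index <- 2L
    d
  })
  both <- c(dc, dg)
  sc2 <- slide_call(both, majority_frac = 0.9)
  expect_equal(sc2$category, "Undefined")
})

test_that("slide calls are invariant to detection order", {
  cfg <- test_config(grid = 256)
  ph <- generate_phantom(cfg, "GPC_pairs_chains", density = 4000, seed = 35)
  dets <- interpret_image(phantom_image(ph))
  sc1 <- slide_call(dets)
  set.seed(9)
  sc2 <- slide_call(sample(dets))
  expect_equal(sc2$category, sc1$category)
  expect_equal(sort(unlist(sc2$evidence)), sort(unlist(sc1$evidence)))
})

test_that("attention maps highlight only detected objects", {
  cfg <- test_config(grid = 256)
  ph <- generate_phantom(cfg, "GPC_clusters", density = 4000, seed = 36)
  dets <- interpret_image(phantom_image(ph))
  sc <- slide_call(dets)
  att <- sc$attention[[1]]
  expect_true(all(att >= 0 & att <= 1))
  union_mask <- matrix(FALSE, 256, 256)
  for (d in dets) union_mask[d$pixels] <- TRUE
  expect_true(all(att[!union_mask] == 0))
  expect_gt(sum(att > 0), 0)
})

test_that("severe decolorization errors degrade accuracy", {
  cfg <- test_config(grid = 256)
  acc <- vapply(c(0, 0.8), function(q) {
    hits <- 0; n <- 0
    for (lab in slide_classes()) for (s in 41:44) {
      sq <- if (q == 0) 0 else q * sign((s %% 2) - 0.5)
      ph <- generate_phantom(cfg, lab, density = 4000, seed = s,
                             stain_quality = sq)
      sc <- slide_call(interpret_image(phantom_image(ph)), min_objects = 5)
      hits <- hits + (sc$category == lab); n <- n + 1
    }
    hits / n
  }, numeric(1))
  expect_lte(acc[2], acc[1])
})
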