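test_that("focus score is zero for constants and shift-invariant", {
  expect_equal(focus_score(matrix(3.7, 32, 32)), 0)
  a <- matrix(runif(32 * 32), 32, 32)
  expect_gt(focus_score(a), 0)
  expect_equal(focus_score(a + 5), focus_score(a))
  expect_error(focus_score(matrix(NaN, 8, 8)), "NaN")
})

test_that("focus score argmax sits at true focus for an absorption object", {
  # pure-amplitude phantom (dn = 0): the contrast metric peaks in focus
  cfg <- test_config(grid = 256, pitch = 0.3, z = 300)
  ph <- generate_phantom(cfg, "GNB", density = 2000, seed = 8, dn = 0,
                         red_cell_density = 1e-6)
  h <- record_hologram(ph, seed = 2, noise = noiseless)
  a <- sqrt(h$frames[[2]] / h$illum_level)
  f <- complex_field(a + 0i, cfg$sensor_pitch, cfg$wavelengths[2])
  zs <- seq(280, 320, by = 0.5)   # 10x finer than a coarse-scan step
  sc <- vapply(zs, function(z) focus_score(Mod(propagate(f, -z)$values)),
               numeric(1))
  expect_lt(abs(zs[which.max(sc)] - h$z_true), 5)
})

test_that("coarse focus enforces the span and slice-count contract", {
  cfg <- test_config(grid = 128, jitter = 10)
  ph <- generate_phantom(cfg, "GNB", density = 2000, seed = 1)
  h <- record_hologram(ph, seed = 1)
  expect_error(coarse_focus(h, 250, 350, 30), "span")
  expect_error(coarse_focus(h, 200, 400, 29), "30")
})

test_that("an empty noiseless hologram focuses at the tie-break end", {
  cfg <- test_config(grid = 128, jitter = 0)
  ph <- phantom_from_objects(cfg, NULL, "GNB")
  h <- record_hologram(ph, seed = 1, noise = noiseless)
  fc <- coarse_focus(h, 200, 400, 30)
  expect_true(all(abs(fc$samples$score) < 1e-12))
  expect_equal(fc$z_hat, 200)
  expect_true(fc$at_boundary)
})

test_that("coarse focus recovers the acquisition distance", {
  cfg <- test_config(grid = 256, pitch = 0.3, z = 300, jitter = 100)
  spacing <- 200 / 29
  errs <- vapply(1:8, function(s) {
    ph <- generate_phantom(cfg, slide_classes()[1 + s %% 3],
                           density = 2500, seed = s)
    h <- record_hologram(ph, seed = s, noise = noiseless)
    fc <- coarse_focus(h, 200, 400, 30)
    abs(fc$z_hat - h$z_true)
  }, numeric(1))
  expect_lte(median(errs), spacing)
})

test_that("phase retrieval satisfies its projection and monotonicity contracts", {
  cfg <- test_config(grid = 256, jitter = 0)
  ph <- generate_phantom(cfg, "GNB", density = 1500, seed = 11)
  h <- record_hologram(ph, seed = 5, noise = noiseless)
  st <- gs_reconstruct(h, h$z_true, max_iters = 30, tol = 0)
  # sensor-plane projection replaces amplitude with the measurement exactly
  meas <- sqrt(h$frames[[1]] / h$illum_level)
  v <- propagate(complex_field(st$sample_field[[1]], st$pitch,
                               cfg$wavelengths[1]), h$z_true)
  proj <- meas * exp(1i * Arg(v$values))
  expect_equal(Mod(proj), meas, tolerance = 1e-12)
  # residuals non-increasing (to floating-point slack) on noiseless input
  r <- st$gs_residuals
  expect_true(all(diff(r) <= 1e-6 * r[1]))
  # 30 slices at 1-um steps
  expect_length(st$z_grid, 30)
  expect_equal(diff(st$z_grid), rep(1, 29))
  expect_true(all(vapply(st$amplitude, function(a) all(a >= 0), logical(1))))
})

test_that("noiseless 3-wavelength retrieval reaches 0.95 amplitude fidelity", {
  cfg <- test_config(grid = 256, jitter = 0)
  ph <- generate_phantom(cfg, "GNB", density = 1500, seed = 11)
  h <- record_hologram(ph, seed = 5, noise = noiseless)
  st <- gs_reconstruct(h, h$z_true, max_iters = 50, tol = 0, out_na = NULL)
  k <- which(st$z_grid == h$z_true)
  for (w in 1:3) {
    expect_gte(cor(as.vector(st$amplitude[[w]][, , k]),
                   as.vector(Mod(ph$transmittance[[w]]))), 0.95)
  }
})

test_that("retrieval fidelity degrades with read noise, in expectation", {
  cfg <- test_config(grid = 128, jitter = 0)
  mean_fid <- vapply(c(0, 40, 160), function(sigma) {
    fid <- vapply(1:4, function(s) {
      ph <- generate_phantom(cfg, "GNB", density = 2000, seed = s)
      h <- record_hologram(ph, seed = s,
                           noise = list(shot_scale = 0, read_sigma = sigma))
      st <- gs_reconstruct(h, h$z_true, max_iters = 20, tol = 0,
                           out_na = NULL)
      k <- which(st$z_grid == h$z_true)
      cor(as.vector(st$amplitude[[2]][, , k]),
          as.vector(Mod(ph$transmittance[[2]])))
    }, numeric(1))
    mean(fid)
  }, numeric(1))
  expect_gt(mean_fid[1], mean_fid[2])
  expect_gt(mean_fid[2], mean_fid[3])
})

test_that("single-wavelength mode is allowed and flagged", {
  cfg <- optical_config(wavelengths = 0.52, grid_shape = c(128, 128),
                        grid_pitch = 0.25, sensor_pitch = 0.25,
                        z_nominal = 300, z_jitter = 0)
  ph <- generate_phantom(cfg, "GNB", density = 2000, seed = 1)
  h <- record_hologram(ph, seed = 1, noise = noiseless)
  st <- gs_reconstruct(h, h$z_true, max_iters = 5)
  expect_false(st$multispectral)
})

test_that("per-object focus separates objects at distinct depths", {
  cfg <- test_config(grid = 256, jitter = 0)
  ex <- 256 * 0.25
  obj <- data.frame(kind = "coccus", x = c(ex / 3, 2 * ex / 3),
                    y = c(ex / 3, 2 * ex / 3), size1 = 1.2, size2 = 1.2,
                    orientation = 0, gram = "positive",
                    group_id = c(1L, 2L), z_offset = c(-5, 5))
  ph <- phantom_from_objects(cfg, obj, "GPC_clusters")
  h <- record_hologram(ph, seed = 2, noise = noiseless)
  st <- gs_reconstruct(h, cfg$z_nominal, max_iters = 40, tol = 1e-6)
  masks <- list(holoGram:::object_mask(ph, 1, grow = 0.5),
                holoGram:::object_mask(ph, 2, grow = 0.5))
  pf <- per_object_focus(st, masks)
  expect_equal(abs(diff(pf$object_z)), 10, tolerance = 0.2)
  # a whole-image mask reduces to the per-field slice choice
  whole <- matrix(TRUE, 256, 256)
  pfw <- per_object_focus(st, list(whole), metric = "edge_sparsity")
  expect_equal(pfw$object_z[1], pfw$global_z)
  # empty masks are skipped with a warning
  expect_warning(per_object_focus(st, list(matrix(FALSE, 256, 256))),
                 "empty mask")
})

test_that("single-plane scenes give a flat focus map on the object", {
  cfg <- test_config(grid = 128, jitter = 0)
  one <- data.frame(kind = "coccus", x = 16, y = 16, size1 = 1.2,
                    size2 = 1.2, orientation = 0, gram = "positive",
                    group_id = 1L, z_offset = 0)
  ph <- phantom_from_objects(cfg, one, "GPC_clusters")
  h <- record_hologram(ph, seed = 1, noise = noiseless)
  st <- gs_reconstruct(h, cfg$z_nominal, max_iters = 20)
  m <- holoGram:::object_mask(ph, 1, grow = 0.5)
  pf <- per_object_focus(st, list(m))
  expect_equal(length(unique(pf$focus_map[m])), 1L)
})

test_that("color composition is bright on empty scenes and class-true on GNB", {
  cfg <- test_config(grid = 128, jitter = 0)
  ph0 <- phantom_from_objects(cfg, NULL, "GNB")
  h0 <- record_hologram(ph0, seed = 1, noise = noiseless)
  st0 <- gs_reconstruct(h0, cfg$z_nominal, max_iters = 5)
  ci0 <- compose_color(st0)
  expect_gt(min(ci0$rgb), 0.9)
  cfg2 <- test_config(grid = 256, jitter = 0)
  ph <- generate_phantom(cfg2, "GNB", density = 1500, seed = 42,
                         red_cell_density = 1e-6)
  h <- record_hologram(ph, seed = 3, noise = noiseless)
  st <- gs_reconstruct(h, h$z_true, max_iters = 30, tol = 1e-5)
  ci <- compose_color(st)
  m <- holoGram:::bacteria_mask(ph)
  hues <- holoGram:::rgb_hue(ci$rgb)[m]
  mh <- holoGram:::circ_mean_deg(hues)
  cm <- gram_color_model()
  expect_lte(abs(holoGram:::circ_diff_deg(mh, cm$pink_center)),
             cm$pink_halfwidth)
})

test_that("wavelength order does not affect the composed image", {
  cfg <- test_config(grid = 128, jitter = 0)
  ph <- generate_phantom(cfg, "GNB", density = 2000, seed = 2)
  h <- record_hologram(ph, seed = 2, noise = noiseless)
  st <- gs_reconstruct(h, cfg$z_nominal, max_iters = 10)
  perm <- c(2, 3, 1)
  st2 <- st
  st2$wavelengths <- st$wavelengths[perm]
  st2$amplitude <- st$amplitude[perm]
  st2$phase <- st$phase[perm]
  expect_equal(compose_color(st2)$rgb, compose_color(st)$rgb)
})
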