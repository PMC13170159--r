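test_that("phantom generation is seed-deterministic, bit-exactly", {
  cfg <- test_config(grid = 128)
  a <- generate_phantom(cfg, "GPC_clusters", density = 3000, seed = 11)
  b <- generate_phantom(cfg, "GPC_clusters", density = 3000, seed = 11)
  expect_identical(a$objects, b$objects)
  expect_identical(a$transmittance, b$transmittance)
  c <- generate_phantom(cfg, "GPC_clusters", density = 3000, seed = 12)
  expect_false(identical(a$objects, c$objects))
})

test_that("arrangement structure matches the slide class", {
  cfg <- test_config(grid = 256)
  # pairs/chains: every coccus shares its group with >= 1 other, collinearly
  ph <- generate_phantom(cfg, "GPC_pairs_chains", density = 3000, seed = 7)
  cocci <- ph$objects[ph$objects$kind == "coccus", ]
  expect_gt(nrow(cocci), 0)
  for (g in unique(cocci$group_id)) {
    gr <- cocci[cocci$group_id == g, ]
    expect_gte(nrow(gr), 2)
    if (nrow(gr) >= 3) {
      pts <- cbind(gr$x, gr$y)
      ev <- eigen(cov(pts), symmetric = TRUE)$values
      expect_lte(sqrt(max(ev[2], 0)), 0.2 * mean(gr$size1))
    }
  }
  # clusters: >= 1 group of >= 4 mutually proximal cocci
  ph2 <- generate_phantom(cfg, "GPC_clusters", density = 3000, seed = 7)
  cocci2 <- ph2$objects[ph2$objects$kind == "coccus", ]
  sizes <- table(cocci2$group_id)
  expect_gte(max(sizes), 4)
  big <- cocci2[cocci2$group_id == names(which.max(sizes)), ]
  dmat <- as.matrix(dist(cbind(big$x, big$y)))
  diag(dmat) <- Inf
  expect_lte(max(apply(dmat, 1, min)), 2 * mean(big$size1))
  # GNB: rods with aspect ratio >= 2
  ph3 <- generate_phantom(cfg, "GNB", density = 2000, seed = 7)
  rods <- ph3$objects[ph3$objects$kind == "bacillus", ]
  expect_gt(nrow(rods), 0)
  expect_true(all(rods$size1 / rods$size2 >= 2))
})

test_that("near-zero density leaves a clear field apart from red cells", {
  cfg <- test_config(grid = 128)
  ph <- generate_phantom(cfg, "GNB", density = 1e-6, seed = 1,
                         red_cell_density = 1e-6)
  expect_true(all(abs(Mod(ph$transmittance[[1]]) - 1) < 1e-12))
})

test_that("excessive density raises the too-dense error", {
  cfg <- test_config(grid = 128)
  expect_error(generate_phantom(cfg, "GNB", density = 2e5, seed = 1,
                                max_attempts = 200L),
               "too dense")
})

test_that("rendered amplitudes stay in [0, 1] with one plane per wavelength", {
  cfg <- test_config(grid = 128)
  ph <- generate_phantom(cfg, "GPC_clusters", density = 5000, seed = 3)
  expect_length(ph$transmittance, length(cfg$wavelengths))
  for (tr in ph$transmittance) {
    expect_true(all(Mod(tr) <= 1 + 1e-12))
    expect_true(all(Mod(tr) >= 0))
  }
})

test_that("GNB pixels render in the pink hue band, GP in purple", {
  cfg <- test_config(grid = 256)
  cm <- gram_color_model()
  for (lab in c("GNB", "GPC_clusters")) {
    ph <- generate_phantom(cfg, lab, density = 2000, stain_quality = 0,
                           seed = 42, red_cell_density = 1e-6)
    amps <- lapply(ph$transmittance, Mod)
    mask <- holoGram:::bacteria_mask(ph)
    expect_gt(sum(mask), 0)
    hues <- vapply(which(mask), function(i)
      amps_to_hue(c(amps[[1]][i], amps[[2]][i], amps[[3]][i])), numeric(1))
    if (lab == "GNB") {
      inband <- abs(holoGram:::circ_diff_deg(hues, cm$pink_center)) <=
        cm$pink_halfwidth
    } else {
      inband <- abs(holoGram:::circ_diff_deg(hues, cm$purple_center)) <=
        cm$purple_halfwidth
    }
    expect_gte(mean(inband), 0.9)
  }
})

test_that("spectral separation holds for moderate stain quality", {
  cfg <- test_config(grid = 256)
  for (sq in c(-0.45, 0, 0.45)) {
    gp <- generate_phantom(cfg, "GPC_clusters", density = 2000,
                           stain_quality = sq, seed = 5,
                           red_cell_density = 1e-6)
    m <- holoGram:::bacteria_mask(gp)
    expect_lt(mean(Mod(gp$transmittance[[3]])[m]),   # longest wavelength
              mean(Mod(gp$transmittance[[1]])[m]))   # shortest
    gn <- generate_phantom(cfg, "GNB", density = 2000, stain_quality = sq,
                           seed = 5, red_cell_density = 1e-6)
    m <- holoGram:::bacteria_mask(gn)
    expect_lt(mean(Mod(gn$transmittance[[1]])[m]),
              mean(Mod(gn$transmittance[[3]])[m]))
  }
})

test_that("save/load round trip reproduces the phantom bit-exactly", {
  cfg <- test_config(grid = 128)
  ph <- generate_phantom(cfg, "GPC_pairs_chains", density = 3000, seed = 9,
                         stain_quality = -0.2)
  base <- file.path(tempdir(), "phantom-rt")
  man <- save_phantom(ph, base)
  expect_equal(man$n_objects, nrow(ph$objects))
  ph2 <- load_phantom(base)
  expect_identical(ph2$objects$x, ph$objects$x)
  expect_identical(ph2$transmittance, ph$transmittance)
  expect_identical(ph2$true_label, ph$true_label)
  expect_identical(ph2$stain_quality, ph$stain_quality)
  # the written amplitude stack itself stays within [0, 1]
  pages <- tiff::readTIFF(paste0(base, ".tif"), all = TRUE)
  amp_pages <- pages[seq(1, length(pages), by = 2)]
  for (p in amp_pages) {
    expect_gte(min(p), 0)
    expect_lte(max(p), 1)
  }
  unlink(paste0(base, c(".tif", ".json")))
})

test_that("invalid object tables are rejected", {
  cfg <- test_config(grid = 128)
  bad <- data.frame(kind = "coccus", x = 1, y = 1, size1 = 3, size2 = 3,
                    orientation = 0, gram = "positive", group_id = 1L,
                    z_offset = 0)
  expect_error(phantom_from_objects(cfg, bad, "GPC_clusters"),
               "diameters")
  bad2 <- bad; bad2$size1 <- 1; bad2$z_offset <- 20
  expect_error(phantom_from_objects(cfg, bad2, "GPC_clusters"), "z_offset")
})
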