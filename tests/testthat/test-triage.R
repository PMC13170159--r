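test_that("features behave on degenerate frames", {
  cfg <- test_config(grid = 128)
  wd <- cfg$well_depth
  flat <- matrix(round(wd / 2), 128, 128)
  f <- extract_features(flat, config = cfg)
  expect_lt(f[["occupancy"]], 1e-9)
  expect_lt(f[["fringe_energy"]], 1e-9)
  expect_equal(f[["saturation_frac"]], 0)
  zeros <- matrix(0, 128, 128)
  expect_equal(extract_features(zeros, config = cfg)[["dead_frac"]], 1)
  sat <- matrix(wd, 128, 128)
  expect_equal(extract_features(sat, config = cfg)[["saturation_frac"]], 1)
})

test_that("dense specimens occupy more of a tile than sparse ones", {
  cfg <- test_config(grid = 192, jitter = 10)
  occ <- vapply(c(1500, 20000), function(dens) {
    vals <- vapply(1:3, function(s) {
      ph <- generate_phantom(cfg, "GNB", density = dens, seed = s,
                             red_cell_density = dens * 0.1,
                             max_attempts = 50000L)
      h <- record_hologram(ph, seed = s)
      extract_features(h$frames[[2]], config = cfg)[["occupancy"]]
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_gt(occ[2], occ[1])
})

test_that("the decision list respects its fixed order", {
  base <- c(fringe_energy = 0.5, occupancy = 0.08, saturation_frac = 0,
            dead_frac = 0, texture_entropy = 2)
  lab <- function(f) classify_quality(f)$category
  expect_equal(lab(replace(base, "saturation_frac", 0.5)), "hardware_failure")
  expect_equal(lab(replace(base, "dead_frac", 0.9)), "hardware_failure")
  expect_equal(lab(replace(base, "occupancy", 0.9)), "invalid_too_thick")
  expect_equal(lab(replace(base, "occupancy", 0)), "no_sample")
  expect_equal(lab(replace(base, "fringe_energy", 0.01)), "undefined_debris")
  expect_equal(lab(replace(base, "occupancy", 0.3)), "valid_dense")
  expect_equal(lab(base), "valid_sparse")
  expect_true(classify_quality(base)$is_valid)
  expect_false(classify_quality(replace(base, "occupancy", 0))$is_valid)
})

test_that("every feature vector maps to exactly one of the six categories", {
  set.seed(1)
  for (i in 1:200) {
    f <- c(fringe_energy = runif(1), occupancy = runif(1),
           saturation_frac = runif(1), dead_frac = runif(1),
           texture_entropy = runif(1, 0, 5))
    q <- classify_quality(f)
    expect_length(q$category, 1)
    expect_true(q$category %in% quality_categories())
    expect_identical(q$is_valid,
                     q$category %in% c("valid_sparse", "valid_dense"))
  }
})

test_that("raising occupancy never demotes dense toward sparse or empty", {
  rank <- c(no_sample = 1, valid_sparse = 2, valid_dense = 3)
  set.seed(2)
  for (i in 1:50) {
    f <- c(fringe_energy = runif(1, 0.2, 0.9), occupancy = 0,
           saturation_frac = 0, dead_frac = 0, texture_entropy = 2)
    prev <- -Inf
    for (occ in seq(0, 0.7, by = 0.05)) {
      cat_i <- classify_quality(replace(f, "occupancy", occ))$category
      if (cat_i %in% names(rank)) {
        expect_gte(rank[[cat_i]], prev)
        prev <- rank[[cat_i]]
      }
    }
  }
})

test_that("invalid threshold orderings are configuration errors", {
  expect_error(triage_thresholds(dense_cut = 0.8, thick_cut = 0.7), "below")
  expect_error(triage_thresholds(occ_floor = 0.2, dense_cut = 0.1), "below")
  expect_error(triage_thresholds(sat_cut = 0), "\\(0, 1\\]")
})

test_that("triage over a constructed slide yields the constructed fractions", {
  cfg <- test_config(grid = 128, jitter = 10)
  mk_valid <- function(s) {
    ph <- generate_phantom(cfg, "GNB", density = 4000, seed = s)
    record_hologram(ph, seed = s)
  }
  mk_empty <- function(s) {
    ph <- phantom_from_objects(cfg, NULL, "GNB")
    record_hologram(ph, seed = s)
  }
  holos <- c(lapply(1:5, mk_valid), lapply(6:10, mk_empty))
  tri <- triage_slide(holos)
  expect_equal(tri$valid_fraction, 0.5)
  expect_false(tri$rejected)
  expect_setequal(tri$valid, 1:5)
  # all-invalid slide is rejected
  tri2 <- triage_slide(lapply(11:13, mk_empty))
  expect_true(tri2$rejected)
  expect_equal(length(tri2$valid), 0)
})

test_that("an extinguished smear classifies as too thick", {
  cfg <- test_config(grid = 128)
  lvl <- 0.03 * cfg$well_depth
  set.seed(3)
  frame <- matrix(pmax(round(lvl * runif(128^2, 0.5, 1.5)), 0), 128, 128)
  q <- classify_quality(extract_features(frame, config = cfg))
  expect_equal(q$category, "invalid_too_thick")
})

test_that("the synthetic tile suite is classified at 95% agreement", {
  su <- triage_suite(n = 120, seed = 2026)
  fe <- t(vapply(su$frames, extract_features, numeric(5), config = su$config))
  pred <- vapply(seq_len(nrow(fe)),
                 function(i) classify_quality(fe[i, ])$category, character(1))
  expect_gte(mean(pred == su$labels), 0.95)
})
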