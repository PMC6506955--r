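test_that("a single-pixel plaque's 5 um band holds exactly 80 pixels", {
  lab <- matrix(0L, 21, 21); lab[11, 11] <- 1L
  band <- make_band(fake_labelmap(lab, 1), 1L, band_width_um = 5)
  # lattice points at 0 < d <= 5 around a point: 80
  expect_identical(sum(band$periphery), 80L)
  expect_false(band$periphery[11, 11])
  expect_true(band$interior[11, 11])
})

test_that("band geometry degenerate and exclusion cases", {
  lab <- matrix(0L, 32, 32)
  lab[10:14, 10:14] <- 1L
  lab[10:14, 27:31] <- 2L   # 6 um away at 1 um/px (gap of 12 columns... )
  lm <- fake_labelmap(lab, 1)
  expect_identical(sum(make_band(lm, 1L, 0)$periphery), 0L)
  expect_error(make_band(lm, 99L), "not found")
  # neither band contains the other plaque's pixels
  lab2 <- matrix(0L, 32, 32)
  lab2[15, 10] <- 1L
  lab2[15, 16] <- 2L  # 6 um apart, bands 5 um
  lm2 <- fake_labelmap(lab2, 1)
  b1 <- make_band(lm2, 1L, 5)
  b2 <- make_band(lm2, 2L, 5)
  expect_false(any(b1$periphery & lab2 == 2L))
  expect_false(any(b2$periphery & lab2 == 1L))
  expect_false(any(b1$periphery & b1$interior))
})

test_that("band equals the brute-force distance oracle on random masks", {
  set.seed(101)
  for (rep in 1:6) {
    mask <- matrix(rbinom(64 * 64, 1, 0.01), 64, 64) > 0
    if (!any(mask)) mask[32, 32] <- TRUE
    lab <- matrix(0L, 64, 64); lab[mask] <- 1L
    px <- 0.5
    w <- runif(1, 1, 6)
    band <- make_band(fake_labelmap(lab, px), 1L, w)
    d <- brute_force_distance(mask)
    expected <- d > 0 & d <= w / px
    expect_identical(band$periphery, expected)
  }
})

test_that("band area shrinks monotonically with width", {
  lab <- matrix(0L, 64, 64); lab[disk_mask_px(64, 64, 16, 16, 6, 0.5)] <- 1L
  lm <- fake_labelmap(lab, 0.5)
  widths <- c(0, 1, 2.5, 5, 8)
  areas <- vapply(widths, function(w) sum(make_band(lm, 1L, w)$periphery),
                  integer(1))
  expect_true(all(diff(areas) > 0))
  expect_identical(areas[1], 0L)
})

test_that("uniform GFAP gives enrichment exactly 1, scaling cancels", {
  set.seed(5)
  lab <- matrix(0L, 96, 96); lab[disk_mask_px(96, 96, 20, 20, 8, 0.5)] <- 1L
  lm <- fake_labelmap(lab, 0.5)
  band <- make_band(lm, 1L, 5)
  uni <- matrix(7.3, 96, 96)
  enr <- gfap_enrichment(uni, band, lm)
  expect_identical(enr$interior_enrichment, 1.0)
  expect_identical(enr$periphery_enrichment, 1.0)
  gfap <- matrix(runif(96 * 96, 1, 50), 96, 96)
  e1 <- gfap_enrichment(gfap, band, lm)
  e2 <- gfap_enrichment(gfap * 13.7, band, lm)
  expect_equal(e1$interior_enrichment, e2$interior_enrichment)
  expect_equal(e1$periphery_enrichment, e2$periphery_enrichment)
  expect_error(gfap_enrichment(matrix(0, 96, 96), band, lm), "zero")
})

test_that("planted GFAP band enrichment is recovered on clean renders", {
  spec <- noise_free(scene_spec(
    fov_um = c(200, 200), pixel_size_um = 0.5,
    plaques = list(count = 6L,
                   class_mix = c(dense_core = 1, fibrillar = 0, mixed = 0)),
    gfap = list(band_enrichment_factor = 2.5,
                interior_enrichment_factor = 1.5),
    microglia = list(density_per_mm2 = 0, coverage_range = c(0, 0)),
    neurons = list(density_per_mm2 = 0),
    dystrophies = list(count_range = c(0L, 0L)),
    vessels = list(count = 0L), seed = 42), psf = TRUE)
  sc <- generate_scene(spec)
  res <- analyze_scene(sc$stack, run_config())
  # enrichment factors act on stroke density; the rendered contrast is
  # diluted by the flat base and stroke bleed, so recovery means a clearly
  # elevated periphery over interior over field ordering
  expect_gt(res$summary$mean_periphery_enrichment, 1.2)
  expect_gt(res$summary$mean_periphery_enrichment,
            res$summary$mean_interior_enrichment)
})

test_that("microglial counting: blank images and exact planted densities", {
  cfg <- sharp_config()
  blank <- count_microglia(matrix(0, 64, 64), 0.5, cfg, 0.25)
  expect_identical(blank$microglia_density_per_mm2, 0.0)
  # 12 planted somata in 0.25 mm^2 -> 48 per mm^2, exact when noise-free
  spec <- noise_free(scene_spec(
    fov_um = c(500, 500), pixel_size_um = 1,
    plaques = list(count = 0L),
    gfap = list(filament_density_per_100um2 = 0),
    microglia = list(density_per_mm2 = 48),
    neurons = list(density_per_mm2 = 0),
    vessels = list(count = 0L), seed = 8))
  sc <- generate_scene(spec)
  expect_identical(sc$truth$n_microglia, 12L)
  dens <- count_microglia(sc$stack$channels$iba1, 1, cfg,
                          sc$truth$fov_area_mm2)
  expect_identical(dens$n_microglia, 12L)
  expect_equal(dens$microglia_density_per_mm2, 48)
})

test_that("coverage hits the trivial extremes and is monotone", {
  px <- 0.5
  lab <- matrix(0L, 96, 96)
  dm <- disk_mask_px(96, 96, 24, 24, 8, px)
  lab[dm] <- 1L
  lm <- fake_labelmap(lab, px)
  band <- make_band(lm, 1L, 5)
  # full surrounding ring -> coverage 1
  ring <- disk_mask_px(96, 96, 24, 24, 9.5, px) & !dm
  iba_ring <- matrix(0, 96, 96); iba_ring[ring] <- 100
  cfg <- sharp_config(threshold = list(iba1 = list(method = "fixed_value",
                                                   value = 50)))
  cov_full <- microglial_coverage(iba_ring, band, 2, cfg)
  expect_identical(cov_full$coverage_fraction, 1.0)
  expect_equal(cov_full$covered_perimeter_um, cov_full$perimeter_um)
  # blank channel -> coverage 0
  cov0 <- microglial_coverage(matrix(0, 96, 96), band, 2, cfg)
  expect_identical(cov0$coverage_fraction, 0.0)
  # adding positive pixels never decreases coverage
  set.seed(9)
  iba <- matrix(0, 96, 96)
  prev <- 0
  for (k in 1:5) {
    add <- which(ring & iba == 0)
    iba[sample(add, 40)] <- 100
    cv <- microglial_coverage(iba, band, 2, cfg)$coverage_fraction
    expect_gte(cv, prev)
    prev <- cv
  }
})

test_that("planted angular coverage fractions are recovered", {
  for (f in c(0.25, 0.75)) {
    spec <- noise_free(scene_spec(
      fov_um = c(128, 128), pixel_size_um = 0.5,
      plaques = list(count = 2L, radius_meanlog = log(10), radius_sdlog = 0,
                     class_mix = c(dense_core = 1, fibrillar = 0, mixed = 0)),
      gfap = list(filament_density_per_100um2 = 0),
      microglia = list(density_per_mm2 = 0, coverage_range = c(f, f)),
      neurons = list(density_per_mm2 = 0),
      dystrophies = list(count_range = c(0L, 0L)),
      vessels = list(count = 0L), seed = 31))
    sc <- generate_scene(spec)
    res <- analyze_scene(sc$stack, sharp_config())
    expect_equal(res$plaques$coverage_fraction, rep(f, 2), tolerance = 0.2)
    expect_true(all(abs(res$plaques$coverage_fraction - f) <= 0.05))
  }
})
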