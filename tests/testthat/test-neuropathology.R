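test_that("neuron detection: blank image, analytic areas, watershed split", {
  cfg <- sharp_config()
  blank <- detect_neurons(matrix(0, 64, 64), 0.5, cfg)
  expect_identical(nrow(blank$records), 0L)
  # two well-separated 8 um somata: areas within 10% of pi * 64
  px <- 0.5
  neun <- matrix(0, 128, 128)
  neun <- pmax(neun, disk_image(128, 128, 16, 16, 8, px, level = 160))
  neun <- pmax(neun, disk_image(128, 128, 46, 46, 8, px, level = 160))
  det <- detect_neurons(neun, px, cfg)
  expect_identical(nrow(det$records), 2L)
  expect_equal(det$records$soma_area_um2, rep(pi * 64, 2), tolerance = 0.1)
  expect_true(all(is.infinite(det$records$distance_to_nearest_plaque_um)))
  # overlapping somata (centers 14 um apart, radius 8) split by watershed
  ov <- matrix(0, 128, 128)
  ov <- pmax(ov, disk_image(128, 128, 24, 30, 8, px, level = 160))
  ov <- pmax(ov, disk_image(128, 128, 38, 30, 8, px, level = 160))
  det2 <- detect_neurons(ov, px, cfg)
  expect_identical(nrow(det2$records), 2L)
})

test_that("distance to the nearest plaque is measured from the soma", {
  px <- 0.5
  neun <- disk_image(128, 128, 50, 32, 8, px, level = 160)
  abeta <- disk_image(128, 128, 12, 32, 8, px, level = 300)
  cfg <- sharp_config()
  lm <- segment_plaques(abeta, px, cfg)
  det <- detect_neurons(neun, px, cfg, plaques = lm)
  # centroid at x = 50 um, plaque edge at x = 20 um -> 30 um
  expect_equal(det$records$distance_to_nearest_plaque_um, 30, tolerance = 0.1)
})

test_that("puncta counting is exact, local and soma-restricted", {
  px <- 0.5
  cfg <- sharp_config()
  soma <- disk_mask_px(96, 96, 24, 24, 8, px)
  # uniform soma: top-hat removes flat signal
  flat <- matrix(5, 96, 96); flat[soma] <- 16
  expect_identical(count_neuronal_puncta(flat, soma, px, cfg), 0L)
  # five 1 um-diameter puncta at 5x the soma floor
  abeta <- flat
  pts <- cbind(c(20, 28, 24, 20, 28), c(20, 20, 25, 29, 29))
  for (k in 1:5) {
    abeta <- pmax(abeta, disk_image(96, 96, pts[k, 1], pts[k, 2], 0.5, px,
                                    level = 80))
  }
  expect_identical(count_neuronal_puncta(abeta, soma, px, cfg), 5L)
  # the same puncta fully outside the mask count zero
  far_soma <- disk_mask_px(96, 96, 40, 40, 6, px)
  abeta2 <- matrix(5, 96, 96); abeta2[far_soma] <- 16
  for (k in 1:5) {
    abeta2 <- pmax(abeta2, disk_image(96, 96, pts[k, 1], pts[k, 2], 0.5, px,
                                      level = 80))
  }
  expect_identical(count_neuronal_puncta(abeta2, far_soma, px, cfg), 0L)
  # counts are unchanged by arbitrary modification outside the soma
  abeta3 <- abeta
  abeta3[!soma] <- matrix(runif(96 * 96, 0, 500), 96, 96)[!soma]
  expect_identical(count_neuronal_puncta(abeta3, soma, px, cfg), 5L)
  expect_error(count_neuronal_puncta(abeta, matrix(FALSE, 96, 96), px, cfg),
               "empty")
})

test_that("peri-plaque positivity fraction follows the count threshold", {
  rec <- data.frame(distance_to_nearest_plaque_um = c(10, 20, 30, 40),
                    puncta_count = c(0L, 1L, 3L, 4L))
  r <- fraction_abeta_positive_neurons(rec, 50, 3L)
  expect_identical(r$fraction, 0.5)
  expect_identical(r$n_neurons, 4L)
  # nobody in range -> missing
  far <- fraction_abeta_positive_neurons(
    data.frame(distance_to_nearest_plaque_um = 100, puncta_count = 5L), 50, 3L)
  expect_true(is.na(far$fraction))
  # raising the threshold never raises the fraction
  fr <- vapply(1:6, function(th) {
    fraction_abeta_positive_neurons(rec, 50, th)$fraction
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("positivity flags are pure functions of counts and thresholds", {
  spec <- noise_free(scene_spec(seed = 77))
  sc <- generate_scene(spec)
  res <- analyze_scene(sc$stack, sharp_config())
  neu <- res$neurons
  if (nrow(neu)) {
    expect_identical(neu$abeta_positive, neu$puncta_count >= 3L)
  }
  plq <- res$plaques
  expect_identical(plq$is_dystrophic_plaque, plq$dystrophy_count >= 4L)
})

test_that("dystrophy counting respects the band, size filter and threshold", {
  px <- 0.5
  cfg <- sharp_config(threshold = list(syp = list(method = "fixed_value",
                                                  value = 50)))
  lab <- matrix(0L, 128, 128)
  dm <- disk_mask_px(128, 128, 32, 32, 10, px)
  lab[dm] <- 1L
  band <- make_band(fake_labelmap(lab, px), 1L, 5)
  # blank channel
  d0 <- count_dystrophies(matrix(0, 128, 128), band, px, cfg)
  expect_identical(d0$dystrophy_count, 0L)
  expect_false(d0$is_dystrophic_plaque)
  # blobs of 2.5 um diameter in the band: the dystrophic flag flips at 4
  angles <- seq(0, 2 * pi, length.out = 8)[1:6]
  blob_at <- function(n) {
    syp <- matrix(0, 128, 128)
    for (k in seq_len(n)) {
      syp <- pmax(syp, disk_image(128, 128, 32 + 12.5 * cos(angles[k]),
                                  32 + 12.5 * sin(angles[k]), 1.25, px,
                                  level = 200))
    }
    syp
  }
  d3 <- count_dystrophies(blob_at(3), band, px, cfg)
  expect_identical(d3$dystrophy_count, 3L)
  expect_false(d3$is_dystrophic_plaque)
  d4 <- count_dystrophies(blob_at(4), band, px, cfg)
  expect_identical(d4$dystrophy_count, 4L)
  expect_true(d4$is_dystrophic_plaque)
  # blobs below the minimum area are not "large" and are not counted
  syp <- blob_at(3)
  for (k in 4:6) {
    syp <- pmax(syp, disk_image(128, 128, 32 + 12.5 * cos(angles[k]),
                                32 + 12.5 * sin(angles[k]), 0.6, px,
                                level = 200))
  }
  dmix <- count_dystrophies(syp, band, px, cfg)
  expect_identical(dmix$dystrophy_count, 3L)
  expect_false(dmix$is_dystrophic_plaque)
  # blobs far outside interior + band do not count
  far <- disk_image(128, 128, 60, 10, 1.25, px, level = 200)
  expect_identical(count_dystrophies(far, band, px, cfg)$dystrophy_count, 0L)
})
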