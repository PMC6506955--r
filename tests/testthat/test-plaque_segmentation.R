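test_that("noise-free disks are recovered with analytic areas", {
  px <- 0.5
  img <- matrix(0, 128, 128)
  img <- pmax(img, disk_image(128, 128, 16, 16, 10, px, level = 200))
  img <- pmax(img, disk_image(128, 128, 48, 44, 10, px, level = 200))
  lm <- segment_plaques(img, px, sharp_config())
  expect_identical(max(lm$labels), 2L)
  rec <- measure_plaques(lm, img, pixel_size_um = px)
  expect_equal(rec$area_um2, rep(pi * 100, 2), tolerance = 0.05)
})

test_that("the size filter is strict at the printed 50 um^2 boundary", {
  px <- 0.5
  cfg <- sharp_config(threshold = list(abeta = list(method = "fixed_value",
                                                    value = 50)))
  img49 <- matrix(0, 64, 64); img49[10:23, 10:23] <- 100      # 196 px = 49 um2
  img51 <- matrix(0, 64, 64); img51[10:21, 10:26] <- 100      # 204 px = 51 um2
  expect_identical(max(segment_plaques(img49, px, cfg)$labels), 0L)
  expect_identical(max(segment_plaques(img51, px, cfg)$labels), 1L)
  # exactly 50 um^2 (200 px) is excluded: the criterion is strictly greater
  img50 <- matrix(0, 64, 64); img50[10:19, 10:29] <- 100
  expect_identical(max(segment_plaques(img50, px, cfg)$labels), 0L)
})

test_that("blank and invalid images are handled", {
  cfg <- sharp_config()
  expect_identical(max(segment_plaques(matrix(0, 32, 32), 0.5, cfg)$labels), 0L)
  bad <- matrix(1, 8, 8); bad[2, 2] <- NaN
  expect_error(segment_plaques(bad, 0.5, cfg), "non-finite")
  expect_identical(nrow(measure_plaques(
    segment_plaques(matrix(0, 32, 32), 0.5, cfg), matrix(0, 32, 32),
    pixel_size_um = 0.5)), 0L)
})

test_that("Otsu segmentation is invariant under positive intensity scaling", {
  set.seed(11)
  px <- 0.5
  img <- matrix(0, 128, 128)
  img <- pmax(img, disk_image(128, 128, 20, 20, 8, px, level = 150))
  img <- pmax(img, disk_image(128, 128, 45, 40, 6, px, level = 150))
  img <- img + matrix(runif(128 * 128, 0, 10), 128, 128)
  cfg <- sharp_config()
  base <- segment_plaques(img, px, cfg)
  for (k in c(0.2, 3, 117.3)) {
    scaled <- segment_plaques(img * k, px, cfg)
    expect_identical(scaled$labels, base$labels)
  }
})

test_that("components are 8-connected and labelled in scan order", {
  m <- matrix(0, 10, 10)
  m[2, 2] <- 1; m[3, 3] <- 1         # diagonal contact: one object
  m[8, 8] <- 1
  lab <- label_components(m > 0)
  expect_identical(max(lab), 2L)
  expect_identical(lab[2, 2], lab[3, 3])
  expect_lt(lab[2, 2], lab[8, 8])    # first-seen component gets label 1
})

test_that("measured area and perimeter follow the calibration", {
  px <- 0.5
  # 400-pixel component: area = 400 * 0.25 = 100 um^2
  img <- matrix(0, 64, 64); img[11:30, 21:40] <- 80
  cfg <- sharp_config(threshold = list(abeta = list(method = "fixed_value",
                                                    value = 10)))
  lm <- segment_plaques(img, px, cfg)
  rec <- measure_plaques(lm, img, pixel_size_um = px)
  expect_identical(rec$area_um2, 100.0)
  # 20x20 um square: perimeter within 10% of 80 um
  img2 <- matrix(0, 80, 80); img2[21:60, 21:60] <- 80
  rec2 <- measure_plaques(segment_plaques(img2, px, cfg), img2,
                          pixel_size_um = px)
  expect_equal(rec2$perimeter_um, 80, tolerance = 0.1)
  expect_error(measure_plaques(lm, matrix(0, 8, 8), pixel_size_um = px),
               "co-registered")
})

test_that("every reported component is strictly above the area floor", {
  set.seed(4)
  px <- 0.7
  img <- matrix(rbinom(96 * 96, 1, 0.12) * 100, 96, 96)
  cfg <- sharp_config(min_plaque_area_um2 = 20,
                      threshold = list(abeta = list(method = "fixed_value",
                                                    value = 50)))
  lm <- segment_plaques(img, px, cfg)
  if (max(lm$labels) > 0L) {
    areas <- tabulate(lm$labels[lm$labels > 0]) * px^2
    expect_true(all(areas > 20))
  }
  # exhaustive: the removed pixels are exactly the small components
  all_lab <- label_components(img > 50)
  all_areas <- tabulate(all_lab[all_lab > 0]) * px^2
  expect_identical(max(lm$labels), sum(all_areas > 20))
})

test_that("planted-disk scenes give exact counts and densities", {
  sc <- generate_scene(disk_scene_spec(30, fov = c(256, 256), seed = 9))
  res <- analyze_scene(sc$stack, sharp_config())
  expect_identical(res$summary$n_plaques, 30L)
  expect_equal(res$summary$plaque_density_per_mm2,
               30 / sc$truth$fov_area_mm2)
})

test_that("cortex summary arithmetic and empty case", {
  rec <- data.frame(area_um2 = c(100, 200, 300, 400))
  s <- cortex_plaque_summary(rec, 1.0)
  expect_identical(s$plaque_density_per_mm2, 4.0)
  expect_identical(s$amyloid_load, 1e-3)
  expect_identical(s$mean_plaque_size_um2, 250.0)
  empty <- cortex_plaque_summary(rec[0, , drop = FALSE], 2.0)
  expect_identical(empty$plaque_density_per_mm2, 0.0)
  expect_identical(empty$amyloid_load, 0.0)
  expect_true(is.na(empty$mean_plaque_size_um2))
  expect_error(cortex_plaque_summary(rec, 0), "positive")
  expect_error(cortex_plaque_summary(data.frame(area_um2 = -1), 1),
               "negative")
})

test_that("border-touching plaques are flagged and excludable", {
  px <- 0.5
  img <- matrix(0, 64, 64)
  img[1:20, 1:20] <- 100            # touches the border
  img[40:60, 40:60] <- 100
  cfg <- sharp_config(threshold = list(abeta = list(method = "fixed_value",
                                                    value = 10)))
  lm <- segment_plaques(img, px, cfg)
  rec <- measure_plaques(lm, img, pixel_size_um = px)
  expect_identical(sum(rec$on_border), 1L)
  st <- channel_stack(list(abeta = img), px)
  res <- analyze_scene(st, sharp_config(
    threshold = list(abeta = list(method = "fixed_value", value = 10)),
    exclude_border_plaques = TRUE))
  expect_identical(res$summary$n_plaques, 1L)
})
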