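# a minimal scene_analysis for aggregation tests, built by hand
fake_analysis <- function(animal_id, condition, areas_um2, area_mm2 = 1,
                          image_id = "img") {
  plq <- empty_plq()
  if (length(areas_um2)) {
    plq <- data.frame(
      image_id = image_id, label = seq_along(areas_um2),
      area_um2 = areas_um2, centroid_x = 0, centroid_y = 0,
      perimeter_um = 1, mean_abeta = 1, mean_thios = NA_real_,
      plaque_class = "unclassified", on_border = FALSE,
      interior_enrichment = NA_real_, periphery_enrichment = NA_real_,
      coverage_fraction = NA_real_, dystrophy_count = NA_integer_,
      is_dystrophic_plaque = NA, periplaque_aqp4_ratio = NA_real_,
      stringsAsFactors = FALSE)
  }
  summary <- data.frame(
    image_id = image_id, animal_id = animal_id, condition = condition,
    analyzed_area_mm2 = area_mm2, n_plaques = length(areas_um2),
    microglia_density_per_mm2 = NA_real_,
    perivascular_aqp4_ratio = NA_real_, stringsAsFactors = FALSE)
  structure(list(plaques = plq, summary = summary,
                 neurons = data.frame(distance_to_nearest_plaque_um = numeric(0),
                                      puncta_count = integer(0))),
            class = "scene_analysis")
}

empty_plq <- function() {
  data.frame(image_id = character(0), label = integer(0),
             area_um2 = numeric(0), centroid_x = numeric(0),
             centroid_y = numeric(0), perimeter_um = numeric(0),
             mean_abeta = numeric(0), mean_thios = numeric(0),
             plaque_class = character(0), on_border = logical(0),
             interior_enrichment = numeric(0),
             periphery_enrichment = numeric(0),
             coverage_fraction = numeric(0), dystrophy_count = integer(0),
             is_dystrophic_plaque = logical(0),
             periplaque_aqp4_ratio = numeric(0), stringsAsFactors = FALSE)
}

test_that("per-animal summaries pool plaques and area-weight densities", {
  one <- summarize_mouse(list(fake_analysis("m1", "WT", c(100, 200))))
  expect_identical(one$mean_plaque_size_um2, 150.0)
  # 3 + 7 plaques in two equal-area images: density 10 / total area
  two <- summarize_mouse(list(
    fake_analysis("m1", "WT", rep(50, 3), area_mm2 = 0.5, image_id = "i1"),
    fake_analysis("m1", "WT", rep(50, 7), area_mm2 = 0.5, image_id = "i2")))
  expect_identical(two$plaque_density_per_mm2, 10.0)
  expect_identical(two$n_plaques_analyzed, 10L)
  expect_true(two$low_plaque_count == FALSE)
  # zero plaques: missing plaque-dependent fields, not an error
  zero <- summarize_mouse(list(fake_analysis("m2", "KO", numeric(0))))
  expect_true(is.na(zero$mean_plaque_size_um2))
  expect_identical(zero$amyloid_load, 0.0)
  expect_true(zero$low_plaque_count)
})

test_that("unpaired t-tests match a hand-coded Student oracle", {
  g1 <- c(2.1, 2.5, 1.9, 2.3); g2 <- c(1.1, 1.4, 1.0)
  summ <- data.frame(condition = rep(c("A", "B"), c(4, 3)),
                     metric = c(g1, g2))
  res <- compare_groups(summ, "metric", conditions = c("A", "B"))
  # independent textbook computation of the Student statistic
  n1 <- 4; n2 <- 3
  sp2 <- ((n1 - 1) * var(g1) + (n2 - 1) * var(g2)) / (n1 + n2 - 2)
  t_oracle <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_oracle <- 2 * pt(-abs(t_oracle), n1 + n2 - 2)
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-10)
  expect_identical(res$df, n1 + n2 - 2)
  expect_equal(res$sem1, sd(g1) / 2, tolerance = 1e-12)
  # symmetric under group swap: t flips sign, p unchanged
  swap <- compare_groups(summ, "metric", conditions = c("B", "A"))
  expect_equal(swap$t, -res$t)
  expect_equal(swap$p_value, res$p_value)
})

test_that("degenerate and identical groups are reported sanely", {
  ident <- data.frame(condition = rep(c("A", "B"), each = 3),
                      m = rep(c(1, 2, 3), 2))
  r <- compare_groups(ident, "m", conditions = c("A", "B"))
  expect_equal(r$p_value, 1)
  expect_equal(r$t, 0)
  sep <- data.frame(condition = rep(c("A", "B"), each = 4),
                    m = rep(c(0, 10), each = 4))
  r2 <- compare_groups(sep, "m", conditions = c("A", "B"))
  expect_identical(r2$p_value, 0)
  expect_true(r2$degenerate)
  expect_error(compare_groups(
    data.frame(condition = c("A", "A", "B"), m = 1:3), "m",
    conditions = c("A", "B")), "insufficient")
})

test_that("class-fraction ANOVA: null case and Bonferroni arithmetic", {
  summ <- data.frame(
    animal_id = paste0("m", 1:8),
    condition = rep(c("WT", "KO"), each = 4),
    frac_dense_core = rep(c(0.5, 0.4, 0.6, 0.5), 2),
    frac_fibrillar = rep(c(0.3, 0.4, 0.2, 0.3), 2),
    frac_mixed = rep(c(0.2, 0.2, 0.2, 0.2), 2))
  res <- compare_class_fractions(summ)
  expect_true(all(res$contrasts$p_adjusted >= res$contrasts$p_unadjusted))
  expect_true(all(res$contrasts$p_adjusted == 1))
  # Bonferroni over k = 3 classes multiplies exactly, capped at 1
  expect_equal(stats::p.adjust(0.02, "bonferroni", n = 3), 0.06)
  expect_equal(res$contrasts$p_adjusted,
               pmin(1, 3 * res$contrasts$p_unadjusted))
})

test_that("planted class-mix shifts are detected by the ANOVA post-test", {
  # per-animal fractions drawn from multinomial counts, 30 plaques each:
  # dense 0.5 -> 0.3, fibrillar 0.3 -> 0.5 between conditions
  set.seed(42)
  hits <- 0L
  for (rep in 1:8) {
    draw <- function(n, p) {
      t(stats::rmultinom(n, 30, p)) / 30
    }
    wt <- draw(8, c(0.5, 0.3, 0.2)); ko <- draw(5, c(0.3, 0.5, 0.2))
    summ <- data.frame(
      animal_id = paste0("m", 1:13),
      condition = rep(c("WT", "KO"), c(8, 5)),
      frac_dense_core = c(wt[, 1], ko[, 1]),
      frac_fibrillar = c(wt[, 2], ko[, 2]),
      frac_mixed = c(wt[, 3], ko[, 3]))
    res <- compare_class_fractions(summ)
    ct <- res$contrasts
    dense_sig <- ct$p_adjusted[ct$class == "dense_core"] < 0.05 &
      ct$diff[ct$class == "dense_core"] > 0
    fib_sig <- ct$p_adjusted[ct$class == "fibrillar"] < 0.05 &
      ct$diff[ct$class == "fibrillar"] < 0
    if (dense_sig && fib_sig) hits <- hits + 1L
  }
  expect_gt(hits, 4L)  # majority of replicates flag both shifted classes
})

test_that("ECDFs are valid step functions and detect stochastic dominance", {
  e1 <- cumulative_distribution(5)
  expect_identical(e1$value, 5)
  expect_identical(e1$ecdf, 1.0)
  e4 <- cumulative_distribution(c(3, 1, 4, 2))
  expect_identical(e4$ecdf, c(0.25, 0.5, 0.75, 1.0))
  expect_identical(e4$value, c(1, 2, 3, 4))
  expect_true(all(diff(e4$ecdf) > 0))
  expect_error(cumulative_distribution(numeric(0)), "at least one")
  # a doubled sample dominates at all shared quantiles
  set.seed(8)
  base <- rlnorm(300, log(100), 0.4)
  q <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(quantile(2 * base, q) > quantile(base, q)))
})
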