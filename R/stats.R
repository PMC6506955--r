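# Per-animal aggregation and group statistics.

#' Aggregate one animal's images into a per-animal summary
#'
#' Plaque-level metrics are averaged over all plaques pooled across the
#' animal's images; image-level densities and loads are area-weighted
#' (totals over total analyzed area); missing metrics propagate as NA.
#' Animals with fewer than \code{min_plaques_per_mouse} plaques are flagged
#' (\code{low_plaque_count}), not dropped.
#'
#' @param analyses List of \code{\link{analyze_scene}} results, all from one
#'   animal.
#' @param config A \code{\link{run_config}}.
#' @return One-row data.frame (the per-animal summary used for group
#'   comparisons).
#' @export
summarize_mouse <- function(analyses, config = run_config()) {
  if (!length(analyses)) stop("at least one analyzed image is required")
  summ <- do.call(rbind, lapply(analyses, function(a) a$summary))
  plq <- do.call(rbind, lapply(analyses, function(a) a$plaques))
  neu <- do.call(rbind, lapply(analyses, function(a) a$neurons))
  animal_id <- summ$animal_id[1]
  condition <- summ$condition[1]
  total_area <- sum(summ$analyzed_area_mm2)
  n_plq <- nrow(plq)
  frac_pos <- fraction_abeta_positive_neurons(
    neu, config$neuron_search_radius_um, config$puncta_positive_threshold)
  cf <- class_fractions(plq)
  data.frame(
    animal_id = animal_id, condition = condition,
    n_images = nrow(summ), analyzed_area_mm2 = total_area,
    n_plaques_analyzed = n_plq,
    mean_plaque_size_um2 = mean_or_na(plq$area_um2),
    plaque_density_per_mm2 = n_plq / total_area,
    amyloid_load = sum(plq$area_um2) / (total_area * 1e6),
    frac_dense_core = cf$frac_dense_core,
    frac_fibrillar = cf$frac_fibrillar,
    frac_mixed = cf$frac_mixed,
    mean_interior_enrichment = mean_or_na(plq$interior_enrichment),
    mean_periphery_enrichment = mean_or_na(plq$periphery_enrichment),
    microglia_density_per_mm2 =
      sum(summ$microglia_density_per_mm2 * summ$analyzed_area_mm2) /
        total_area,
    mean_coverage_fraction = mean_or_na(plq$coverage_fraction),
    fraction_abeta_positive_neurons = frac_pos$fraction,
    fraction_dystrophic_plaques = mean_or_na(plq$is_dystrophic_plaque),
    mean_periplaque_aqp4_ratio = mean_or_na(plq$periplaque_aqp4_ratio),
    mean_perivascular_aqp4_ratio = mean_or_na(summ$perivascular_aqp4_ratio),
    low_plaque_count = n_plq < config$min_plaques_per_mouse,
    stringsAsFactors = FALSE)
}

#' Summarize every animal in an analyzed cohort
#'
#' @param analyses List of \code{\link{analyze_scene}} results (any number
#'   of animals and images).
#' @param config A \code{\link{run_config}}.
#' @return Data.frame with one row per animal.
#' @export
summarize_cohort <- function(analyses, config = run_config()) {
  ids <- vapply(analyses, function(a) a$summary$animal_id, character(1))
  out <- lapply(split(analyses, ids), summarize_mouse, config = config)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$condition, res$animal_id), ]
}

#' Two-group comparison of a per-animal metric
#'
#' Two-sided unpaired t-test between the two conditions, Student
#' (equal-variance) by default, Welch optionally. Reports group means with
#' SEM, the t statistic, p value, and the conventional significance stars
#' (* p < 0.05, ** p < 0.01, *** p < 0.001). When both groups have zero
#' variance the test is degenerate: p is reported as 0 (means differ) or 1
#' (means equal) with \code{degenerate = TRUE}.
#'
#' @param summaries Per-animal summary data.frame with \code{condition}.
#' @param metric Column name to compare.
#' @param test \code{"student"} or \code{"welch"}.
#' @param conditions Optional length-2 character vector selecting/ordering
#'   the groups; the t statistic is group1 minus group2.
#' @return One-row data.frame of class \code{comparison_result}.
#' @export
compare_groups <- function(summaries, metric, test = c("student", "welch"),
                           conditions = NULL) {
  test <- match.arg(test)
  if (!metric %in% names(summaries)) stop("unknown metric: ", metric)
  if (is.null(conditions)) conditions <- unique(summaries$condition)
  if (length(conditions) != 2L) {
    stop("compare_groups needs exactly two conditions")
  }
  g1 <- summaries[summaries$condition == conditions[1], metric]
  g2 <- summaries[summaries$condition == conditions[2], metric]
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("insufficient data: each group needs >= 2 non-missing animals")
  }
  degenerate <- stats::var(g1) == 0 && stats::var(g2) == 0
  if (degenerate) {
    tt <- list(statistic = if (mean(g1) == mean(g2)) 0 else
      sign(mean(g1) - mean(g2)) * Inf,
      p.value = if (mean(g1) == mean(g2)) 1 else 0,
      parameter = length(g1) + length(g2) - 2)
  } else {
    tt <- stats::t.test(g1, g2, var.equal = (test == "student"))
  }
  p <- unname(tt$p.value)
  data.frame(
    metric = metric,
    group1 = conditions[1], group2 = conditions[2],
    n1 = length(g1), n2 = length(g2),
    mean1 = mean(g1), mean2 = mean(g2),
    sem1 = stats::sd(g1) / sqrt(length(g1)),
    sem2 = stats::sd(g2) / sqrt(length(g2)),
    test = test,
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = p,
    stars = p_stars(p),
    degenerate = degenerate,
    stringsAsFactors = FALSE)
}

p_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

#' Two-way ANOVA on plaque class fractions with Bonferroni post-tests
#'
#' Per-animal class fractions are analyzed as condition x class (animals as
#' replicates) with type II sums of squares, the standard choice for the
#' unbalanced group sizes typical of animal cohorts. Per-class condition
#' contrasts use the pooled residual error of the ANOVA and are
#' Bonferroni-adjusted over the number of classes tested. A class absent in
#' every animal is excluded with a warning.
#'
#' @param summaries Per-animal summaries (with \code{frac_dense_core},
#'   \code{frac_fibrillar}, \code{frac_mixed} and \code{condition}).
#' @return List with \code{anova} (type II table as data.frame) and
#'   \code{contrasts} (per-class data.frame: difference, t, df, unadjusted
#'   and Bonferroni-adjusted p, stars).
#' @export
compare_class_fractions <- function(summaries) {
  classes <- c(dense_core = "frac_dense_core", fibrillar = "frac_fibrillar",
               mixed = "frac_mixed")
  present <- vapply(classes, function(cl) {
    any(!is.na(summaries[[cl]]) & summaries[[cl]] > 0)
  }, logical(1))
  if (any(!present)) {
    warning("class(es) absent in all animals, excluded: ",
            paste(names(classes)[!present], collapse = ", "))
    classes <- classes[present]
  }
  if (!length(classes)) stop("no plaque classes present")
  long <- do.call(rbind, lapply(names(classes), function(cl) {
    data.frame(animal_id = summaries$animal_id,
               condition = summaries$condition,
               class = cl, fraction = summaries[[classes[cl]]],
               stringsAsFactors = FALSE)
  }))
  long <- long[!is.na(long$fraction), ]
  long$condition <- factor(long$condition, levels = unique(long$condition))
  long$class <- factor(long$class, levels = names(classes))
  fit <- stats::lm(fraction ~ condition * class, data = long)
  an <- as.data.frame(car::Anova(fit, type = 2))
  an <- cbind(term = rownames(an), an)
  rownames(an) <- NULL
  mse <- stats::sigma(fit)^2
  dfres <- stats::df.residual(fit)
  conds <- levels(long$condition)
  k <- length(classes)
  contrasts <- do.call(rbind, lapply(names(classes), function(cl) {
    a <- long$fraction[long$class == cl & long$condition == conds[1]]
    b <- long$fraction[long$class == cl & long$condition == conds[2]]
    diff <- mean(a) - mean(b)
    se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
    tval <- if (se > 0) diff / se else if (diff == 0) 0 else sign(diff) * Inf
    p <- 2 * stats::pt(-abs(tval), dfres)
    data.frame(class = cl, diff = diff, t = tval, df = dfres,
               p_unadjusted = p,
               p_adjusted = stats::p.adjust(p, "bonferroni", n = k),
               stringsAsFactors = FALSE)
  }))
  contrasts$stars <- vapply(contrasts$p_adjusted, p_stars, character(1))
  list(anova = an, contrasts = contrasts)
}

#' Empirical cumulative distribution of a pooled per-plaque metric
#'
#' Sorted values with ECDF step heights i/n, as exported for cumulative
#' frequency plots of pooled plaque metrics.
#'
#' @param values Numeric vector (NAs removed; must leave at least one).
#' @return Data.frame with \code{value} (sorted) and \code{ecdf}.
#' @export
cumulative_distribution <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("cumulative_distribution needs at least one value")
  data.frame(value = sort(values), ecdf = seq_len(n) / n)
}
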