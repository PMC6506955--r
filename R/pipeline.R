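# Whole-image measurement pipeline: every per-plaque and per-neuron metric
# from one channel stack.

#' Run all measurements on one channel stack
#'
#' Segments plaques from the Abeta channel and computes every metric the
#' available channels support: plaque morphometry and class (thioS),
#' peri-plaque GFAP enrichment, microglial density and perimeter coverage
#' (Iba1), presynaptic dystrophies (synaptophysin), neuronal Abeta-puncta
#' positivity (NeuN + Abeta), and AQP4 peri-plaque / perivascular ratios
#' (AQP4, the latter only with a vessel mask). Missing channels simply
#' leave their metrics NA.
#'
#' @param stack A \code{\link{channel_stack}}.
#' @param config A \code{\link{run_config}}.
#' @param vessel_mask Optional logical matrix of vessel lumen pixels for
#'   perivascular AQP4 scoring.
#' @return List of class \code{scene_analysis}: \code{plaques} (per-plaque
#'   data.frame), \code{neurons} (per-neuron data.frame), \code{summary}
#'   (one-row per-image data.frame), \code{labelmap}.
#' @export
analyze_scene <- function(stack, config = run_config(), vessel_mask = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  validate_config(config)
  ch <- stack$channels
  if (is.null(ch$abeta)) stop("analyze_scene requires an 'abeta' channel")
  px <- stack$pixel_size_um
  area_mm2 <- prod(dim(ch$abeta)) * px^2 / 1e6

  lm <- segment_plaques(ch$abeta, px, config, image_id = stack$image_id)
  plq <- measure_plaques(lm, ch$abeta, ch$thios, px)
  if (config$exclude_border_plaques && nrow(plq)) {
    keep <- !plq$on_border
    lm$labels <- filter_labels(lm$labels, plq$label[keep])
    lm$border_labels <- integer(0)
    plq <- measure_plaques(lm, ch$abeta, ch$thios, px)
  }
  if (!is.null(ch$thios) && nrow(plq)) {
    plq <- classify_plaques(plq, lm, ch$abeta, ch$thios,
                            config$classification)
  }

  n_pl <- nrow(plq)
  plq$interior_enrichment <- rep(NA_real_, n_pl)
  plq$periphery_enrichment <- rep(NA_real_, n_pl)
  plq$coverage_fraction <- rep(NA_real_, n_pl)
  plq$dystrophy_count <- rep(NA_integer_, n_pl)
  plq$is_dystrophic_plaque <- rep(NA, n_pl)
  plq$periplaque_aqp4_ratio <- rep(NA_real_, n_pl)

  # shared per-image precomputations
  fieldm <- NULL
  iba1_dist <- NULL
  syp_mask <- NULL
  if (n_pl > 0L) {
    if (!is.null(ch$gfap) || !is.null(ch$aqp4)) {
      fieldm <- field_mask(lm, config$band_width_um)
    }
    if (!is.null(ch$iba1)) {
      im <- threshold_image(ch$iba1, threshold_spec_for(config, "iba1"))
      iba1_dist <- distance_to_mask(im)
    }
    if (!is.null(ch$syp)) {
      syp_mask <- threshold_image(ch$syp, threshold_spec_for(config, "syp"))
    }
  }
  aqp4_corr <- if (!is.null(ch$aqp4)) {
    background_correct(ch$aqp4, config$background_percentile)
  } else NULL
  aqp4_parenchyma <- NULL
  if (!is.null(aqp4_corr)) {
    aqp4_parenchyma <- if (is.null(fieldm)) {
      matrix(TRUE, nrow(ch$aqp4), ncol(ch$aqp4))
    } else fieldm
    if (!is.null(vessel_mask)) {
      pv_excl <- distance_to_mask(vessel_mask) <=
        config$band_width_um / px
      aqp4_parenchyma <- aqp4_parenchyma & !pv_excl
    }
  }

  for (i in seq_len(n_pl)) {
    band <- make_band(lm, plq$label[i], config$band_width_um, px)
    if (!is.null(ch$gfap)) {
      enr <- gfap_enrichment(ch$gfap, band, lm, field = fieldm)
      plq$interior_enrichment[i] <- enr$interior_enrichment
      plq$periphery_enrichment[i] <- enr$periphery_enrichment
    }
    if (!is.null(ch$iba1)) {
      cov <- microglial_coverage(ch$iba1, band,
                                 config$coverage_distance_um, config,
                                 iba1_distance = iba1_dist)
      plq$coverage_fraction[i] <- cov$coverage_fraction
    }
    if (!is.null(syp_mask)) {
      dys <- count_dystrophies(ch$syp, band, px, config, syp_mask = syp_mask)
      plq$dystrophy_count[i] <- dys$dystrophy_count
      plq$is_dystrophic_plaque[i] <- dys$is_dystrophic_plaque
    }
    if (!is.null(aqp4_corr) && any(band$periphery) &&
        any(aqp4_parenchyma)) {
      pmean <- mean(aqp4_corr[aqp4_parenchyma])
      if (pmean > 0) {
        plq$periplaque_aqp4_ratio[i] <- mean(aqp4_corr[band$periphery]) / pmean
      }
    }
  }

  # microglial density
  mg <- if (!is.null(ch$iba1)) {
    count_microglia(ch$iba1, px, config, area_mm2)
  } else data.frame(n_microglia = NA_integer_,
                    microglia_density_per_mm2 = NA_real_)

  # neurons
  neurons <- empty_neuron_records()
  frac_pos <- list(fraction = NA_real_, n_neurons = 0L, n_positive = 0L)
  if (!is.null(ch$neun)) {
    det <- detect_neurons(ch$neun, px, config, plaques = lm,
                          image_id = stack$image_id)
    if (nrow(det$records) && !is.null(ch$abeta)) {
      neurons <- score_neuron_puncta(det, ch$abeta, px, config)
      frac_pos <- fraction_abeta_positive_neurons(
        neurons, config$neuron_search_radius_um,
        config$puncta_positive_threshold)
    } else {
      neurons <- det$records
    }
  }

  # perivascular AQP4
  pv_ratio <- NA_real_
  if (!is.null(aqp4_corr) && !is.null(vessel_mask) && any(vessel_mask)) {
    roi <- perivascular_roi(vessel_mask, config$coverage_distance_um, px)
    paren <- aqp4_parenchyma & !roi & !vessel_mask
    if (any(roi) && any(paren)) {
      pmean <- mean(aqp4_corr[paren])
      if (pmean > 0) pv_ratio <- mean(aqp4_corr[roi]) / pmean
    }
  }

  morpho <- cortex_plaque_summary(plq, area_mm2)
  cf <- class_fractions(plq)
  summary <- data.frame(
    image_id = stack$image_id, animal_id = stack$animal_id,
    condition = stack$condition, analyzed_area_mm2 = area_mm2,
    morpho, cf,
    mean_interior_enrichment = mean_or_na(plq$interior_enrichment),
    mean_periphery_enrichment = mean_or_na(plq$periphery_enrichment),
    microglia_density_per_mm2 = mg$microglia_density_per_mm2,
    mean_coverage_fraction = mean_or_na(plq$coverage_fraction),
    fraction_abeta_positive_neurons = frac_pos$fraction,
    n_periplaque_neurons = frac_pos$n_neurons,
    fraction_dystrophic_plaques = mean_or_na(plq$is_dystrophic_plaque),
    mean_periplaque_aqp4_ratio = mean_or_na(plq$periplaque_aqp4_ratio),
    perivascular_aqp4_ratio = pv_ratio,
    stringsAsFactors = FALSE)

  structure(list(plaques = plq, neurons = neurons, summary = summary,
                 labelmap = lm),
            class = "scene_analysis")
}

mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x)) mean(x) else NA_real_
}
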