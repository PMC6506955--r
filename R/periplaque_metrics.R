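# Peri-plaque astrocyte (GFAP) enrichment and microglial (Iba1) metrics.

#' GFAP enrichment within and around one plaque
#'
#' Enrichment is the mean GFAP intensity of a region divided by the mean
#' GFAP intensity of the surrounding field of view. The field excludes every
#' plaque interior and every peri-plaque band (not just the target's), so
#' the denominator is a clean non-plaque tissue reference.
#'
#' @param gfap GFAP intensity channel.
#' @param band A \code{\link{make_band}} result for the target plaque.
#' @param all_plaques The full \code{\link{segment_plaques}} result, used to
#'   exclude all plaques (and their bands) from the field.
#' @param field Optional precomputed field mask (from
#'   \code{\link{field_mask}}); pass when scoring many plaques on one image.
#' @return One-row data.frame: \code{plaque_label},
#'   \code{interior_enrichment}, \code{periphery_enrichment} (NA when the
#'   band is empty) and \code{field_mean_gfap}.
#' @export
gfap_enrichment <- function(gfap, band, all_plaques, field = NULL) {
  check_image(gfap)
  stopifnot(inherits(band, "band_roi"))
  lab <- all_plaques$labels
  check_same_shape(gfap, lab)
  if (is.null(field)) field <- field_mask(all_plaques, band$band_width_um)
  if (!any(field)) stop("field region is empty")
  fmean <- mean(gfap[field])
  if (fmean == 0) stop("field mean GFAP is zero; enrichment undefined")
  interior_enr <- mean(gfap[band$interior]) / fmean
  periph_enr <- if (any(band$periphery)) {
    mean(gfap[band$periphery]) / fmean
  } else NA_real_
  data.frame(plaque_label = band$plaque_label,
             interior_enrichment = interior_enr,
             periphery_enrichment = periph_enr,
             field_mean_gfap = fmean)
}

#' Non-plaque field mask
#'
#' Pixels farther than \code{band_width_um} from every plaque: the
#' "surrounding field of view" used as the enrichment denominator.
#'
#' @param labelmap A \code{\link{segment_plaques}} result.
#' @param band_width_um Band width (um) to exclude around each plaque.
#' @return Logical matrix.
#' @export
field_mask <- function(labelmap, band_width_um) {
  lab <- labelmap$labels
  if (max(lab) == 0L) return(matrix(TRUE, nrow(lab), ncol(lab)))
  d <- distance_to_mask(lab > 0L)
  d > band_width_um / labelmap$pixel_size_um
}

#' Microglial cell density
#'
#' Iba1-positive somata are found by intensity thresholding, 8-connected
#' labelling and a soma-area window (excluding debris below and merged
#' clusters above the window), then expressed per square millimetre.
#'
#' @param iba1 Iba1 intensity channel.
#' @param pixel_size_um Micrometres per pixel.
#' @param config A \code{\link{run_config}} (threshold for channel
#'   \code{"iba1"}; \code{microglia_soma_area_um2} window).
#' @param analyzed_area_mm2 Analyzed area in mm^2.
#' @return One-row data.frame: \code{n_microglia},
#'   \code{microglia_density_per_mm2}.
#' @export
count_microglia <- function(iba1, pixel_size_um, config = run_config(),
                            analyzed_area_mm2) {
  check_image(iba1)
  if (analyzed_area_mm2 <= 0) stop("analyzed_area_mm2 must be positive")
  mask <- threshold_image(iba1, threshold_spec_for(config, "iba1"))
  lab <- label_components(mask)
  n <- 0L
  if (max(lab) > 0L) {
    areas <- label_areas_px(lab) * pixel_size_um^2
    w <- config$microglia_soma_area_um2
    n <- sum(areas >= w[1] & areas <= w[2])
  }
  data.frame(n_microglia = n,
             microglia_density_per_mm2 = n / analyzed_area_mm2)
}

#' Microglial coverage of one plaque's perimeter
#'
#' Automated surrogate for the manual perimeter-tracing measurement of
#' plaque containment: the plaque boundary pixels are extracted, and a
#' boundary pixel counts as covered when a thresholded Iba1-positive pixel
#' lies within \code{coverage_distance_um} of it. The coverage fraction is
#' covered boundary pixels over total boundary pixels.
#'
#' @param iba1 Iba1 intensity channel.
#' @param band A \code{\link{make_band}} result for the plaque.
#' @param coverage_distance_um Association distance (um), default from
#'   config.
#' @param config A \code{\link{run_config}}.
#' @param iba1_distance Optional precomputed
#'   \code{\link{distance_to_mask}} of the thresholded Iba1 mask (pixels);
#'   pass when scoring many plaques on one image.
#' @return One-row data.frame: \code{plaque_label}, \code{perimeter_um},
#'   \code{covered_perimeter_um}, \code{coverage_fraction}.
#' @export
microglial_coverage <- function(iba1, band,
                                coverage_distance_um = config$coverage_distance_um,
                                config = run_config(),
                                iba1_distance = NULL) {
  stopifnot(inherits(band, "band_roi"))
  bnd <- boundary_mask(band$interior)
  n_bnd <- sum(bnd)
  if (n_bnd == 0L) stop("plaque boundary is empty")
  if (is.null(iba1_distance)) {
    check_image(iba1)
    check_same_shape(iba1, band$interior)
    mask <- threshold_image(iba1, threshold_spec_for(config, "iba1"))
    iba1_distance <- distance_to_mask(mask)
  }
  cov_px <- coverage_distance_um / band$pixel_size_um
  covered <- sum(iba1_distance[bnd] <= cov_px)
  px <- band$pixel_size_um
  data.frame(plaque_label = band$plaque_label,
             perimeter_um = n_bnd * px,
             covered_perimeter_um = covered * px,
             coverage_fraction = covered / n_bnd)
}
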