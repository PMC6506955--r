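# Neuronal Abeta uptake and peri-plaque presynaptic dystrophies.

#' Detect NeuN-positive neuronal somata
#'
#' Threshold, hole filling, distance-transform watershed to split touching
#' somata, and a soma-area window. The distance from each soma centroid to
#' the nearest plaque interior pixel is recorded (Inf when the image has no
#' plaques).
#'
#' @param neun NeuN intensity channel.
#' @param pixel_size_um Micrometres per pixel.
#' @param config A \code{\link{run_config}} (threshold for channel
#'   \code{"neun"}; \code{neuron_soma_area_um2} window).
#' @param plaques Optional \code{\link{segment_plaques}} result for the
#'   distance-to-plaque field.
#' @param image_id Identifier recorded in the records.
#' @return List with \code{labels} (integer soma label map) and
#'   \code{records}, a data.frame with one row per neuron
#'   (\code{neuron_label}, centroid, \code{soma_area_um2},
#'   \code{distance_to_nearest_plaque_um}; \code{puncta_count} and
#'   \code{abeta_positive} unfilled).
#' @export
detect_neurons <- function(neun, pixel_size_um, config = run_config(),
                           plaques = NULL, image_id = "image") {
  check_image(neun)
  mask <- threshold_image(neun, threshold_spec_for(config, "neun"))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  m <- EBImage::fillHull(m)
  lab <- EBImage::watershed(EBImage::distmap(m))
  lab <- relabel_raster_order(matrix(as.integer(lab), nrow(m), ncol(m)))
  if (max(lab) > 0L) {
    areas <- label_areas_px(lab) * pixel_size_um^2
    w <- config$neuron_soma_area_um2
    lab <- filter_labels(lab, which(areas >= w[1] & areas <= w[2]))
  }
  n <- max(lab)
  if (n == 0L) {
    return(list(labels = lab, records = empty_neuron_records()))
  }
  nz <- which(lab > 0L)
  labs <- lab[nz]
  rows <- ((nz - 1L) %% nrow(lab)) + 1L
  cols <- ((nz - 1L) %/% nrow(lab)) + 1L
  cx <- as.numeric(tapply(cols, labs, mean))
  cy <- as.numeric(tapply(rows, labs, mean))
  areas <- label_areas_px(lab) * pixel_size_um^2
  dist_um <- rep(Inf, n)
  if (!is.null(plaques) && max(plaques$labels) > 0L) {
    d <- distance_to_mask(plaques$labels > 0L)
    ij <- cbind(pmin(pmax(round(cy), 1L), nrow(lab)),
                pmin(pmax(round(cx), 1L), ncol(lab)))
    dist_um <- d[ij] * pixel_size_um
  }
  records <- data.frame(
    image_id = image_id,
    neuron_label = seq_len(n),
    centroid_x = cx, centroid_y = cy,
    soma_area_um2 = areas,
    distance_to_nearest_plaque_um = dist_um,
    puncta_count = NA_integer_,
    abeta_positive = NA,
    stringsAsFactors = FALSE
  )
  list(labels = lab, records = records)
}

empty_neuron_records <- function() {
  data.frame(image_id = character(0), neuron_label = integer(0),
             centroid_x = numeric(0), centroid_y = numeric(0),
             soma_area_um2 = numeric(0),
             distance_to_nearest_plaque_um = numeric(0),
             puncta_count = integer(0), abeta_positive = logical(0),
             stringsAsFactors = FALSE)
}

#' Count intracellular Abeta puncta within one soma
#'
#' Within the soma mask only: white top-hat filtering (structuring radius
#' about the largest punctum), thresholding at a configured contrast above
#' the within-soma median, 8-connected labelling and a punctum-area window.
#' Pixels outside the soma never contribute, so the count is unchanged by
#' any modification of the image beyond the mask.
#'
#' @param abeta Abeta intensity channel.
#' @param neuron_mask Logical matrix, one soma.
#' @param pixel_size_um Micrometres per pixel.
#' @param config A \code{\link{run_config}}.
#' @return Integer punctum count.
#' @export
count_neuronal_puncta <- function(abeta, neuron_mask, pixel_size_um,
                                  config = run_config()) {
  check_image(abeta)
  check_same_shape(abeta, neuron_mask)
  if (!any(neuron_mask)) stop("neuron_mask is empty")
  idx <- which(neuron_mask, arr.ind = TRUE)
  pad <- um_to_px(config$punctum_radius_um, pixel_size_um) + 2L
  r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nrow(abeta), max(idx[, 1]) + pad)
  c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(ncol(abeta), max(idx[, 2]) + pad)
  crop <- abeta[r0:r1, c0:c1, drop = FALSE]
  mcrop <- neuron_mask[r0:r1, c0:c1, drop = FALSE]
  soma_median <- stats::median(crop[mcrop])
  # flatten everything outside the soma so external structure cannot leak in
  crop[!mcrop] <- soma_median
  br <- disc_brush(config$punctum_radius_um, pixel_size_um)
  th <- EBImage::whiteTopHat(EBImage::Image(crop), br)
  th <- matrix(as.numeric(th), nrow(crop), ncol(crop))
  # the opening baseline sits below the noise floor, so the top-hat of pure
  # noise has a positive pedestal; subtract its within-soma median before
  # applying the contrast criterion
  pedestal <- stats::median(th[mcrop])
  cut <- (config$puncta_contrast_factor - 1) * soma_median
  pm <- (th - pedestal) > cut & mcrop
  lab <- label_components(pm)
  if (max(lab) == 0L) return(0L)
  areas <- label_areas_px(lab) * pixel_size_um^2
  w <- config$punctum_area_um2
  sum(areas >= w[1] & areas <= w[2])
}

#' Score puncta for every detected neuron
#'
#' Fills \code{puncta_count} and \code{abeta_positive} (count at or above
#' \code{puncta_positive_threshold}) for each record.
#'
#' @param neurons A \code{\link{detect_neurons}} result.
#' @param abeta Abeta intensity channel.
#' @param pixel_size_um Micrometres per pixel.
#' @param config A \code{\link{run_config}}.
#' @return The records data.frame with puncta fields filled.
#' @export
score_neuron_puncta <- function(neurons, abeta, pixel_size_um,
                                config = run_config()) {
  rec <- neurons$records
  for (i in seq_len(nrow(rec))) {
    rec$puncta_count[i] <- count_neuronal_puncta(
      abeta, neurons$labels == rec$neuron_label[i], pixel_size_um, config)
  }
  rec$abeta_positive <- rec$puncta_count >= config$puncta_positive_threshold
  rec
}

#' Fraction of peri-plaque neurons positive for intracellular Abeta
#'
#' Restricts to neurons within \code{neuron_search_radius_um} of the nearest
#' plaque and reports the fraction whose punctum count reaches
#' \code{puncta_positive_threshold}.
#'
#' @param records Neuron records with puncta counts filled.
#' @param neuron_search_radius_um Peri-plaque radius (um).
#' @param puncta_positive_threshold Minimum punctum count for positivity.
#' @return List with \code{fraction} (NA when no neuron is in range),
#'   \code{n_neurons}, \code{n_positive}.
#' @export
fraction_abeta_positive_neurons <- function(records,
                                            neuron_search_radius_um = 50,
                                            puncta_positive_threshold = 3L) {
  near <- records[records$distance_to_nearest_plaque_um <=
                    neuron_search_radius_um, , drop = FALSE]
  n <- nrow(near)
  if (n == 0L) {
    return(list(fraction = NA_real_, n_neurons = 0L, n_positive = 0L))
  }
  pos <- sum(near$puncta_count >= puncta_positive_threshold)
  list(fraction = pos / n, n_neurons = n, n_positive = pos)
}

#' Count large presynaptic dystrophies around one plaque
#'
#' The search region is the plaque interior plus its peri-plaque band. The
#' synaptophysin channel is thresholded, labelled with 8-connectivity within
#' the region, and components of at least \code{min_dystrophy_area_um2}
#' ("large" dystrophies) are counted. The plaque is dystrophic when the
#' count reaches \code{dystrophy_positive_threshold}.
#'
#' @param syp Synaptophysin intensity channel.
#' @param band A \code{\link{make_band}} result for the plaque.
#' @param pixel_size_um Micrometres per pixel.
#' @param config A \code{\link{run_config}}.
#' @param syp_mask Optional precomputed thresholded synaptophysin mask.
#' @return One-row data.frame: \code{plaque_label}, \code{dystrophy_count},
#'   \code{is_dystrophic_plaque}.
#' @export
count_dystrophies <- function(syp, band, pixel_size_um,
                              config = run_config(), syp_mask = NULL) {
  stopifnot(inherits(band, "band_roi"))
  if (is.null(syp_mask)) {
    check_image(syp)
    check_same_shape(syp, band$interior)
    syp_mask <- threshold_image(syp, threshold_spec_for(config, "syp"))
  }
  region <- band$interior | band$periphery
  lab <- label_components(syp_mask & region)
  count <- 0L
  if (max(lab) > 0L) {
    areas <- label_areas_px(lab) * pixel_size_um^2
    count <- sum(areas >= config$min_dystrophy_area_um2)
  }
  data.frame(plaque_label = band$plaque_label,
             dystrophy_count = count,
             is_dystrophic_plaque = count >= config$dystrophy_positive_threshold)
}
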