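# Plaque segmentation and morphometry.

#' Segment amyloid plaques from an Abeta channel
#'
#' The Abeta image is Gaussian-smoothed (\code{blur_radius_um}; 0 disables
#' smoothing, as in plain size/number morphometry of low-magnification
#' images), intensity-thresholded (Otsu by default), labelled with
#' 8-connectivity, and components not strictly larger than
#' \code{min_plaque_area_um2} are removed. The area filter is applied in
#' square micrometres after calibration, so the same criterion holds at any
#' magnification. Components touching the image border are kept but flagged.
#'
#' @param abeta Numeric matrix, Abeta intensity channel.
#' @param pixel_size_um Micrometres per pixel.
#' @param config A \code{\link{run_config}}.
#' @param image_id Identifier recorded in the result.
#' @return An object of class \code{plaque_labelmap}: list with
#'   \code{labels} (integer matrix), \code{border_labels} (labels touching
#'   the border), \code{pixel_size_um}, \code{image_id} and
#'   \code{params_used}.
#' @export
segment_plaques <- function(abeta, pixel_size_um, config = run_config(),
                            image_id = "image") {
  check_image(abeta)
  validate_config(config)
  spec <- threshold_spec_for(config, "abeta")
  sm <- gaussian_blur_um(abeta, config$blur_radius_um, pixel_size_um)
  mask <- threshold_image(sm, spec)
  lab <- label_components(mask)
  if (max(lab) > 0L) {
    areas_um2 <- label_areas_px(lab) * pixel_size_um^2
    lab <- filter_labels(lab, which(areas_um2 > config$min_plaque_area_um2))
  }
  border <- integer(0)
  if (max(lab) > 0L) {
    H <- nrow(lab); W <- ncol(lab)
    border <- sort(unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W])))
    border <- border[border > 0L]
  }
  structure(
    list(labels = lab, border_labels = border,
         pixel_size_um = pixel_size_um, image_id = image_id,
         params_used = list(
           blur_radius_um = config$blur_radius_um,
           threshold = spec,
           threshold_value = attr(mask, "threshold"),
           min_plaque_area_um2 = config$min_plaque_area_um2,
           connectivity = 8L)),
    class = "plaque_labelmap"
  )
}

#' Measure per-plaque morphometry and intensity
#'
#' One record per label: area (pixel count times the pixel area), centroid
#' (pixel coordinates, x = column, y = row), perimeter (boundary-pixel
#' contour length times pixel size), and mean channel intensities over the
#' component. \code{plaque_class} is initialized to \code{"unclassified"};
#' see \code{\link{classify_plaque}}.
#'
#' @param labelmap A \code{\link{segment_plaques}} result.
#' @param abeta Abeta channel (same shape as the label map).
#' @param thios Optional thioflavin S channel.
#' @param pixel_size_um Micrometres per pixel; defaults to the label map's.
#' @return A data.frame of plaque records.
#' @export
measure_plaques <- function(labelmap, abeta, thios = NULL,
                            pixel_size_um = labelmap$pixel_size_um) {
  stopifnot(inherits(labelmap, "plaque_labelmap"))
  lab <- labelmap$labels
  check_same_shape(lab, abeta)
  if (!is.null(thios)) check_same_shape(lab, thios)
  n <- max(lab)
  if (n == 0L) return(empty_plaque_records())
  areas_px <- label_areas_px(lab)
  nz <- which(lab > 0L)
  labs <- lab[nz]
  rows <- ((nz - 1L) %% nrow(lab)) + 1L
  cols <- ((nz - 1L) %/% nrow(lab)) + 1L
  cx <- as.numeric(tapply(cols, labs, mean))
  cy <- as.numeric(tapply(rows, labs, mean))
  mean_abeta <- as.numeric(tapply(abeta[nz], labs, mean))
  mean_thios <- if (is.null(thios)) rep(NA_real_, n) else
    as.numeric(tapply(thios[nz], labs, mean))
  shp <- EBImage::computeFeatures.shape(lab)
  perim_um <- shp[, "s.perimeter"] * pixel_size_um
  data.frame(
    image_id = labelmap$image_id,
    label = seq_len(n),
    area_um2 = areas_px * pixel_size_um^2,
    centroid_x = cx,
    centroid_y = cy,
    perimeter_um = as.numeric(perim_um),
    mean_abeta = mean_abeta,
    mean_thios = mean_thios,
    plaque_class = "unclassified",
    on_border = seq_len(n) %in% labelmap$border_labels,
    stringsAsFactors = FALSE
  )
}

empty_plaque_records <- function() {
  data.frame(image_id = character(0), label = integer(0),
             area_um2 = numeric(0), centroid_x = numeric(0),
             centroid_y = numeric(0), perimeter_um = numeric(0),
             mean_abeta = numeric(0), mean_thios = numeric(0),
             plaque_class = character(0), on_border = logical(0),
             stringsAsFactors = FALSE)
}

#' Per-image plaque morphometry summary
#'
#' Cortical amyloid morphometry: mean plaque size, plaque density per square
#' millimetre, and amyloid load (fraction of the analyzed area occupied by
#' plaques).
#'
#' @param records Plaque records from \code{\link{measure_plaques}}.
#' @param analyzed_area_mm2 Area of the analyzed region in mm^2.
#' @return One-row data.frame with \code{n_plaques},
#'   \code{mean_plaque_size_um2} (NA when there are no plaques),
#'   \code{plaque_density_per_mm2} and \code{amyloid_load}.
#' @export
cortex_plaque_summary <- function(records, analyzed_area_mm2) {
  if (!is.numeric(analyzed_area_mm2) || analyzed_area_mm2 <= 0) {
    stop("analyzed_area_mm2 must be positive")
  }
  if (nrow(records) && any(records$area_um2 < 0)) {
    stop("negative plaque area")
  }
  n <- nrow(records)
  total_um2 <- if (n) sum(records$area_um2) else 0
  data.frame(
    n_plaques = n,
    mean_plaque_size_um2 = if (n) total_um2 / n else NA_real_,
    plaque_density_per_mm2 = n / analyzed_area_mm2,
    amyloid_load = total_um2 / (analyzed_area_mm2 * 1e6)
  )
}
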