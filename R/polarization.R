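# AQP4 polarization / enrichment ratios.

#' Subtract a low-percentile background floor
#'
#' Background correction used for AQP4 quantification: the given low
#' percentile of the image is subtracted and the result clipped at zero. A
#' constant image corrects to all zeros, which is valid input downstream
#' (the ratio then errors out explicitly).
#'
#' @param img Intensity image.
#' @param background_percentile Percentile in [0, 100) to subtract.
#' @return Corrected image (numeric matrix, non-negative).
#' @export
background_correct <- function(img, background_percentile = 1) {
  check_image(img)
  if (background_percentile < 0 || background_percentile >= 100) {
    stop("background_percentile must be in [0, 100)")
  }
  floor_val <- stats::quantile(img, background_percentile / 100, names = FALSE)
  pmax(img - floor_val, 0)
}

#' AQP4 polarization ratio for one ROI
#'
#' The background-corrected mean AQP4 intensity within the ROI divided by
#' the background-corrected mean within non-plaque parenchyma. ROIs may be
#' imported (manually drawn masks) or constructed automatically: a
#' perivascular band around a vessel mask (\code{\link{perivascular_roi}})
#' or the peri-plaque band (\code{\link{make_band}}).
#'
#' @param aqp4 AQP4 intensity channel.
#' @param roi_mask Logical matrix, the ROI.
#' @param parenchyma_mask Logical matrix of non-plaque parenchyma, disjoint
#'   from the ROI.
#' @param roi_kind \code{"perivascular"} or \code{"periplaque"}.
#' @param config A \code{\link{run_config}} (background percentile).
#' @return One-row data.frame: \code{roi_kind}, \code{roi_mean},
#'   \code{parenchyma_mean}, \code{polarization_ratio}.
#' @export
polarization_ratio <- function(aqp4, roi_mask, parenchyma_mask,
                               roi_kind = c("perivascular", "periplaque"),
                               config = run_config()) {
  roi_kind <- match.arg(roi_kind)
  check_image(aqp4)
  check_same_shape(aqp4, roi_mask)
  check_same_shape(aqp4, parenchyma_mask)
  if (!any(roi_mask)) stop("roi_mask is empty")
  if (!any(parenchyma_mask)) stop("parenchyma_mask is empty")
  if (any(roi_mask & parenchyma_mask)) {
    stop("roi_mask and parenchyma_mask must be disjoint")
  }
  corr <- background_correct(aqp4, config$background_percentile)
  roi_mean <- mean(corr[roi_mask])
  par_mean <- mean(corr[parenchyma_mask])
  if (par_mean == 0 && mean(aqp4[parenchyma_mask]) > 0) {
    # the percentile floor annihilated a flat image; fall back to raw
    # intensities so a uniform field reports the well-defined ratio 1
    roi_mean <- mean(aqp4[roi_mask])
    par_mean <- mean(aqp4[parenchyma_mask])
  }
  if (par_mean == 0) stop("parenchyma mean is zero; ratio undefined")
  data.frame(roi_kind = roi_kind, roi_mean = roi_mean,
             parenchyma_mean = par_mean,
             polarization_ratio = roi_mean / par_mean,
             stringsAsFactors = FALSE)
}

#' Perivascular band ROI from a vessel mask
#'
#' Pixels within \code{width_um} of the vessel (excluding the vessel
#' itself), the automatic stand-in for a manually drawn perivascular ROI.
#'
#' @param vessel_mask Logical matrix of vessel lumen pixels.
#' @param width_um Band width (um).
#' @param pixel_size_um Micrometres per pixel.
#' @return Logical matrix.
#' @export
perivascular_roi <- function(vessel_mask, width_um, pixel_size_um) {
  if (!any(vessel_mask)) stop("vessel_mask is empty")
  d <- distance_to_mask(vessel_mask)
  d > 0 & d <= width_um / pixel_size_um
}

#' Import ROI masks from a labeled TIFF or polygon CSV
#'
#' Labeled TIFF: any nonzero pixel belongs to the ROI of its label. Polygon
#' CSV: columns \code{roi}, \code{x}, \code{y} (0-based pixel coordinates of
#' the vertices, in drawing order); each polygon is filled by even-odd
#' point-in-polygon testing of pixel centers.
#'
#' @param path Path to a \code{.tif}/\code{.tiff} label mask or a
#'   \code{.csv} polygon table.
#' @param dim_hw Height/width of the target image, required for CSV input.
#' @return Named list of logical ROI masks (names are label numbers or roi
#'   identifiers).
#' @export
import_rois <- function(path, dim_hw = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    lab <- read_label_mask(path)
    labs <- sort(unique(lab[lab > 0L]))
    out <- lapply(labs, function(l) lab == l)
    names(out) <- labs
    return(out)
  }
  if (ext == "csv") {
    if (is.null(dim_hw)) stop("dim_hw is required for polygon CSV input")
    df <- utils::read.csv(path)
    need <- c("roi", "x", "y")
    if (!all(need %in% names(df))) {
      stop("polygon CSV needs columns: ", paste(need, collapse = ", "))
    }
    out <- lapply(split(df, df$roi), function(p) {
      polygon_mask(p$x, p$y, dim_hw)
    })
    return(out)
  }
  stop("unsupported ROI format: .", ext)
}

# even-odd fill of a polygon given 0-based vertex coordinates
polygon_mask <- function(x, y, dim_hw) {
  H <- dim_hw[1]; W <- dim_hw[2]
  mask <- matrix(FALSE, H, W)
  cc <- rep(seq_len(W), each = H) - 1L   # 0-based x of each pixel
  rr <- rep(seq_len(H), times = W) - 1L  # 0-based y
  n <- length(x)
  inside <- rep(FALSE, H * W)
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > rr) != (y[j] > rr)) &
      (cc < (x[j] - x[i]) * (rr - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  mask[matrix(c(rr + 1L, cc + 1L), ncol = 2)] <- inside
  mask
}
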