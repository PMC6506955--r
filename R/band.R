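# Peri-plaque band construction by exact Euclidean distance transform.

#' Build the peri-plaque band around one plaque
#'
#' The periphery is the set of pixels whose exact Euclidean distance to the
#' target plaque component lies in \code{(0, band_width_um]}, clipped at the
#' image border, and excluding pixels belonging to any other plaque
#' component. This reproduces the fixed-width annulus ("make band") used to
#' delimit the peri-plaque region around a segmented plaque.
#'
#' @param labelmap A \code{\link{segment_plaques}} result (or a list with an
#'   integer \code{labels} matrix and \code{pixel_size_um}).
#' @param target_label Label of the plaque to band.
#' @param band_width_um Band width in micrometres (0 gives an empty band).
#' @param pixel_size_um Micrometres per pixel; defaults to the label map's.
#' @return An object of class \code{band_roi}: list with logical matrices
#'   \code{interior} and \code{periphery} (disjoint), \code{plaque_label},
#'   \code{band_width_um} and \code{n_excluded_other_plaque} (periphery
#'   pixels removed because they belong to other plaques).
#' @export
make_band <- function(labelmap, target_label,
                      band_width_um = 5,
                      pixel_size_um = labelmap$pixel_size_um) {
  lab <- labelmap$labels
  stopifnot(is.matrix(lab))
  if (band_width_um < 0) stop("band_width_um must be >= 0")
  interior <- lab == target_label
  if (!any(interior)) stop("label ", target_label, " not found in label map")
  H <- nrow(lab); W <- ncol(lab)
  periphery <- matrix(FALSE, H, W)
  n_excl <- 0L
  if (band_width_um > 0) {
    band_px <- band_width_um / pixel_size_um
    # distances only matter inside the bounding box grown by the band width,
    # so the transform runs on a crop
    idx <- which(interior, arr.ind = TRUE)
    pad <- ceiling(band_px) + 1L
    r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(H, max(idx[, 1]) + pad)
    c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(W, max(idx[, 2]) + pad)
    d <- distance_to_mask(interior[r0:r1, c0:c1, drop = FALSE])
    band_crop <- d > 0 & d <= band_px
    lab_crop <- lab[r0:r1, c0:c1, drop = FALSE]
    other <- band_crop & lab_crop != 0L & lab_crop != target_label
    n_excl <- sum(other)
    periphery[r0:r1, c0:c1] <- band_crop & !other
  }
  structure(
    list(plaque_label = target_label, interior = interior,
         periphery = periphery, band_width_um = band_width_um,
         pixel_size_um = pixel_size_um,
         n_excluded_other_plaque = n_excl),
    class = "band_roi"
  )
}
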