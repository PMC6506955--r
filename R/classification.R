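# Dense-core / fibrillar / mixed plaque classification from relative
# Abeta and thioflavin S intensity.

#' Plaque classification parameters
#'
#' Numeric surrogate for the qualitative dense-core / fibrillar / mixed
#' distinction: compact cores show very bright thioflavin S labelling while
#' fibrillar material labels weakly. None of these cutoffs are established
#' reference values; they are this package's reproducible operationalization
#' of that visual criterion, and all four are exposed in the configuration.
#'
#' @param core_thios_quantile Within-plaque thioS quantile defining candidate
#'   core pixels (default 0.90).
#' @param core_bright_ratio Minimum ratio of core mean thioS to halo mean
#'   thioS for a "very bright" core (default 2).
#' @param min_core_frac Core area fraction required to call a plaque with no
#'   distinct halo dense-core (default 0.25).
#' @param min_halo_frac Halo area fraction above which a cored plaque is
#'   mixed rather than dense-core (default 0.25).
#' @param opening_radius_um Radius (um) of the morphological opening that
#'   removes speckle from the candidate core (default 1).
#' @return An object of class \code{classification_params}.
#' @export
classification_params <- function(core_thios_quantile = 0.90,
                                  core_bright_ratio = 2.0,
                                  min_core_frac = 0.25,
                                  min_halo_frac = 0.25,
                                  opening_radius_um = 1.0) {
  p <- list(core_thios_quantile = core_thios_quantile,
            core_bright_ratio = core_bright_ratio,
            min_core_frac = min_core_frac,
            min_halo_frac = min_halo_frac,
            opening_radius_um = opening_radius_um)
  class(p) <- "classification_params"
  validate_classification_params(p)
  p
}

validate_classification_params <- function(p) {
  stopifnot(inherits(p, "classification_params"))
  if (p$core_thios_quantile <= 0 || p$core_thios_quantile >= 1) {
    stop("core_thios_quantile must be in (0, 1)")
  }
  if (p$core_bright_ratio <= 1) stop("core_bright_ratio must be > 1")
  for (f in c("min_core_frac", "min_halo_frac")) {
    if (p[[f]] <= 0 || p[[f]] >= 1) stop(f, " must be in (0, 1)")
  }
  if (p$opening_radius_um <= 0) stop("opening_radius_um must be > 0")
  invisible(p)
}

#' Classify one plaque from its Abeta and thioflavin S intensity
#'
#' Deterministic rule. (1) Candidate core pixels are within-plaque pixels at
#' or above the \code{core_thios_quantile} within-plaque thioS value,
#' morphologically opened to remove speckle; the halo is the remainder of
#' the plaque. (2) The core is "very bright" when it is nonempty and its mean
#' thioS is at least \code{core_bright_ratio} times the halo mean (infinite
#' ratio when the halo is empty). (3) A bright-cored plaque is dense-core
#' when the halo fraction is below \code{min_halo_frac} and mixed otherwise.
#' (4) A plaque without an internal bright core is homogeneous; it is
#' classified by the relative staining intensity of thioflavin S versus
#' Abeta (each normalized to its channel's field mean, so per-channel gain
#' cancels): homogeneously thioS-bright plaques (thioS enrichment at least
#' the Abeta enrichment) are dense-core, homogeneously thioS-weak plaques
#' are fibrillar. Plaques whose thioS does not stand above background are
#' unclassified (diffuse, thioS-negative objects are not given a class of
#' their own).
#'
#' Background is estimated from \code{field_mask} (default: everything
#' outside the plaque); the plaque is "above background" when its mean thioS
#' exceeds the background mean by two background standard deviations.
#'
#' @param abeta,thios Intensity channels (co-registered with the mask).
#' @param plaque_mask Logical matrix, one plaque component.
#' @param params A \code{\link{classification_params}}.
#' @param pixel_size_um Micrometres per pixel (for the opening radius).
#' @param field_mask Optional logical matrix of background pixels for the
#'   thioS-negativity check; in pipelines, pass tissue outside all plaques.
#' @return One of \code{"dense_core"}, \code{"fibrillar"}, \code{"mixed"},
#'   \code{"unclassified"}.
#' @export
classify_plaque <- function(abeta, thios, plaque_mask,
                            params = classification_params(),
                            pixel_size_um = 1,
                            field_mask = NULL) {
  check_image(thios)
  check_same_shape(thios, plaque_mask)
  validate_classification_params(params)
  if (!any(plaque_mask)) stop("plaque_mask is empty")
  if (is.null(field_mask)) field_mask <- !plaque_mask
  # evaluate on the lightly eroded mask: the segmentation boundary carries
  # the PSF edge rolloff, which would otherwise mimic a weak halo
  em <- erode_mask(plaque_mask, params$opening_radius_um, pixel_size_um)
  if (!any(em)) em <- plaque_mask
  tv <- thios[em]

  # thioS-negative => unclassified
  bg <- thios[field_mask]
  bg_mean <- if (length(bg)) mean(bg) else 0
  bg_sd <- if (length(bg) > 1L) stats::sd(bg) else 0
  if (mean(tv) <= bg_mean + 2 * bg_sd) return("unclassified")

  qv <- stats::quantile(tv, params$core_thios_quantile, names = FALSE)
  cand <- em & (thios >= qv)
  rest <- em & !cand
  if (any(cand) && any(rest)) {
    # under noise the quantile cut selects scattered bright pixels; grow the
    # candidate to the midpoint between candidate and remainder means so a
    # genuine compact core is recovered as a region, then open off speckle
    t2 <- (mean(thios[cand]) + mean(thios[rest])) / 2
    cand <- em & (thios >= t2)
  }
  core <- open_mask(cand, params$opening_radius_um, pixel_size_um) & em
  halo <- em & !core
  n_core <- sum(core); n_halo <- sum(halo)
  ratio <- if (n_core == 0L) 0 else if (n_halo == 0L) Inf else
    mean(thios[core]) / mean(thios[halo])
  bright_core <- n_core > 0L && ratio >= params$core_bright_ratio
  if (bright_core) {
    halo_frac <- n_halo / sum(em)
    if (n_halo == 0L) {
      core_frac <- n_core / sum(em)
      if (core_frac >= params$min_core_frac) return("dense_core")
      return("fibrillar")
    }
    if (halo_frac < params$min_halo_frac) "dense_core" else "mixed"
  } else {
    # homogeneous plaque: relative thioS vs Abeta staining intensity,
    # field-normalized per channel so gain cancels
    check_image(abeta)
    t_field <- mean(thios[field_mask])
    a_field <- mean(abeta[field_mask])
    e_thios <- if (t_field > 0) mean(tv) / t_field else Inf
    e_abeta <- if (a_field > 0) mean(abeta[em]) / a_field else Inf
    if (e_thios >= e_abeta) "dense_core" else "fibrillar"
  }
}

erode_mask <- function(mask, radius_um, pixel_size_um) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  br <- disc_brush(radius_um, pixel_size_um)
  EBImage::erode(m, br) > 0.5
}

open_mask <- function(mask, radius_um, pixel_size_um) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  br <- disc_brush(radius_um, pixel_size_um)
  EBImage::opening(m, br) > 0.5
}

#' Classify all plaques in a label map
#'
#' Convenience wrapper applying \code{\link{classify_plaque}} to every label,
#' with the field for the background check taken as everything outside all
#' plaques.
#'
#' @param records Plaque records from \code{\link{measure_plaques}}.
#' @param labelmap The matching \code{\link{segment_plaques}} result.
#' @param abeta,thios Intensity channels.
#' @param params A \code{\link{classification_params}}.
#' @return \code{records} with \code{plaque_class} filled in.
#' @export
classify_plaques <- function(records, labelmap, abeta, thios,
                             params = classification_params()) {
  stopifnot(inherits(labelmap, "plaque_labelmap"))
  lab <- labelmap$labels
  field <- lab == 0L
  for (i in seq_len(nrow(records))) {
    records$plaque_class[i] <- classify_plaque(
      abeta, thios, lab == records$label[i], params,
      pixel_size_um = labelmap$pixel_size_um, field_mask = field)
  }
  records
}

#' Fraction of plaques in each morphological class
#'
#' Fractions over the classified plaques (dense-core, fibrillar, mixed) sum
#' to one; unclassified plaques are excluded from the denominator and
#' reported separately.
#'
#' @param classes Character vector of per-plaque classes (or a plaque-record
#'   data.frame with a \code{plaque_class} column).
#' @return One-row data.frame: \code{frac_dense_core}, \code{frac_fibrillar},
#'   \code{frac_mixed}, \code{n_classified}, \code{n_unclassified}. With
#'   zero classified plaques the fractions are NA.
#' @export
class_fractions <- function(classes) {
  if (is.data.frame(classes)) classes <- classes$plaque_class
  n_un <- sum(classes == "unclassified")
  cl <- classes[classes != "unclassified"]
  n <- length(cl)
  if (n == 0L) {
    return(data.frame(frac_dense_core = NA_real_, frac_fibrillar = NA_real_,
                      frac_mixed = NA_real_, n_classified = 0L,
                      n_unclassified = n_un))
  }
  data.frame(
    frac_dense_core = sum(cl == "dense_core") / n,
    frac_fibrillar = sum(cl == "fibrillar") / n,
    frac_mixed = sum(cl == "mixed") / n,
    n_classified = n,
    n_unclassified = n_un
  )
}
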