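#' Analysis run configuration
#'
#' Builds a validated configuration object holding every tunable parameter of
#' the pipeline. All geometric parameters are in physical units (micrometres
#' or square micrometres) and are converted to pixels only at the point of
#' use, so one configuration applies across magnifications.
#'
#' @param blur_radius_um Gaussian smoothing sigma (um) applied to the Abeta
#'   channel before thresholding when defining plaque boundaries. The
#'   boundary-definition protocol uses 2 um; set to 0 to threshold the raw
#'   image (as in plain size/number morphometry).
#' @param min_plaque_area_um2 Objects must be strictly larger than this
#'   (um^2) to count as plaques. Default 50.
#' @param band_width_um Width (um) of the peri-plaque band. Default 5.
#' @param coverage_distance_um A plaque boundary pixel counts as covered by
#'   microglia when a thresholded Iba1-positive pixel lies within this
#'   distance (um). Default 2.
#' @param neuron_search_radius_um Neurons within this distance (um) of the
#'   nearest plaque are "peri-plaque" for Abeta-positivity scoring.
#' @param puncta_positive_threshold A neuron is Abeta-positive when it
#'   contains at least this many intracellular Abeta puncta. Default 3.
#' @param dystrophy_positive_threshold A plaque is dystrophic when at least
#'   this many large presynaptic dystrophies surround it. Default 4.
#' @param min_dystrophy_area_um2 Minimum area (um^2) for a synaptophysin blob
#'   to count as a "large" dystrophy. Default 3.
#' @param background_percentile Percentile subtracted by
#'   \code{\link{background_correct}}. Default 1.
#' @param threshold Named list mapping channel names to a threshold
#'   specification \code{list(method = , value = )} with method one of
#'   \code{"otsu"}, \code{"fixed_percentile"}, \code{"fixed_value"}.
#'   Channels without an entry use Otsu.
#' @param classification A \code{\link{classification_params}} object.
#' @param microglia_soma_area_um2 Length-2 numeric, area window (um^2) for
#'   Iba1-positive soma counting. Default c(20, 500).
#' @param neuron_soma_area_um2 Length-2 numeric, soma area window for NeuN
#'   detection. Default c(40, 400).
#' @param punctum_area_um2 Length-2 numeric, area window for an intracellular
#'   Abeta punctum. Default c(0.2, 5).
#' @param punctum_radius_um Top-hat structuring radius (um), approximately the
#'   largest punctum radius. Default 1.5.
#' @param puncta_contrast_factor Punctum pixels must exceed the within-soma
#'   median by (factor - 1) times the median after top-hat filtering.
#'   Default 2.5.
#' @param min_plaques_per_mouse Per-animal plaque floor below which summary
#'   rows are flagged. Default 10.
#' @param exclude_border_plaques Drop plaques touching the image border from
#'   summaries. Default FALSE (they are flagged, not dropped).
#' @param rng_seed Integer seed recorded with the run.
#'
#' @return An object of class \code{periplaque_config} (a named list).
#' @export
run_config <- function(blur_radius_um = 2.0,
                       min_plaque_area_um2 = 50.0,
                       band_width_um = 5.0,
                       coverage_distance_um = 2.0,
                       neuron_search_radius_um = 50.0,
                       puncta_positive_threshold = 3L,
                       dystrophy_positive_threshold = 4L,
                       min_dystrophy_area_um2 = 3.0,
                       background_percentile = 1.0,
                       threshold = list(),
                       classification = classification_params(),
                       microglia_soma_area_um2 = c(20, 500),
                       neuron_soma_area_um2 = c(40, 400),
                       punctum_area_um2 = c(0.2, 5),
                       punctum_radius_um = 1.5,
                       puncta_contrast_factor = 2.5,
                       min_plaques_per_mouse = 10L,
                       exclude_border_plaques = FALSE,
                       rng_seed = 1L) {
  cfg <- list(
    blur_radius_um = blur_radius_um,
    min_plaque_area_um2 = min_plaque_area_um2,
    band_width_um = band_width_um,
    coverage_distance_um = coverage_distance_um,
    neuron_search_radius_um = neuron_search_radius_um,
    puncta_positive_threshold = as.integer(puncta_positive_threshold),
    dystrophy_positive_threshold = as.integer(dystrophy_positive_threshold),
    min_dystrophy_area_um2 = min_dystrophy_area_um2,
    background_percentile = background_percentile,
    threshold = threshold,
    classification = classification,
    microglia_soma_area_um2 = as.numeric(microglia_soma_area_um2),
    neuron_soma_area_um2 = as.numeric(neuron_soma_area_um2),
    punctum_area_um2 = as.numeric(punctum_area_um2),
    punctum_radius_um = punctum_radius_um,
    puncta_contrast_factor = puncta_contrast_factor,
    min_plaques_per_mouse = as.integer(min_plaques_per_mouse),
    exclude_border_plaques = isTRUE(exclude_border_plaques),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "periplaque_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "periplaque_config"))
  pos <- c("min_plaque_area_um2", "band_width_um", "coverage_distance_um",
           "neuron_search_radius_um", "min_dystrophy_area_um2",
           "punctum_radius_um")
  for (p in pos) {
    if (!is.numeric(cfg[[p]]) || length(cfg[[p]]) != 1L || cfg[[p]] <= 0) {
      stop("config: '", p, "' must be a single positive number")
    }
  }
  if (!is.numeric(cfg$blur_radius_um) || cfg$blur_radius_um < 0) {
    stop("config: 'blur_radius_um' must be >= 0 (0 disables smoothing)")
  }
  if (cfg$puncta_positive_threshold < 1L || cfg$dystrophy_positive_threshold < 1L) {
    stop("config: count thresholds must be positive integers")
  }
  if (cfg$background_percentile < 0 || cfg$background_percentile >= 100) {
    stop("config: 'background_percentile' must be in [0, 100)")
  }
  for (w in c("microglia_soma_area_um2", "neuron_soma_area_um2",
              "punctum_area_um2")) {
    v <- cfg[[w]]
    if (length(v) != 2L || any(v <= 0) || v[1] >= v[2]) {
      stop("config: '", w, "' must be an increasing positive length-2 window")
    }
  }
  for (nm in names(cfg$threshold)) {
    ts <- cfg$threshold[[nm]]
    if (!ts$method %in% c("otsu", "fixed_percentile", "fixed_value")) {
      stop("config: unknown threshold method '", ts$method, "' for ", nm)
    }
    if (ts$method != "otsu" && is.null(ts$value)) {
      stop("config: threshold method '", ts$method, "' needs a value")
    }
    if (ts$method == "fixed_percentile" &&
        (ts$value < 0 || ts$value > 100)) {
      stop("config: percentile must be in [0, 100]")
    }
  }
  validate_classification_params(cfg$classification)
  invisible(cfg)
}

#' Read or write a run configuration as YAML
#'
#' A flat YAML document holding every field of \code{\link{run_config}};
#' omitted fields take the documented defaults, so a config file only needs
#' the parameters a run overrides. \code{write_config} echoes the fully
#' resolved configuration, which is how runs record their parameters.
#'
#' @param path File path of the YAML document.
#' @return \code{read_config} returns a \code{periplaque_config}.
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  cls <- doc$classification
  doc$classification <- NULL
  known <- names(formals(run_config))
  unknown <- setdiff(names(doc), known)
  if (length(unknown)) {
    stop("config file: unknown fields: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(cls)) {
    doc$classification <- do.call(classification_params, cls)
  }
  do.call(run_config, doc)
}

#' @param config A \code{periplaque_config}.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  validate_config(config)
  doc <- unclass(config)
  doc$classification <- unclass(doc$classification)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Convert a physical length to a whole number of pixels
#'
#' Structuring-element radii and other integer pixel sizes are derived from
#' micrometre parameters by round-half-up, with a floor of one pixel, so the
#' conversion is deterministic across platforms.
#'
#' @param length_um Length in micrometres.
#' @param pixel_size_um Micrometres per pixel (> 0).
#' @return A positive integer number of pixels.
#' @export
um_to_px <- function(length_um, pixel_size_um) {
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be positive")
  }
  max(1L, as.integer(floor(length_um / pixel_size_um + 0.5)))
}

# threshold spec for a channel, defaulting to Otsu
threshold_spec_for <- function(config, channel) {
  ts <- config$threshold[[channel]]
  if (is.null(ts)) list(method = "otsu", value = NULL) else ts
}
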