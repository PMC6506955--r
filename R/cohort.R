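# Two-condition synthetic cohorts with per-animal variability.

COHORT_EFFECT_KNOBS <- c("plaque_count", "plaque_area",
                         "gfap_band_enrichment", "gfap_interior_enrichment",
                         "coverage", "neuron_positivity", "aqp4_band")

#' Apply condition or animal effect multipliers to a scene spec
#'
#' Recognized knobs: \code{plaque_count} (rounds the plaque count),
#' \code{plaque_area} (multiplies every plaque area, i.e. scales radii by
#' the square root), \code{gfap_band_enrichment},
#' \code{gfap_interior_enrichment} (scale the factors' excess over 1, so a
#' multiplier cannot push an enrichment below baseline), \code{coverage}
#' (scales the coverage range, clipped to [0, 1]),
#' \code{neuron_positivity} (clipped to [0, 1]) and \code{aqp4_band}.
#'
#' @param spec A \code{\link{scene_spec}}.
#' @param effects Named numeric vector/list of positive multipliers.
#' @return The modified spec.
#' @export
apply_effects <- function(spec, effects) {
  effects <- unlist(effects)
  if (!length(effects)) return(spec)
  unknown <- setdiff(names(effects), COHORT_EFFECT_KNOBS)
  if (length(unknown)) {
    stop("unknown effect knob(s): ", paste(unknown, collapse = ", "))
  }
  if (any(effects <= 0)) stop("effect multipliers must be positive")
  e <- function(k) if (k %in% names(effects)) effects[[k]] else 1
  spec$plaques$count <- as.integer(round(spec$plaques$count * e("plaque_count")))
  spec$plaques$radius_meanlog <- spec$plaques$radius_meanlog +
    0.5 * log(e("plaque_area"))
  spec$gfap$band_enrichment_factor <- 1 +
    (spec$gfap$band_enrichment_factor - 1) * e("gfap_band_enrichment")
  spec$gfap$interior_enrichment_factor <- 1 +
    (spec$gfap$interior_enrichment_factor - 1) * e("gfap_interior_enrichment")
  spec$microglia$coverage_range <-
    pmin(pmax(spec$microglia$coverage_range * e("coverage"), 0), 1)
  spec$neurons$positivity_rate <-
    min(max(spec$neurons$positivity_rate * e("neuron_positivity"), 0), 1)
  spec$aqp4$band_enrichment_factor <- 1 +
    (spec$aqp4$band_enrichment_factor - 1) * e("aqp4_band")
  spec
}

#' Generate a multi-animal, multi-condition synthetic cohort
#'
#' Each animal gets its own scene spec: the base spec with the condition's
#' effect multipliers and, when \code{animal_sdlog > 0}, independent
#' lognormal between-animal multipliers (one per knob). Every scene is
#' rendered deterministically from a seed derived from the cohort seed.
#'
#' @param base_spec A \code{\link{scene_spec}}.
#' @param condition_effects Named list: one entry per condition, each a
#'   named vector of effect multipliers (see \code{\link{apply_effects}});
#'   an empty vector means the base condition.
#' @param n_per_condition Named integer vector of animals per condition (>= 1).
#' @param images_per_animal Scenes rendered per animal.
#' @param seed Cohort seed; all randomness derives from it.
#' @param animal_sdlog Between-animal lognormal variability (sdlog) applied
#'   to every effect knob; 0 disables it.
#' @param pair_conditions When TRUE, the k-th animal of every condition uses
#'   the same scene seeds (matched sampling, useful for paired construction
#'   checks); default FALSE, fully independent animals.
#' @return An object of class \code{cohort}: list with \code{scenes} (each
#'   \code{stack}, \code{truth}, \code{animal_id}, \code{condition}) and
#'   \code{manifest} (data.frame: image_id, animal_id, condition).
#' @export
generate_cohort <- function(base_spec, condition_effects,
                            n_per_condition, images_per_animal = 1L,
                            seed = 1L, animal_sdlog = 0.15,
                            pair_conditions = FALSE) {
  stopifnot(inherits(base_spec, "scene_spec"))
  conds <- names(condition_effects)
  if (is.null(conds) || !all(conds %in% names(n_per_condition))) {
    stop("condition_effects and n_per_condition must share condition names")
  }
  if (any(n_per_condition < 1L)) stop("n_per_condition must be >= 1")
  scenes <- list()
  manifest <- NULL
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    n_animals <- n_per_condition[[cond]]
    cond_spec <- apply_effects(base_spec, condition_effects[[cond]])
    # per-animal multipliers, one independent lognormal draw per knob
    animal_mults <- with_rng_seed(seed + 131L * ci, {
      lapply(seq_len(n_animals), function(a) {
        m <- exp(stats::rnorm(length(COHORT_EFFECT_KNOBS), 0, animal_sdlog))
        names(m) <- COHORT_EFFECT_KNOBS
        m
      })
    })
    for (a in seq_len(n_animals)) {
      animal_id <- sprintf("%s_m%02d", cond, a)
      spec_a <- if (animal_sdlog > 0) {
        apply_effects(cond_spec, animal_mults[[a]])
      } else cond_spec
      for (j in seq_len(images_per_animal)) {
        scene_seed <- if (pair_conditions) {
          seed + 1009L * a + j
        } else {
          seed + 100003L * ci + 1009L * a + j
        }
        image_id <- sprintf("%s_img%02d", animal_id, j)
        sc <- generate_scene(spec_a, seed = scene_seed, image_id = image_id,
                             animal_id = animal_id, condition = cond)
        scenes[[length(scenes) + 1L]] <- c(sc, list(animal_id = animal_id,
                                                    condition = cond))
        manifest <- rbind(manifest, data.frame(
          image_id = image_id, animal_id = animal_id, condition = cond,
          stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(scenes = scenes, manifest = manifest,
                 images_per_animal = images_per_animal, seed = seed),
            class = "cohort")
}

#' Write a cohort to disk
#'
#' One OME-TIFF per scene, one ground-truth JSON per scene, plus a manifest
#' CSV (image, animal, condition, file names).
#'
#' @param cohort A \code{\link{generate_cohort}} result.
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame (with file columns), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$image_file <- paste0(man$image_id, ".ome.tif")
  man$truth_file <- paste0(man$image_id, ".truth.json")
  for (i in seq_along(cohort$scenes)) {
    sc <- cohort$scenes[[i]]
    write_channel_stack(sc$stack, file.path(dir, man$image_file[i]))
    tr <- sc$truth
    tr$plaque_labels <- NULL  # masks live in TIFF outputs, not JSON
    tr$vessel_mask <- NULL
    jsonlite::write_json(unclass(tr), file.path(dir, man$truth_file[i]),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
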