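# Synthetic multi-channel histology scenes with planted ground truth.
#
# Scenes emulate the image structure the measurements assume: compact
# plaque cores with weaker fibrillar halos (Abeta / thioflavin S),
# filamentous GFAP webs whose stroke density is multiplied near plaques,
# microglial somata plus perimeter arcs covering planted fractions of
# plaque boundaries, neuronal somata with intracellular Abeta puncta,
# peri-plaque synaptophysin dystrophy blobs, vessels with perivascular
# AQP4 enrichment, then PSF blur and Poisson-Gaussian camera noise.

#' Specification of a synthetic scene
#'
#' All lengths in micrometres, densities per mm^2 (or per 100 um^2 for GFAP
#' filaments), intensities in arbitrary camera units. Any field can be
#' overridden; the remaining fields keep their defaults.
#'
#' @param fov_um Height/width of the field of view (um).
#' @param pixel_size_um Micrometres per pixel.
#' @param plaques,background,gfap,microglia,neurons,dystrophies,vessels,aqp4,noise
#'   Named lists overriding individual parameters; see the package vignette
#'   for the meaning and rationale of each default.
#' @param seed Default RNG seed used by \code{\link{generate_scene}}.
#' @return An object of class \code{scene_spec}.
#' @export
scene_spec <- function(fov_um = c(128, 128), pixel_size_um = 0.5,
                       plaques = list(), background = list(), gfap = list(),
                       microglia = list(), neurons = list(),
                       dystrophies = list(), vessels = list(),
                       aqp4 = list(), noise = list(), seed = 1L) {
  spec <- list(
    fov_um = rep(fov_um, length.out = 2),
    pixel_size_um = pixel_size_um,
    plaques = list(
      count = 10L,
      radius_meanlog = log(7), radius_sdlog = 0.2,
      min_radius_um = 4.2,
      class_mix = c(dense_core = 0.4, fibrillar = 0.4, mixed = 0.2),
      core_radius_frac = 0.4,
      abeta_core_level = 300, abeta_halo_level = 200,
      thios_bright_level = 500, thios_weak_level = 60,
      min_gap_um = 12, border_margin_um = 8),
    background = list(abeta = 5, thios = 4, gfap = 4, iba1 = 2,
                      neun = 3, syp = 2, aqp4 = 0),
    gfap = list(filament_density_per_100um2 = 0.8,
                stroke_length_um = 4, stroke_width_um = 0.6,
                stroke_level = 120,
                band_enrichment_factor = 2.5,
                interior_enrichment_factor = 1.5),
    microglia = list(density_per_mm2 = 150, soma_radius_um = 3.5,
                     soma_level = 250, coverage_range = c(0.3, 0.9),
                     arc_thickness_um = 1.5, arc_level = 250,
                     assoc_distance_um = 2),
    neurons = list(density_per_mm2 = 500, soma_radius_um = 8,
                   soma_level = 160, positivity_rate = 0.3,
                   puncta_pos_range = c(3L, 7L), puncta_neg_range = c(0L, 2L),
                   punctum_radius_um = 0.5, soma_abeta_floor = 16,
                   punctum_level = 80, search_radius_um = 50),
    dystrophies = list(count_range = c(2L, 6L), blob_radius_um = 1.25,
                       level = 200, small_count = 0L,
                       small_radius_um = 0.7),
    vessels = list(count = 1L, radius_um = 5, pv_width_um = 2,
                   pv_enrichment_factor = 4, lumen_level = 0),
    aqp4 = list(parenchyma_level = 100, band_enrichment_factor = 1.8,
                offset = 0),
    noise = list(psf_sigma_um = 0.3, photon_scale = 1, read_sd = 2),
    seed = as.integer(seed)
  )
  for (part in c("plaques", "background", "gfap", "microglia", "neurons",
                 "dystrophies", "vessels", "aqp4", "noise")) {
    ov <- get(part)
    unknown <- setdiff(names(ov), names(spec[[part]]))
    if (length(unknown)) {
      stop("scene_spec: unknown ", part, " field(s): ",
           paste(unknown, collapse = ", "))
    }
    spec[[part]][names(ov)] <- ov
  }
  validate_scene_spec(spec)
  class(spec) <- "scene_spec"
  spec
}

validate_scene_spec <- function(spec) {
  stopifnot(all(spec$fov_um > 0), spec$pixel_size_um > 0)
  mix <- spec$plaques$class_mix
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
    stop("plaque class_mix must be a probability vector over ",
         "dense_core/fibrillar/mixed")
  }
  if (spec$neurons$positivity_rate < 0 || spec$neurons$positivity_rate > 1) {
    stop("neuron positivity_rate must be in [0, 1]")
  }
  lv <- c(unlist(spec$background), spec$plaques$abeta_core_level,
          spec$gfap$stroke_level, spec$aqp4$parenchyma_level)
  if (any(lv < 0)) stop("intensity levels must be non-negative")
  invisible(spec)
}

#' Disable PSF blur and camera noise in a scene spec
#'
#' Convenience for ground-truth recovery checks that assume geometrically
#' exact renders.
#'
#' @param spec A \code{\link{scene_spec}}.
#' @param psf Keep the PSF (TRUE) or zero it as well (FALSE, default).
#' @return The modified spec.
#' @export
noise_free <- function(spec, psf = FALSE) {
  spec$noise$photon_scale <- 0
  spec$noise$read_sd <- 0
  if (!psf) spec$noise$psf_sigma_um <- 0
  spec
}

# run code with a private RNG state
with_rng_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Render a synthetic scene
#'
#' Draws object geometry from the spec, renders every channel, convolves
#' with a Gaussian PSF and applies Poisson photon noise plus Gaussian read
#' noise. All randomness flows from the single seed, so identical
#' spec + seed gives bit-identical output.
#'
#' @param spec A \code{\link{scene_spec}}.
#' @param seed RNG seed (defaults to \code{spec$seed}).
#' @param image_id,animal_id,condition Metadata for the resulting stack.
#' @return List with \code{stack} (a \code{\link{channel_stack}}) and
#'   \code{truth} (a \code{scene_truth}: per-object planted parameters,
#'   the planted plaque label map, and the enrichment factors).
#' @export
generate_scene <- function(spec, seed = spec$seed, image_id = "scene",
                           animal_id = "animal", condition = "") {
  stopifnot(inherits(spec, "scene_spec"))
  with_rng_seed(seed, render_scene(spec, image_id, animal_id, condition))
}

render_scene <- function(spec, image_id, animal_id, condition) {
  px <- spec$pixel_size_um
  H <- as.integer(round(spec$fov_um[1] / px))
  W <- as.integer(round(spec$fov_um[2] / px))
  xs <- (seq_len(W) - 0.5) * px  # pixel-center coordinates in um
  ys <- (seq_len(H) - 0.5) * px
  fov_area_um2 <- H * W * px^2

  chan <- function(base) matrix(base, H, W)
  bg <- spec$background
  abeta <- chan(bg$abeta); thios <- chan(bg$thios)
  gfap <- chan(bg$gfap); iba1 <- chan(bg$iba1)
  neun <- chan(bg$neun); syp <- chan(bg$syp)
  aqp4 <- chan(spec$aqp4$parenchyma_level)

  ## ---- plaques -----------------------------------------------------
  pl <- spec$plaques
  n_pl <- as.integer(pl$count)
  plaque_truth <- NULL
  plaque_lab <- matrix(0L, H, W)
  if (n_pl > 0L) {
    # radii are floored just above the size filter so every planted plaque
    # is, by construction, a countable object
    radii <- pmax(stats::rlnorm(n_pl, pl$radius_meanlog, pl$radius_sdlog),
                  pl$min_radius_um)
    classes <- sample(names(pl$class_mix), n_pl, replace = TRUE,
                      prob = pl$class_mix)
    pos <- place_disks(n_pl, radii, spec$fov_um, pl$border_margin_um,
                       pl$min_gap_um, what = "plaques")
    plaque_truth <- data.frame(
      id = seq_len(n_pl), cx_um = pos$x, cy_um = pos$y,
      radius_um = radii, class = classes,
      coverage_fraction = NA_real_, n_dystrophies = NA_integer_,
      stringsAsFactors = FALSE)
    for (i in seq_len(n_pl)) {
      dm <- disk_mask(xs, ys, pos$x[i], pos$y[i], radii[i])
      plaque_lab[dm] <- i
      cls <- classes[i]
      if (cls == "dense_core") {
        abeta[dm] <- pmax(abeta[dm], pl$abeta_core_level)
        thios[dm] <- pmax(thios[dm], pl$thios_bright_level)
      } else if (cls == "fibrillar") {
        tex <- 0.7 + 0.6 * stats::runif(sum(dm))
        abeta[dm] <- pmax(abeta[dm], pl$abeta_halo_level * tex)
        thios[dm] <- pmax(thios[dm], pl$thios_weak_level *
                            (0.7 + 0.6 * stats::runif(sum(dm))))
      } else {  # mixed: bright compact core inside a weak fibrillar halo
        core <- disk_mask(xs, ys, pos$x[i], pos$y[i],
                          radii[i] * pl$core_radius_frac)
        abeta[dm] <- pmax(abeta[dm], pl$abeta_halo_level)
        abeta[core] <- pmax(abeta[core], pl$abeta_core_level)
        thios[dm] <- pmax(thios[dm], pl$thios_weak_level *
                            (0.7 + 0.6 * stats::runif(sum(dm))))
        thios[core] <- pmax(thios[core], pl$thios_bright_level)
      }
    }
  }

  # distance (px) from every pixel to the nearest plaque, for band regions
  d_plaque <- if (n_pl > 0L) distance_to_mask(plaque_lab > 0L) else
    matrix(Inf, H, W)
  band_px <- 5 / px  # the 5-um band region the enrichment factors target
  band_region <- d_plaque > 0 & d_plaque <= band_px
  interior_region <- plaque_lab > 0L

  ## ---- GFAP filament web -------------------------------------------
  gf <- spec$gfap
  n_base <- round(gf$filament_density_per_100um2 * fov_area_um2 / 100)
  if (n_base > 0L && gf$stroke_level > 0) {
    fmax <- max(1, gf$band_enrichment_factor, gf$interior_enrichment_factor)
    n_cand <- round(n_base * fmax)
    cx <- stats::runif(n_cand, 0, spec$fov_um[2])
    cy <- stats::runif(n_cand, 0, spec$fov_um[1])
    ang <- stats::runif(n_cand, 0, pi)
    u <- stats::runif(n_cand)
    ci <- pmin(pmax(ceiling(cy / px), 1L), H)
    cj <- pmin(pmax(ceiling(cx / px), 1L), W)
    local_f <- ifelse(interior_region[cbind(ci, cj)],
                      gf$interior_enrichment_factor,
                      ifelse(band_region[cbind(ci, cj)],
                             gf$band_enrichment_factor, 1))
    keep <- u < local_f / fmax
    gfap <- add_strokes(gfap, xs, ys, cx[keep], cy[keep], ang[keep],
                        gf$stroke_length_um, gf$stroke_width_um,
                        gf$stroke_level)
  }

  ## ---- microglia ----------------------------------------------------
  mg <- spec$microglia
  n_mg <- as.integer(round(mg$density_per_mm2 * fov_area_um2 / 1e6))
  mg_truth <- NULL
  if (n_mg > 0L) {
    mpos <- place_disks(n_mg, rep(mg$soma_radius_um, n_mg), spec$fov_um,
                        mg$soma_radius_um + 1,
                        min_gap_um = 1,
                        avoid = plaque_truth,
                        avoid_gap_um = mg$assoc_distance_um + 2,
                        what = "microglial somata")
    mg_truth <- data.frame(id = seq_len(n_mg), cx_um = mpos$x,
                           cy_um = mpos$y, radius_um = mg$soma_radius_um)
    for (i in seq_len(n_mg)) {
      dm <- disk_mask(xs, ys, mpos$x[i], mpos$y[i], mg$soma_radius_um)
      iba1[dm] <- pmax(iba1[dm], mg$soma_level)
    }
  }
  # perimeter coverage arcs; the planted fraction is defined as the fraction
  # of boundary within the association distance of the arc, so arc ends are
  # trimmed by that reach
  if (n_pl > 0L) {
    fr <- stats::runif(n_pl, mg$coverage_range[1], mg$coverage_range[2])
    th0 <- stats::runif(n_pl, 0, 2 * pi)
    for (i in seq_len(n_pl)) {
      plaque_truth$coverage_fraction[i] <- fr[i]
      iba1 <- add_arc(iba1, xs, ys, plaque_truth$cx_um[i],
                      plaque_truth$cy_um[i], plaque_truth$radius_um[i],
                      fr[i], th0[i], mg$arc_thickness_um,
                      mg$assoc_distance_um, mg$arc_level)
    }
  }

  ## ---- neurons and intracellular Abeta puncta ----------------------
  ne <- spec$neurons
  n_ne <- as.integer(round(ne$density_per_mm2 * fov_area_um2 / 1e6))
  neuron_truth <- NULL
  if (n_ne > 0L) {
    npos <- place_disks(n_ne, rep(ne$soma_radius_um, n_ne), spec$fov_um,
                        ne$soma_radius_um + 1,
                        min_gap_um = 2,
                        avoid = plaque_truth, avoid_gap_um = 1,
                        what = "neurons")
    edge_dist <- edge_distance(npos, plaque_truth)
    eligible <- edge_dist <= ne$search_radius_um
    positive <- eligible & stats::runif(n_ne) < ne$positivity_rate
    counts <- integer(n_ne)
    counts[positive] <- sample_range(ne$puncta_pos_range, sum(positive))
    counts[!positive] <- sample_range(ne$puncta_neg_range, sum(!positive))
    neuron_truth <- data.frame(
      id = seq_len(n_ne), cx_um = npos$x, cy_um = npos$y,
      radius_um = ne$soma_radius_um,
      distance_to_plaque_um = edge_dist,
      eligible = eligible, positive = positive, puncta_count = counts)
    for (i in seq_len(n_ne)) {
      dm <- disk_mask(xs, ys, npos$x[i], npos$y[i], ne$soma_radius_um)
      neun[dm] <- pmax(neun[dm], ne$soma_level)
      abeta[dm] <- pmax(abeta[dm], ne$soma_abeta_floor)
      if (counts[i] > 0L) {
        pp <- place_in_disk(counts[i], npos$x[i], npos$y[i],
                            ne$soma_radius_um - ne$punctum_radius_um - 1,
                            min_sep_um = 2.5)
        for (k in seq_len(nrow(pp))) {
          pm <- disk_mask(xs, ys, pp[k, 1], pp[k, 2], ne$punctum_radius_um)
          abeta[pm] <- pmax(abeta[pm], ne$punctum_level)
        }
      }
    }
  }

  ## ---- presynaptic dystrophies -------------------------------------
  dy <- spec$dystrophies
  if (n_pl > 0L) {
    for (i in seq_len(n_pl)) {
      k <- sample_range(dy$count_range, 1L)
      plaque_truth$n_dystrophies[i] <- k
      blobs <- place_on_annulus(
        k + dy$small_count, plaque_truth$cx_um[i], plaque_truth$cy_um[i],
        plaque_truth$radius_um[i] + dy$blob_radius_um + 0.3,
        plaque_truth$radius_um[i] + 5 - dy$blob_radius_um - 0.3,
        min_sep_um = 2 * dy$blob_radius_um + 1)
      if (nrow(blobs)) {
        for (k2 in seq_len(nrow(blobs))) {
          r_b <- if (k2 <= k) dy$blob_radius_um else dy$small_radius_um
          bm <- disk_mask(xs, ys, blobs[k2, 1], blobs[k2, 2], r_b)
          syp[bm] <- pmax(syp[bm], dy$level)
        }
      }
    }
  }

  ## ---- vessels and AQP4 --------------------------------------------
  vs <- spec$vessels
  vessel_truth <- NULL
  vessel_mask <- matrix(FALSE, H, W)
  if (spec$aqp4$band_enrichment_factor != 1 && n_pl > 0L) {
    aqp4[band_region] <- pmax(aqp4[band_region],
                              spec$aqp4$band_enrichment_factor *
                                spec$aqp4$parenchyma_level)
  }
  if (vs$count > 0L) {
    vessel_truth <- place_vessels(vs$count, spec$fov_um, plaque_truth,
                                  vs$radius_um + 1)
    for (i in seq_len(nrow(vessel_truth))) {
      dl <- line_distance(xs, ys, vessel_truth$x_um[i],
                          vessel_truth$y_um[i], vessel_truth$angle[i])
      lum <- dl <= vs$radius_um
      rim <- dl > vs$radius_um & dl <= vs$radius_um + vs$pv_width_um
      aqp4[rim] <- pmax(aqp4[rim], vs$pv_enrichment_factor *
                          spec$aqp4$parenchyma_level)
      aqp4[lum] <- vs$lumen_level
      vessel_mask <- vessel_mask | lum
    }
  }
  if (spec$aqp4$offset > 0) aqp4 <- aqp4 + spec$aqp4$offset

  ## ---- PSF and camera noise ----------------------------------------
  channels <- list(abeta = abeta, thios = thios, gfap = gfap, iba1 = iba1,
                   neun = neun, syp = syp, aqp4 = aqp4)
  no <- spec$noise
  channels <- lapply(channels, function(ch) {
    if (no$psf_sigma_um > 0) ch <- gaussian_blur_um(ch, no$psf_sigma_um, px)
    if (no$photon_scale > 0) {
      ch <- stats::rpois(length(ch), no$photon_scale * pmax(ch, 0)) /
        no$photon_scale
      ch <- matrix(ch, H, W)
    }
    if (no$read_sd > 0) {
      ch <- ch + matrix(stats::rnorm(H * W, 0, no$read_sd), H, W)
    }
    pmax(ch, 0)
  })

  truth <- structure(
    list(plaques = plaque_truth, neurons = neuron_truth,
         microglia = mg_truth, vessels = vessel_truth,
         plaque_labels = plaque_lab, vessel_mask = vessel_mask,
         factors = list(
           gfap_band = spec$gfap$band_enrichment_factor,
           gfap_interior = spec$gfap$interior_enrichment_factor,
           aqp4_band = spec$aqp4$band_enrichment_factor,
           aqp4_perivascular = spec$vessels$pv_enrichment_factor),
         n_plaques = n_pl, n_microglia = if (is.null(mg_truth)) 0L else n_mg,
         n_neurons = if (is.null(neuron_truth)) 0L else n_ne,
         fov_area_mm2 = fov_area_um2 / 1e6),
    class = "scene_truth")
  list(stack = channel_stack(channels, px, image_id = image_id,
                             animal_id = animal_id, condition = condition),
       truth = truth)
}

## ---- geometry helpers ----------------------------------------------

disk_mask <- function(xs, ys, cx, cy, r) {
  outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
}

line_distance <- function(xs, ys, x0, y0, angle) {
  # distance from pixel centers to an infinite line through (x0,y0)
  nx <- -sin(angle); ny <- cos(angle)
  abs(outer(ny * (ys - y0), nx * (xs - x0), "+"))
}

place_disks <- function(n, radii, fov_um, border_margin_um, min_gap_um,
                        avoid = NULL, avoid_gap_um = 0, what = "objects",
                        max_tries = 2000L) {
  x <- numeric(0); y <- numeric(0); r <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      m <- max(border_margin_um, radii[i])
      cx <- stats::runif(1, m, fov_um[2] - m)
      cy <- stats::runif(1, m, fov_um[1] - m)
      ok <- TRUE
      if (length(x)) {
        ok <- all(sqrt((x - cx)^2 + (y - cy)^2) >= r + radii[i] + min_gap_um)
      }
      if (ok && !is.null(avoid) && nrow(avoid)) {
        ok <- all(sqrt((avoid$cx_um - cx)^2 + (avoid$cy_um - cy)^2) >=
                    avoid$radius_um + radii[i] + avoid_gap_um)
      }
      if (ok) {
        x <- c(x, cx); y <- c(y, cy); r <- c(r, radii[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("placement error: could not place ", what, " object ", i, " of ",
           n, " without overlap; reduce count/size or grow the field of view")
    }
  }
  list(x = x, y = y)
}

place_in_disk <- function(n, cx, cy, r_max, min_sep_um, max_tries = 2000L) {
  if (r_max <= 0) stop("placement error: soma too small for puncta")
  pts <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    for (t in seq_len(max_tries)) {
      rr <- r_max * sqrt(stats::runif(1))
      aa <- stats::runif(1, 0, 2 * pi)
      p <- c(cx + rr * cos(aa), cy + rr * sin(aa))
      if (!nrow(pts) ||
          all(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= min_sep_um)) {
        pts <- rbind(pts, p)
        break
      }
      if (t == max_tries) stop("placement error: puncta do not fit in soma")
    }
  }
  pts
}

place_on_annulus <- function(n, cx, cy, r_min, r_max, min_sep_um,
                             max_tries = 2000L) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  if (r_max <= r_min) stop("placement error: annulus too thin for blobs")
  pts <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      rr <- stats::runif(1, r_min, r_max)
      aa <- stats::runif(1, 0, 2 * pi)
      p <- c(cx + rr * cos(aa), cy + rr * sin(aa))
      if (!nrow(pts) ||
          all(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= min_sep_um)) {
        pts <- rbind(pts, p)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("placement error: dystrophy blobs do not fit in band")
  }
  pts
}

place_vessels <- function(n, fov_um, plaques, clearance_um,
                          max_tries = 2000L) {
  out <- data.frame(x_um = numeric(0), y_um = numeric(0), angle = numeric(0))
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      x0 <- stats::runif(1, 0.2 * fov_um[2], 0.8 * fov_um[2])
      y0 <- stats::runif(1, 0.2 * fov_um[1], 0.8 * fov_um[1])
      ang <- stats::runif(1, 0, pi)
      good <- TRUE
      if (!is.null(plaques) && nrow(plaques)) {
        nx <- -sin(ang); ny <- cos(ang)
        d <- abs(nx * (plaques$cx_um - x0) + ny * (plaques$cy_um - y0))
        good <- all(d >= plaques$radius_um + clearance_um)
      }
      if (length(out$x_um)) {
        good <- good && all(abs(out$angle - ang) > 0.2 |
                              sqrt((out$x_um - x0)^2 + (out$y_um - y0)^2) >
                                4 * clearance_um)
      }
      if (good) {
        out <- rbind(out, data.frame(x_um = x0, y_um = y0, angle = ang))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("placement error: vessel ", i,
                  " cannot avoid all plaques; reduce plaque count")
  }
  out
}

edge_distance <- function(pos, plaques) {
  if (is.null(plaques) || !nrow(plaques)) {
    return(rep(Inf, length(pos$x)))
  }
  vapply(seq_along(pos$x), function(i) {
    max(0, min(sqrt((plaques$cx_um - pos$x[i])^2 +
                      (plaques$cy_um - pos$y[i])^2) - plaques$radius_um))
  }, numeric(1))
}

sample_range <- function(rng, n) {
  if (n == 0L) return(integer(0))
  lo <- as.integer(rng[1]); hi <- as.integer(rng[2])
  if (lo >= hi) return(rep(lo, n))
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

add_strokes <- function(img, xs, ys, cx, cy, ang, len_um, width_um, level) {
  px <- xs[2] - xs[1]
  half <- len_um / 2
  hw <- width_um / 2
  H <- length(ys); W <- length(xs)
  for (i in seq_along(cx)) {
    dx <- cos(ang[i]); dy <- sin(ang[i])
    x1 <- cx[i] - half * dx; x2 <- cx[i] + half * dx
    y1 <- cy[i] - half * dy; y2 <- cy[i] + half * dy
    c0 <- max(1L, floor((min(x1, x2) - hw) / px)); c1 <- min(W, ceiling((max(x1, x2) + hw) / px) + 1L)
    r0 <- max(1L, floor((min(y1, y2) - hw) / px)); r1 <- min(H, ceiling((max(y1, y2) + hw) / px) + 1L)
    if (c0 > c1 || r0 > r1) next
    xg <- xs[c0:c1]; yg <- ys[r0:r1]
    # distance from pixel centers to the segment
    vx <- x2 - x1; vy <- y2 - y1
    L2 <- vx^2 + vy^2
    tx <- outer(rep(1, length(yg)), xg - x1)
    ty <- outer(yg - y1, rep(1, length(xg)))
    tt <- pmin(pmax((tx * vx + ty * vy) / L2, 0), 1)
    d2 <- (tx - tt * vx)^2 + (ty - tt * vy)^2
    hit <- d2 <= hw^2
    if (any(hit)) {
      blk <- img[r0:r1, c0:c1, drop = FALSE]
      blk[hit] <- blk[hit] + level
      img[r0:r1, c0:c1] <- blk
    }
  }
  img
}

add_arc <- function(img, xs, ys, cx, cy, r, frac, theta0, thickness_um,
                    assoc_um, level) {
  if (frac <= 0) return(img)
  if (frac >= 1) {
    span <- 2 * pi
  } else {
    span <- 2 * pi * frac - 2 * assoc_um / r
    if (span <= 0) return(img)
  }
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  ring <- d2 >= r^2 & d2 <= (r + thickness_um)^2
  if (span < 2 * pi) {
    angle <- outer(ys - cy, xs - cx, function(dy, dx) atan2(dy, dx))
    mid <- theta0 + span / 2
    dd <- (angle - mid) %% (2 * pi)
    dd <- pmin(dd, 2 * pi - dd)
    ring <- ring & dd <= span / 2
  }
  img[ring] <- pmax(img[ring], level)
  img
}
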