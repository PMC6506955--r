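# Shared fixture builders. Everything is generated in code; tests never read
# files that are not written by the test itself.

# render a disk of given radius (um) at an intensity level on a background
disk_image <- function(h_px, w_px, cx_um, cy_um, r_um, pixel_size_um,
                       level = 100, background = 0) {
  xs <- (seq_len(w_px) - 0.5) * pixel_size_um
  ys <- (seq_len(h_px) - 0.5) * pixel_size_um
  img <- matrix(background, h_px, w_px)
  img[outer((ys - cy_um)^2, (xs - cx_um)^2, "+") <= r_um^2] <- level
  img
}

disk_mask_px <- function(h_px, w_px, cx_um, cy_um, r_um, pixel_size_um) {
  disk_image(h_px, w_px, cx_um, cy_um, r_um, pixel_size_um, 1, 0) > 0
}

# independent brute-force oracle: Euclidean distance from every pixel to the
# nearest TRUE pixel of a mask
brute_force_distance <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nrow(mask), ncol(mask))
  if (!nrow(idx)) return(out)
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      out[i, j] <- sqrt(min((idx[, 1] - i)^2 + (idx[, 2] - j)^2))
    }
  }
  out
}

# plaque_labelmap wrapper around a hand-built label matrix
fake_labelmap <- function(labels, pixel_size_um, image_id = "test") {
  structure(list(labels = labels, border_labels = integer(0),
                 pixel_size_um = pixel_size_um, image_id = image_id,
                 params_used = list()),
            class = "plaque_labelmap")
}

# spec for plain disk-plaque scenes: uniform bright disks, nothing else
disk_scene_spec <- function(count, meanlog = log(5), sdlog = 0.2,
                            fov = c(256, 256), seed = 1) {
  noise_free(scene_spec(
    fov_um = fov, pixel_size_um = 0.5,
    plaques = list(count = as.integer(count), radius_meanlog = meanlog,
                   radius_sdlog = sdlog,
                   class_mix = c(dense_core = 1, fibrillar = 0, mixed = 0)),
    gfap = list(filament_density_per_100um2 = 0),
    microglia = list(density_per_mm2 = 0, coverage_range = c(0, 0)),
    neurons = list(density_per_mm2 = 0),
    dystrophies = list(count_range = c(0L, 0L)),
    vessels = list(count = 0L),
    seed = seed))
}

# config with smoothing off: raw-threshold morphometry of sharp renders
sharp_config <- function(...) run_config(blur_radius_um = 0, ...)

# match measured plaques to truth rows by centroid
match_truth_plaque <- function(rec_row, truth, pixel_size_um) {
  which.min((truth$cx_um - rec_row$centroid_x * pixel_size_um)^2 +
              (truth$cy_um - rec_row$centroid_y * pixel_size_um)^2)
}
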