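# Shared low-level image helpers. Images are plain numeric matrices indexed
# [row, col]; masks are logical matrices; label maps are integer matrices
# with 0 = background.

#' Threshold an intensity image
#'
#' Applies one of the supported thresholding rules and returns the foreground
#' mask (pixels strictly above the threshold).
#'
#' \describe{
#'   \item{otsu}{Otsu's method on a 256-bin histogram of the min-max
#'     normalized image, so the result is invariant under positive rescaling
#'     of the intensities.}
#'   \item{fixed_percentile}{Threshold at the given percentile of the image.}
#'   \item{fixed_value}{Threshold at the given absolute intensity.}
#' }
#'
#' @param img Numeric matrix of non-negative intensities.
#' @param spec List with \code{method} and, for the fixed methods,
#'   \code{value}.
#' @return Logical matrix, TRUE = foreground.
#' @export
threshold_image <- function(img, spec = list(method = "otsu")) {
  check_image(img)
  thr <- switch(spec$method,
    otsu = {
      rng <- range(img)
      if (rng[1] == rng[2]) {
        rng[2]  # constant image: nothing strictly above => empty mask
      } else {
        norm <- (img - rng[1]) / (rng[2] - rng[1])
        t01 <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
        rng[1] + t01 * (rng[2] - rng[1])
      }
    },
    fixed_percentile = stats::quantile(img, spec$value / 100, names = FALSE),
    fixed_value = spec$value,
    stop("unknown threshold method: ", spec$method)
  )
  structure(img > thr, threshold = thr)
}

check_image <- function(img, name = deparse(substitute(img))) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(name, " must be a numeric matrix")
  }
  if (!all(is.finite(img))) stop(name, " contains non-finite pixels")
  invisible(img)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop("images are not co-registered: shapes ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  }
  invisible(TRUE)
}

#' Label connected components with 8-connectivity
#'
#' Components are 8-connected (diagonal contact joins objects, matching the
#' usual particle-analysis convention). Labels are renumbered 1..n in
#' column-major scan order of each component's first pixel, so labelling is
#' deterministic.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of labels, 0 = background.
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)  # 4-connected
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  n <- max(lab)
  if (n == 0L) return(lab)
  # union labels that touch diagonally
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  H <- nrow(lab); W <- ncol(lab)
  if (H > 1L && W > 1L) {
    a1 <- lab[-H, -W]; b1 <- lab[-1, -1]   # down-right diagonal
    a2 <- lab[-1, -W]; b2 <- lab[-H, -1]   # up-right diagonal
    pairs <- rbind(
      cbind(as.vector(a1), as.vector(b1)),
      cbind(as.vector(a2), as.vector(b2))
    )
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      pairs <- unique(pairs)
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lab[lab > 0L] <- roots[lab[lab > 0L]]
  relabel_raster_order(lab)
}

# renumber nonzero labels 1..n by column-major position of first occurrence
relabel_raster_order <- function(lab) {
  nz <- which(lab > 0L)
  if (!length(nz)) return(lab)
  first <- tapply(nz, lab[nz], min)
  old <- as.integer(names(first))[order(first)]
  map <- integer(max(lab))
  map[old] <- seq_along(old)
  lab[nz] <- map[lab[nz]]
  lab
}

#' Exact Euclidean distance (in pixels) from every pixel to a mask
#'
#' @param mask Logical matrix; distance is measured to the TRUE set.
#' @return Numeric matrix of distances; pixels of the mask itself are 0. If
#'   the mask is empty, all distances are Inf.
#' @export
distance_to_mask <- function(mask) {
  if (!any(mask)) {
    return(matrix(Inf, nrow(mask), ncol(mask)))
  }
  inv <- matrix(as.numeric(!mask), nrow(mask), ncol(mask))
  d <- EBImage::distmap(inv, metric = "euclidean")
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

# boundary pixels of a mask: mask pixels 8-exposed to background (erosion by
# a 3x3 box); image border counts as exposure
boundary_mask <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  er <- EBImage::erode(m, EBImage::makeBrush(3, shape = "box"))
  padded_interior <- matrix(FALSE, nrow(mask), ncol(mask))
  if (nrow(mask) > 2 && ncol(mask) > 2) {
    padded_interior[2:(nrow(mask) - 1), 2:(ncol(mask) - 1)] <- TRUE
  }
  mask & !(er > 0.5 & padded_interior)
}

# disc brush with odd diameter covering radius_um
disc_brush <- function(radius_um, pixel_size_um) {
  r <- um_to_px(radius_um, pixel_size_um)
  EBImage::makeBrush(2L * r + 1L, shape = "disc")
}

# per-label pixel counts, ordered by label 1..max
label_areas_px <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(integer(0))
  tabulate(lab[lab > 0L], nbins = n)
}

# keep only labels whose index is in `keep`, renumbering in raster order
filter_labels <- function(lab, keep) {
  n <- max(lab)
  if (n == 0L) return(lab)
  map <- integer(n)
  map[keep] <- 1L
  nz <- which(lab > 0L)
  drop <- nz[map[lab[nz]] == 0L]
  lab[drop] <- 0L
  relabel_raster_order(lab)
}

# Gaussian smoothing with sigma in um; sigma 0 returns the image unchanged
gaussian_blur_um <- function(img, sigma_um, pixel_size_um) {
  if (sigma_um <= 0) return(img)
  sigma_px <- sigma_um / pixel_size_um
  g <- EBImage::gblur(EBImage::Image(img), sigma = sigma_px)
  matrix(as.numeric(g), nrow(img), ncol(img))
}
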