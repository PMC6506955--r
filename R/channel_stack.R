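# Multi-channel image container and TIFF/OME-TIFF I/O.

CHANNEL_NAMES <- c("abeta", "thios", "gfap", "iba1", "neun", "syp", "aqp4")

#' Construct a co-registered multi-channel image stack
#'
#' The unit of analysis: a named set of 2D intensity images sharing one
#' physical pixel size. Any subset of the recognized channels
#' (\code{abeta, thios, gfap, iba1, neun, syp, aqp4}) may be present.
#'
#' @param channels Named list of numeric matrices, all the same size.
#' @param pixel_size_um Micrometres per pixel (isotropic, > 0).
#' @param image_id,animal_id,condition Metadata strings carried into all
#'   output tables.
#' @return An object of class \code{channel_stack}.
#' @export
channel_stack <- function(channels, pixel_size_um, image_id = "image",
                          animal_id = "animal", condition = "") {
  if (!length(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("channels must be a non-empty named list")
  }
  bad <- setdiff(names(channels), CHANNEL_NAMES)
  if (length(bad)) {
    stop("unknown channel name(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(CHANNEL_NAMES, collapse = ", "), ")")
  }
  dims <- lapply(channels, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("all channel images must share the same height x width")
  }
  for (nm in names(channels)) {
    check_image(channels[[nm]], nm)
    if (any(channels[[nm]] < 0)) {
      stop("channel '", nm, "' has negative intensities")
    }
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um,
         image_id = image_id, animal_id = animal_id, condition = condition),
    class = "channel_stack"
  )
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("channel_stack '", x$image_id, "' (", x$animal_id,
      if (nzchar(x$condition)) paste0(", ", x$condition), ")\n",
      "  ", d[1], " x ", d[2], " px @ ", x$pixel_size_um, " um/px\n",
      "  channels: ", paste(names(x$channels), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Load a channel stack from a (OME-)TIFF file
#'
#' Reads a single- or multi-page grayscale TIFF and assembles the named
#' channels. The physical pixel size is taken from OME-XML metadata
#' (\code{PhysicalSizeX}) in the ImageDescription when present; otherwise the
#' explicit override is required. Pixel size is never guessed: every
#' downstream parameter is in micrometres, so running uncalibrated would
#' silently produce wrong-unit results.
#'
#' @param path TIFF file path.
#' @param channel_map Named integer vector or list mapping channel names to
#'   1-based page indices, e.g. \code{c(abeta = 1, gfap = 2)}.
#' @param pixel_size_um Optional pixel-size override (um per pixel).
#' @param image_id,animal_id,condition Metadata; \code{image_id} defaults to
#'   the file name without extension.
#' @return A \code{\link{channel_stack}}.
#' @export
load_channel_stack <- function(path, channel_map, pixel_size_um = NULL,
                               image_id = NULL, animal_id = "animal",
                               condition = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_px <- ome_pixel_size(pages)
  px <- if (!is.null(pixel_size_um)) pixel_size_um else meta_px
  if (is.null(px)) {
    stop("calibration error: ", path, " carries no OME PhysicalSizeX and no ",
         "pixel_size_um override was given")
  }
  idx <- unlist(channel_map)
  if (any(idx < 1L) || any(idx > length(pages))) {
    stop("channel_map indexes page(s) beyond the ", length(pages),
         " page(s) in ", path)
  }
  chans <- lapply(idx, function(i) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # gray stored with 1 sample
    storage.mode(pg) <- "double"
    unname_attrs(pg)
  })
  names(chans) <- names(channel_map)
  if (is.null(image_id)) {
    image_id <- tools::file_path_sans_ext(basename(path))
  }
  channel_stack(chans, px, image_id = image_id, animal_id = animal_id,
                condition = condition)
}

unname_attrs <- function(m) {
  matrix(as.numeric(m), nrow(m), ncol(m))
}

# pull PhysicalSizeX="..." from any page's ImageDescription
ome_pixel_size <- function(pages) {
  for (pg in pages) {
    desc <- attr(pg, "description")
    if (is.null(desc)) next
    m <- regmatches(desc,
                    regexec("PhysicalSizeX=\"([0-9.eE+-]+)\"", desc))[[1]]
    if (length(m) == 2L) {
      v <- suppressWarnings(as.numeric(m[2]))
      if (is.finite(v) && v > 0) return(v)
    }
  }
  NULL
}

#' Write a channel stack as a multi-page OME-TIFF
#'
#' One grayscale 16-bit page per channel (in the order of
#' \code{names(stack$channels)}), with a minimal OME-XML ImageDescription on
#' the first page recording channel names and the physical pixel size, so
#' \code{\link{load_channel_stack}} round-trips the calibration without an
#' override. Intensities are rounded to integers and clipped to [0, 65535].
#'
#' @param stack A \code{\link{channel_stack}}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_channel_stack <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  imgs <- lapply(stack$channels, function(ch) {
    v <- round(ch)
    v[v < 0] <- 0
    v[v > 65535] <- 65535
    v
  })
  desc <- ome_description(stack)
  write_tiff16(imgs, path, description = desc)
  invisible(path)
}

ome_description <- function(stack) {
  d <- dim(stack$channels[[1]])
  ch <- paste0(
    vapply(names(stack$channels),
           function(nm) sprintf('<Channel ID="Channel:0:%d" Name="%s"/>',
                                match(nm, names(stack$channels)) - 1L, nm),
           character(1)),
    collapse = "")
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    sprintf('<Image ID="Image:0" Name="%s">', stack$image_id),
    sprintf(paste0('<Pixels ID="Pixels:0" DimensionOrder="XYCZT" Type="uint16" ',
                   'SizeX="%d" SizeY="%d" SizeC="%d" SizeZ="1" SizeT="1" ',
                   'PhysicalSizeX="%.10g" PhysicalSizeY="%.10g">'),
            d[2], d[1], length(stack$channels),
            stack$pixel_size_um, stack$pixel_size_um),
    ch, "</Pixels></Image></OME>")
}

# Minimal multi-page 16-bit grayscale uncompressed little-endian TIFF writer.
# Exists because the 'tiff' package cannot write an ImageDescription tag,
# which is where OME-TIFF keeps the physical pixel size.
write_tiff16 <- function(imgs, path, description = NULL) {
  stopifnot(is.list(imgs), length(imgs) >= 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  npage <- length(imgs)
  sizes <- lapply(imgs, dim)
  nbytes <- vapply(sizes, function(d) 2L * d[1] * d[2], integer(1))
  desc_raw <- if (!is.null(description)) {
    c(charToRaw(description), as.raw(0L))  # ASCII tag includes one NUL
  } else raw(0)
  desc_count <- length(desc_raw)
  if (desc_count %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))  # pad only

  # layout: 8-byte header | pixel data blocks | description | IFDs
  data_off <- cumsum(c(8L, nbytes))
  desc_off <- data_off[npage + 1L]
  ifd_start <- desc_off + length(desc_raw)
  n_entries <- function(i) if (i == 1L && length(desc_raw)) 11L else 10L
  ifd_size <- function(i) 2L + 12L * n_entries(i) + 4L
  ifd_off <- ifd_start + cumsum(c(0L, vapply(seq_len(npage), ifd_size,
                                             integer(1))))[seq_len(npage)]

  # header
  writeBin(charToRaw("II"), con)
  w2(42L); w4(ifd_off[1])
  # pixel data (unsigned 16-bit via two's complement for writeBin)
  for (img in imgs) {
    v <- as.integer(t(img))  # TIFF rows are image rows
    v[v > 32767L] <- v[v > 32767L] - 65536L
    writeBin(v, con, size = 2, endian = "little")
  }
  if (length(desc_raw)) writeBin(desc_raw, con)
  # IFDs
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3L && count == 1L) { w2(value); w2(0L) } else w4(value)
  }
  for (i in seq_len(npage)) {
    d <- sizes[[i]]
    with_desc <- i == 1L && length(desc_raw) > 0L
    w2(n_entries(i))
    entry(256L, 4L, 1L, d[2])            # ImageWidth
    entry(257L, 4L, 1L, d[1])            # ImageLength
    entry(258L, 3L, 1L, 16L)             # BitsPerSample
    entry(259L, 3L, 1L, 1L)              # Compression = none
    entry(262L, 3L, 1L, 1L)              # Photometric = BlackIsZero
    if (with_desc) entry(270L, 2L, desc_count, desc_off)
    entry(273L, 4L, 1L, data_off[i])     # StripOffsets
    entry(277L, 3L, 1L, 1L)              # SamplesPerPixel
    entry(278L, 4L, 1L, d[1])            # RowsPerStrip
    entry(279L, 4L, 1L, nbytes[i])       # StripByteCounts
    entry(339L, 3L, 1L, 1L)              # SampleFormat = unsigned
    w4(if (i < npage) ifd_off[i + 1L] else 0L)
  }
  invisible(path)
}
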