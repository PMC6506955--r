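# Tabular and label-mask output.

#' Write a measurement table as CSV
#'
#' Writes one row per record with a header, numbers at full precision, and a
#' deterministic row order (sorted by \code{image_id} then \code{label} when
#' those columns exist), so identical inputs produce byte-identical files.
#'
#' @param records A data.frame of per-plaque, per-neuron or per-mouse rows.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_measurements <- function(records, path) {
  if (!is.data.frame(records) || ncol(records) == 0L) {
    stop("records must be a data.frame with at least one column")
  }
  ord <- seq_len(nrow(records))
  keys <- intersect(c("image_id", "label"), names(records))
  if (length(keys)) {
    ord <- do.call(order, records[keys])
  }
  out <- records[ord, , drop = FALSE]
  con <- tryCatch(file(path, "wb"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  utils::write.csv(format_full_precision(out), con, row.names = FALSE,
                   quote = TRUE, eol = "\n")
  invisible(path)
}

format_full_precision <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(v) {
        if (is.na(v)) NA_character_ else format(v, digits = 17)
      }, character(1))
    }
  }
  df
}

#' Write / read a label mask as TIFF
#'
#' Label maps (0 = background, positive integers = objects) are stored as
#' single-page grayscale TIFF: 16-bit when the largest label fits, 32-bit
#' float otherwise (lossless for labels below 2^24). \code{read_label_mask}
#' inverts the encoding exactly.
#'
#' @param labelmap Integer matrix of non-negative labels.
#' @param path TIFF path.
#' @return \code{write_label_mask}: the path, invisibly;
#'   \code{read_label_mask}: an integer matrix.
#' @export
write_label_mask <- function(labelmap, path) {
  if (!is.matrix(labelmap) || !is.numeric(labelmap)) {
    stop("labelmap must be a numeric matrix")
  }
  if (any(!is.finite(labelmap)) || any(labelmap < 0) ||
      any(labelmap != round(labelmap))) {
    stop("labelmap must contain non-negative integers")
  }
  mx <- max(labelmap)
  if (mx <= 65535) {
    tiff::writeTIFF(labelmap / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  } else if (mx < 2^24) {
    tiff::writeTIFF(labelmap / (2^32 - 1), path, bits.per.sample = 32L,
                    compression = "none")
  } else {
    stop("label maps with labels >= 2^24 are not supported")
  }
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  out <- matrix(as.integer(round(m)), nrow(m), ncol(m))
  out
}
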