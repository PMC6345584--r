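#' Pixel image container
#'
#' A thin wrapper around a numeric matrix of intensities with optional
#' pixel-size metadata.  This is the atom consumed by every imaging
#' operation in the package.  Coordinates are 0-based `(row, col)`
#' throughout, matching the convention of the segmentation outputs.
#'
#' @param values numeric matrix of non-negative, finite intensities.
#' @param pixel_size physical pixel size in micrometres per pixel, or
#'   `NA` when unknown (areas are then reported in pixels only).
#' @param frame_index optional integer frame index for time series.
#' @param channel_name optional channel label.
#' @return An object of class `pixel_image` (a matrix with attributes).
#' @examples
#' img <- pixel_image(matrix(runif(64), 8, 8), pixel_size = 0.1)
#' dim(img)
#' @export
pixel_image <- function(values, pixel_size = NA_real_, frame_index = NA_integer_,
                        channel_name = "") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("image intensities must all be finite", call. = FALSE)
  }
  structure(values,
            pixel_size = as.numeric(pixel_size),
            frame_index = as.integer(frame_index),
            channel_name = as.character(channel_name),
            class = c("pixel_image", "matrix", "array"))
}

#' @export
print.pixel_image <- function(x, ...) {
  ps <- attr(x, "pixel_size")
  cat(sprintf("<pixel_image> %d x %d px", nrow(x), ncol(x)))
  if (!is.na(ps)) cat(sprintf(", %.4g um/px", ps))
  ch <- attr(x, "channel_name")
  if (nzchar(ch)) cat(sprintf(", channel '%s'", ch))
  cat(sprintf("\n  intensity range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

# Strip attributes down to a plain matrix (internal).
as_matrix <- function(x) {
  if (inherits(x, "pixel_image")) {
    attributes(x) <- list(dim = dim(x))
  }
  as.matrix(x)
}

#' Region-of-interest mask
#'
#' A boolean raster aligned to a [pixel_image()], tagged with the kind of
#' region it represents (whole cell, membrane band, leading-edge line, or
#' custom).
#'
#' @param mask logical matrix, `TRUE` inside the region.
#' @param kind one of `"whole_cell"`, `"membrane_band"`,
#'   `"leading_edge_line"`, `"custom"`.
#' @param band_width band width in pixels, for band/line kinds.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(mask, kind = c("custom", "whole_cell", "membrane_band",
                                       "leading_edge_line"),
                        band_width = NA_real_) {
  kind <- match.arg(kind)
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("`mask` must be a logical matrix", call. = FALSE)
  }
  structure(mask, kind = kind, band_width = as.numeric(band_width),
            class = c("region_mask", "matrix", "array"))
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> kind '%s', %d x %d px, %d pixels in region\n",
              attr(x, "kind"), nrow(x), ncol(x), sum(x)))
  invisible(x)
}
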