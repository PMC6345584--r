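# Colocalization and intensity quantification: Pearson correlation over
# ROIs, object-pixel overlap between segmented channels, surface/total
# receptor levels, and flow-cytometry background subtraction.

#' Pearson colocalization within a region of interest
#'
#' Standard Pearson correlation of paired pixel intensities inside the
#' ROI, computed on raw intensities with no thresholding.  This is the
#' headline statistic of ROI-based colocalization analysis; it is
#' invariant to independent affine rescaling (positive gain) of either
#' channel.
#'
#' @param img_a,img_b [pixel_image()]s or matrices of identical shape.
#' @param roi a [region_mask()] (or logical matrix) of the same shape;
#'   defaults to the whole image.
#' @return list with `pearson_r`, `n_pixels`, `roi_kind`.
#' @examples
#' a <- matrix(runif(100), 10, 10)
#' pearson_coloc(a, 2 * a + 1)$pearson_r  # exactly 1
#' @export
pearson_coloc <- function(img_a, img_b, roi = NULL) {
  a <- as_matrix(img_a); b <- as_matrix(img_b)
  if (!all(dim(a) == dim(b))) stop("channel shapes differ", call. = FALSE)
  if (is.null(roi)) roi <- region_mask(matrix(TRUE, nrow(a), ncol(a)),
                                       kind = "whole_cell")
  kind <- if (inherits(roi, "region_mask")) attr(roi, "kind") else "custom"
  m <- as.logical(roi)
  dim(m) <- dim(a)
  if (!all(dim(m) == dim(a))) stop("ROI shape differs from images", call. = FALSE)
  va <- a[m]; vb <- b[m]
  if (length(va) < 2L) stop("ROI must contain at least 2 pixels", call. = FALSE)
  if (stats::var(va) == 0 || stats::var(vb) == 0) {
    deg <- if (stats::var(va) == 0) "A" else "B"
    stop(sprintf("Pearson undefined: channel %s has zero variance inside the ROI",
                 deg), call. = FALSE)
  }
  list(pearson_r = stats::cor(va, vb), n_pixels = length(va), roi_kind = kind)
}

#' Leading-edge line ROI
#'
#' Rasterizes a fixed-width band around a polyline, the "n pixels wide
#' line along the leading edge" ROI: a pixel belongs to the mask when its
#' center lies within `width / 2` (Euclidean) of the path.
#'
#' @param path m x 2 matrix of ordered 0-based (row, col) vertices, m >= 2.
#' @param width band width in pixels (default 10).
#' @param shape image dimensions `c(rows, cols)`.
#' @return A [region_mask()] of kind `leading_edge_line`.
#' @export
leading_edge_roi <- function(path, width = 10, shape) {
  path <- matrix(as.numeric(path), ncol = 2)
  if (nrow(path) < 2L) {
    stop("`path` needs at least 2 vertices (a single point is degenerate)",
         call. = FALSE)
  }
  if (width < 1) stop("`width` must be >= 1", call. = FALSE)
  shape <- as.integer(shape)
  if (any(path[, 1] < 0) || any(path[, 1] > shape[1] - 1) ||
      any(path[, 2] < 0) || any(path[, 2] > shape[2] - 1)) {
    stop("path vertices must lie inside the image bounds", call. = FALSE)
  }
  pr <- matrix(rep(seq_len(shape[1]) - 1, shape[2]), shape[1], shape[2])
  pc <- matrix(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[1], shape[2])
  d2 <- matrix(Inf, shape[1], shape[2])
  for (s in seq_len(nrow(path) - 1L)) {
    p <- path[s, ]; q <- path[s + 1L, ]
    v <- q - p
    len2 <- sum(v^2)
    if (len2 == 0) {
      d2s <- (pr - p[1])^2 + (pc - p[2])^2
    } else {
      t <- ((pr - p[1]) * v[1] + (pc - p[2]) * v[2]) / len2
      t <- pmin(pmax(t, 0), 1)
      d2s <- (pr - (p[1] + t * v[1]))^2 + (pc - (p[2] + t * v[2]))^2
    }
    d2 <- pmin(d2, d2s)
  }
  region_mask(d2 <= (width / 2)^2, kind = "leading_edge_line",
              band_width = width)
}

#' Membrane band from a cell mask
#'
#' The band is the cell mask minus its inward erosion by `width` pixels
#' (box structuring element of half-width `width`, i.e. Chebyshev
#' distance), operationalizing "surface" receptor levels as the outermost
#' `width`-pixel rim of the cell.
#'
#' @param cell_mask a [region_mask()] or logical matrix, non-empty.
#' @param width band width in pixels (>= 1; default 3).
#' @return A [region_mask()] of kind `membrane_band`.
#' @export
membrane_band <- function(cell_mask, width = 3) {
  m <- as.logical(cell_mask)
  dim(m) <- dim(cell_mask)
  if (!any(m)) stop("cell mask is empty", call. = FALSE)
  if (width < 1) stop("`width` must be >= 1", call. = FALSE)
  brush <- EBImage::makeBrush(2L * as.integer(width) + 1L, shape = "box")
  eroded <- EBImage::erode(m * 1, brush) > 0.5
  eroded <- matrix(eroded, nrow(m), ncol(m))
  if (!any(eroded)) {
    stop("erosion empties the mask: cell is thinner than the requested band",
         call. = FALSE)
  }
  region_mask(m & !eroded, kind = "membrane_band", band_width = width)
}

#' Total and surface intensity levels per cell
#'
#' Mean intensity per unit cell area over the whole-cell mask (total) and
#' over the membrane band (surface), optionally normalized to
#' control-group means, matching the convention of reporting receptor
#' levels relative to control cells in the same sample set.
#'
#' @param image a [pixel_image()] or matrix.
#' @param cell_mask whole-cell [region_mask()].
#' @param band membrane-band [region_mask()]; must be a subset of
#'   `cell_mask`.
#' @param control_means optional numeric `c(total, surface)` control
#'   means (> 0) used for normalization.
#' @return list with `total_mean`, `surface_mean`, and (when controls are
#'   given) `normalized_total`, `normalized_surface`.
#' @export
intensity_levels <- function(image, cell_mask, band, control_means = NULL) {
  x <- as_matrix(image)
  cm <- as.logical(cell_mask); dim(cm) <- dim(x)
  bm <- as.logical(band); dim(bm) <- dim(x)
  if (!any(cm) || !any(bm)) stop("masks must be non-empty", call. = FALSE)
  if (any(bm & !cm)) {
    stop("band must be a subset of the cell mask", call. = FALSE)
  }
  out <- list(total_mean = mean(x[cm]), surface_mean = mean(x[bm]))
  if (!is.null(control_means)) {
    if (any(control_means <= 0)) {
      stop("control means must be > 0 for normalization", call. = FALSE)
    }
    out$normalized_total <- out$total_mean / control_means[1]
    out$normalized_surface <- out$surface_mean / control_means[2]
  }
  out
}

#' Object-pixel overlap between two segmented channels
#'
#' Asymmetric overlap of channel-A vesicle pixels with channel-B vesicle
#' pixels: `|A-pixels inside B-pixels| / |A-pixels|`, plus the same
#' fraction per A vesicle.  Channel B acts as the reference compartment
#' (e.g. the lysosome channel).
#'
#' @param vesicles_a,vesicles_b `vesicle_set` objects ([detect_vesicles()])
#'   with label maps of identical shape.
#' @return list with `overlap_fraction`, `n_vesicles_a`, `per_vesicle`
#'   (named numeric, one fraction per A label).
#' @export
vesicle_overlap <- function(vesicles_a, vesicles_b) {
  stopifnot(inherits(vesicles_a, "vesicle_set"),
            inherits(vesicles_b, "vesicle_set"))
  la <- vesicles_a$label_map; lb <- vesicles_b$label_map
  if (!all(dim(la) == dim(lb))) stop("label map shapes differ", call. = FALSE)
  sel <- la > 0L
  if (!any(sel)) {
    stop("overlap undefined: channel A has no labeled pixels", call. = FALSE)
  }
  inside <- lb[sel] > 0L
  per <- tapply(inside, la[sel], mean)
  list(overlap_fraction = mean(inside),
       n_vesicles_a = vesicles_a$n_vesicles,
       per_vesicle = per)
}

#' Background-subtracted surface level from flow-cytometry events
#'
#' Subtracts the central fluorescence of a background (e.g. secondary
#' antibody only) event population from that of the sample population,
#' floored at zero.  Arithmetic means by default; medians by flag.
#'
#' @param sample_events,background_events numeric vectors of per-event
#'   fluorescence values, non-empty.
#' @param statistic `"mean"` (default) or `"median"`.
#' @return list with `level` (subtracted, floored at 0), `sample_stat`,
#'   `background_stat`, `n_sample`, `n_background`.
#' @export
facs_surface_level <- function(sample_events, background_events,
                               statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (length(sample_events) == 0L || length(background_events) == 0L) {
    stop("event sets must be non-empty", call. = FALSE)
  }
  f <- if (statistic == "mean") mean else stats::median
  s <- f(sample_events); b <- f(background_events)
  list(level = max(0, s - b), sample_stat = s, background_stat = b,
       n_sample = length(sample_events), n_background = length(background_events))
}
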