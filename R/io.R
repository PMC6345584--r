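# File I/O: TIFF image stacks and the CSV table formats used by the
# pipeline.  Intensities become floating point on read; integer bit
# depth is a storage detail only.

#' Read a grayscale TIFF image stack
#'
#' @param path TIFF file (8- or 16-bit grayscale, single- or multi-page).
#' @param layout how pages map to images: `"single"` (one page),
#'   `"multipage_time"` (pages are frames, indices 0..n-1) or
#'   `"multipage_channel"` (pages are channels "ch1", "ch2", ...).
#' @param pixel_size optional micrometres per pixel recorded on each
#'   image.
#' @return list of [pixel_image()]s.
#' @export
read_image_stack <- function(path, layout = c("single", "multipage_time",
                                              "multipage_channel"),
                             pixel_size = NA_real_) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) {
                      stop(sprintf("cannot read '%s' as TIFF: %s", path,
                                   conditionMessage(e)), call. = FALSE)
                    })
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) != 2L) {
      stop("RGB or multi-sample TIFF not supported; expected grayscale",
           call. = FALSE)
    }
  }
  if (layout == "single" && length(pages) != 1L) {
    stop(sprintf("layout 'single' but file has %d pages", length(pages)),
         call. = FALSE)
  }
  lapply(seq_along(pages), function(i) {
    pixel_image(matrix(as.numeric(pages[[i]]), nrow(pages[[i]])),
                pixel_size = pixel_size,
                frame_index = if (layout == "multipage_time") i - 1L else NA_integer_,
                channel_name = if (layout == "multipage_channel")
                  paste0("ch", i) else "")
  })
}

#' Write images as a 16-bit grayscale TIFF
#'
#' Intensities are clamped to `[0, 65535]` and rounded; compression is
#' disabled so output bytes are reproducible.
#'
#' @param images a single image/matrix or a list (written as pages).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(images, path) {
  if (!is.list(images)) images <- list(images)
  pages <- lapply(images, function(im) {
    x <- as_matrix(im)
    pmin(pmax(round(x), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Write / read a FRAP trace CSV
#'
#' Columns `time_s, roi_intensity, whole_image_intensity`, preceded by a
#' comment header line `# n_prebleach: <n>`.
#'
#' @param trace a [frap_trace()] object.
#' @param path CSV file.
#' @return `write_frap_csv`: `path` invisibly; `read_frap_csv`: a
#'   [frap_trace()].
#' @export
write_frap_csv <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_prebleach: %d", trace$n_prebleach), con)
  utils::write.csv(data.frame(time_s = trace$times,
                              roi_intensity = trace$roi_intensity,
                              whole_image_intensity = trace$whole_image_intensity),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_csv
#' @export
read_frap_csv <- function(path) {
  first <- readLines(path, n = 1L)
  n_pre <- 3L
  if (grepl("^#\\s*n_prebleach:", first)) {
    n_pre <- as.integer(sub("^#\\s*n_prebleach:\\s*", "", first))
  }
  d <- utils::read.csv(path, comment.char = "#")
  frap_trace(d$time_s, d$roi_intensity, d$whole_image_intensity, n_pre)
}

#' Write / read a titration CSV
#'
#' Columns `ligand_conc_M, response`; the target concentration travels in
#' a `# target_conc_M:` comment line.
#'
#' @param series a [titration_series()].
#' @param path CSV file.
#' @return `write_titration_csv`: `path` invisibly; `read_titration_csv`:
#'   a [titration_series()].
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# target_conc_M: %.10g", series$target_conc), con)
  utils::write.csv(data.frame(ligand_conc_M = series$ligand_conc,
                              response = series$response),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration_csv
#' @export
read_titration_csv <- function(path, target_conc = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(target_conc)) {
    if (!grepl("^#\\s*target_conc_M:", first)) {
      stop("CSV lacks a '# target_conc_M:' header; pass `target_conc`",
           call. = FALSE)
    }
    target_conc <- as.numeric(sub("^#\\s*target_conc_M:\\s*", "", first))
  }
  d <- utils::read.csv(path, comment.char = "#")
  titration_series(d$ligand_conc_M, d$response, target_conc)
}

#' Write / read a decay-histogram CSV (columns `time_ns, counts`)
#'
#' @param decay a [decay_histogram()].
#' @param path CSV file.
#' @return `write_decay_csv`: `path` invisibly; `read_decay_csv`: a
#'   [decay_histogram()].
#' @export
write_decay_csv <- function(decay, path) {
  stopifnot(inherits(decay, "decay_histogram"))
  utils::write.csv(data.frame(time_ns = decay$bin_centers,
                              counts = decay$counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decay_csv
#' @export
read_decay_csv <- function(path) {
  d <- utils::read.csv(path)
  decay_histogram(d$time_ns, d$counts)
}

#' Write / read migration tracks CSV
#'
#' Long format, columns `cell_id, frame, x, y`; frame interval and pixel
#' size travel in comment header lines.
#'
#' @param tracks list of [track()] objects.
#' @param path CSV file.
#' @return `write_tracks_csv`: `path` invisibly; `read_tracks_csv`: list
#'   of [track()]s.
#' @export
write_tracks_csv <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# frame_interval_min: %.10g", tracks[[1]]$frame_interval),
               sprintf("# pixel_size_um: %.10g", tracks[[1]]$pixel_size)), con)
  rows <- do.call(rbind, lapply(tracks, function(t) {
    data.frame(cell_id = t$cell_id, frame = t$frames,
               x = t$positions[, 1], y = t$positions[, 2])
  }))
  utils::write.csv(rows, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path, frame_interval = NULL, pixel_size = NULL) {
  hdr <- readLines(path, n = 2L)
  get_num <- function(key, default) {
    ln <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(ln)) as.numeric(sub(paste0("^#\\s*", key, ":\\s*"), "", ln[1]))
    else default
  }
  if (is.null(frame_interval)) frame_interval <- get_num("frame_interval_min", 10)
  if (is.null(pixel_size)) pixel_size <- get_num("pixel_size_um", 1)
  d <- utils::read.csv(path, comment.char = "#")
  lapply(split(d, d$cell_id), function(g) {
    g <- g[order(g$frame), ]
    track(g$cell_id[1], g$frame, cbind(g$x, g$y), frame_interval, pixel_size)
  })
}

#' Write a per-vesicle statistics CSV
#'
#' Columns `frame,label,area_px,area_um2,centroid_row,centroid_col,
#' mean_intensity,total_intensity`.
#'
#' @param vesicles a `vesicle_set`.
#' @param path CSV file.
#' @return `path`, invisibly.
#' @export
write_vesicles_csv <- function(vesicles, path) {
  stopifnot(inherits(vesicles, "vesicle_set"))
  s <- vesicles$stats
  utils::write.csv(data.frame(frame = s$frame_index, label = s$label,
                              area_px = s$area_px, area_um2 = s$area_um2,
                              centroid_row = s$centroid_row,
                              centroid_col = s$centroid_col,
                              mean_intensity = s$mean_intensity,
                              total_intensity = s$total_intensity),
                   path, row.names = FALSE)
  invisible(path)
}
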