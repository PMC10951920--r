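#' Read a track table from CSV
#'
#' Expects the canonical dialect `track_id,frame,x_um,y_um,intensity`
#' (comma-separated, '.' decimal, UTF-8). Coordinates are stored in
#' micrometres so downstream physical-unit computations (diffusion in
#' um^2/s, precision in nm) need no pixel-size bookkeeping. Rows are grouped
#' by `track_id` and sorted by frame.
#'
#' @param path CSV file path.
#' @param frame_interval seconds between frames (default 0.03).
#' @param pixel_size micrometres per pixel (metadata only; coordinates in the
#'   file are already micrometres).
#' @param cell_id,stage optional metadata labels.
#' @return a [trackset()].
#' @export
read_tracks_csv <- function(path, frame_interval = 0.03,
                            pixel_size = NA_real_,
                            cell_id = "cell", stage = NA_character_) {
  if (!file.exists(path))
    stop_gliotrack(paste0("file not found: ", path), "gliotrack_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("track_id", "frame", "x_um", "y_um")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_gliotrack(paste0("track CSV missing column(s): ",
                          paste(missing_cols, collapse = ", ")),
                   "gliotrack_format_error")
  if (nrow(df)) {
    bad <- !is.finite(suppressWarnings(as.numeric(df$x_um))) |
      !is.finite(suppressWarnings(as.numeric(df$y_um))) |
      !is.finite(suppressWarnings(as.numeric(df$frame)))
    if (any(bad))
      stop_gliotrack(sprintf("%d malformed row(s) in %s", sum(bad), path),
                     "gliotrack_format_error")
  }
  trackset(df, frame_interval = frame_interval, pixel_size = pixel_size,
           cell_id = cell_id, stage = stage)
}

#' Write a track table to CSV
#'
#' Inverse of [read_tracks_csv()]: round-trips a trackset up to float
#' formatting (coordinates written with enough digits that read-back agrees
#' to well below 1e-6 um). Gaps in tracks are preserved as missing frames.
#'
#' @param ts a [trackset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(ts, path) {
  stopifnot(inherits(ts, "trackset"))
  out <- ts$tracks
  out$x_um <- formatC(out$x_um, format = "g", digits = 15)
  out$y_um <- formatC(out$y_um, format = "g", digits = 15)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    stop_gliotrack(paste0("cannot write ", path), "gliotrack_io_error")
  invisible(path)
}

#' Time-lapse image stack
#'
#' `framestack` holds a T x H x W array of 16-bit-range integer intensities
#' plus acquisition metadata.
#'
#' @param data numeric array, dimensions T x H x W, values in [0, 65535].
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds per frame.
#' @return object of class `framestack`.
#' @export
framestack <- function(data, pixel_size = NA_real_, frame_interval = 0.03) {
  if (length(dim(data)) == 2L) dim(data) <- c(1L, dim(data))
  if (length(dim(data)) != 3L)
    stop_gliotrack("stack data must be T x H x W", "gliotrack_validation_error")
  if (any(data < 0) || any(data > 65535))
    stop_gliotrack("intensities must lie in [0, 65535]",
                   "gliotrack_validation_error")
  structure(list(data = data, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "framestack")
}

#' @export
print.framestack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<framestack> %d frame(s) of %d x %d px\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Read a multipage 16-bit grayscale TIFF as a frame stack
#'
#' @param path TIFF file path.
#' @param pixel_size,frame_interval acquisition metadata (TIFF tags are not
#'   relied upon).
#' @return a [framestack()].
#' @export
read_tiff_stack <- function(path, pixel_size = NA_real_,
                            frame_interval = 0.03) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop_gliotrack(paste0("not a readable TIFF: ", path),
                                     "gliotrack_format_error"))
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop_gliotrack("only grayscale TIFF stacks are supported (got a multi-channel image)",
                   "gliotrack_format_error")
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr <- array(0, dim = c(length(pages), h, w))
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]]
  framestack(arr, pixel_size = pixel_size, frame_interval = frame_interval)
}

#' Write a frame stack as a multipage 16-bit grayscale TIFF
#'
#' Integer-lossless round-trip with [read_tiff_stack()].
#'
#' @param stack a [framestack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path) {
  stopifnot(inherits(stack, "framestack"))
  pages <- lapply(seq_len(dim(stack$data)[1]), function(t)
    round(stack$data[t, , ]) / 65535)
  ok <- tryCatch({
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    stop_gliotrack(paste0("cannot write TIFF: ", path), "gliotrack_io_error")
  invisible(path)
}
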