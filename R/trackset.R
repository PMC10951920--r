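#' Track set container
#'
#' A `trackset` bundles the particle trajectories of one imaged cell with its
#' acquisition metadata. Trajectories are stored long-format: one row per
#' localization with columns `track_id`, `frame` (0-based integer), `x_um`,
#' `y_um` (micrometres) and `intensity`. Frames within a track must be
#' strictly increasing; gaps (missing frames) are permitted and are never
#' interpolated, since gap-closing during linking is legitimate but
#' interpolation would bias displacement statistics.
#'
#' @param tracks data.frame with columns `track_id`, `frame`, `x_um`, `y_um`
#'   and optionally `intensity` (defaults to 0).
#' @param frame_interval frame-to-frame time in seconds (default 0.03, i.e.
#'   30 ms exposures).
#' @param pixel_size pixel pitch in micrometres per pixel. There is no
#'   standard default; it must be supplied when converting to/from pixels.
#' @param cell_id identifier of the imaged cell.
#' @param stage free-text maturation stage label (e.g. "OPC", "eOL", "mOL").
#' @param roi optional ROI polygon (see [roi_polygon()]).
#' @return An object of class `trackset`.
#' @examples
#' ts <- trackset(data.frame(track_id = "a", frame = 0:2,
#'                           x_um = c(0, 1, 2), y_um = 0))
#' n_tracks(ts)
#' @export
trackset <- function(tracks, frame_interval = 0.03, pixel_size = NA_real_,
                     cell_id = "cell", stage = NA_character_, roi = NULL) {
  if (!is.data.frame(tracks))
    stop_gliotrack("`tracks` must be a data.frame", "gliotrack_validation_error")
  required <- c("track_id", "frame", "x_um", "y_um")
  missing_cols <- setdiff(required, names(tracks))
  if (length(missing_cols))
    stop_gliotrack(paste0("missing track column(s): ",
                          paste(missing_cols, collapse = ", ")),
                   "gliotrack_format_error")
  if (is.null(tracks$intensity)) tracks$intensity <- 0
  tracks <- tracks[, c(required, "intensity")]
  tracks$track_id <- as.character(tracks$track_id)
  tracks$frame <- as.integer(tracks$frame)
  assert_scalar_num(frame_interval, "frame_interval", 0, strict = TRUE)
  if (!is.na(pixel_size))
    assert_scalar_num(pixel_size, "pixel_size", 0, strict = TRUE)

  if (nrow(tracks)) {
    if (any(tracks$frame < 0L))
      stop_gliotrack("frames must be >= 0", "gliotrack_validation_error")
    if (any(!is.finite(tracks$x_um)) || any(!is.finite(tracks$y_um)))
      stop_gliotrack("coordinates must be finite", "gliotrack_validation_error")
    tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
    rownames(tracks) <- NULL
    dup <- duplicated(tracks[, c("track_id", "frame")])
    if (any(dup))
      stop_gliotrack("duplicate (track_id, frame) pairs", "gliotrack_validation_error")
  }
  structure(list(tracks = tracks,
                 frame_interval = frame_interval,
                 pixel_size = pixel_size,
                 cell_id = cell_id,
                 stage = stage,
                 roi = roi),
            class = "trackset")
}

#' @export
print.trackset <- function(x, ...) {
  cat(sprintf("<trackset> cell '%s'%s: %d tracks, %d localizations, dt = %g s\n",
              x$cell_id,
              if (is.na(x$stage)) "" else paste0(" [", x$stage, "]"),
              n_tracks(x), nrow(x$tracks), x$frame_interval))
  invisible(x)
}

#' Number of tracks in a trackset
#' @param ts a [trackset()].
#' @return integer count.
#' @export
n_tracks <- function(ts) length(unique(ts$tracks$track_id))

#' Split a trackset into per-track coordinate lists
#'
#' Internal-friendly accessor: returns a named list, one element per track,
#' each a list with vectors `frame`, `x`, `y`.
#' @param ts a [trackset()].
#' @return named list keyed by track id.
#' @export
track_list <- function(ts) {
  tr <- ts$tracks
  idx <- split(seq_len(nrow(tr)), tr$track_id)
  lapply(idx, function(i)
    list(frame = tr$frame[i], x = tr$x_um[i], y = tr$y_um[i]))
}

#' ROI polygon
#'
#' Region-of-interest polygon in micrometre coordinates. The polygon is
#' implicitly closed (last vertex connects back to the first).
#'
#' @param x,y vertex coordinates (micrometres), length >= 3.
#' @return matrix of class `roi_polygon` with columns `x`, `y`.
#' @export
roi_polygon <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_gliotrack("a polygon needs >= 3 (x, y) vertices",
                   "gliotrack_validation_error")
  structure(cbind(x = as.numeric(x), y = as.numeric(y)),
            class = c("roi_polygon", "matrix", "array"))
}

# Even-odd point-in-polygon with boundary points counted as inside.
# px, py vectors; poly a 2-column matrix.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    # boundary test: point collinear with edge and within its bounding box
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    seg <- abs(cross) < 1e-12 &
      px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
      py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | seg
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Restrict a trackset to tracks fully inside an ROI polygon
#'
#' Mirrors manual curation of tracks to the cell outline: a track is kept
#' only if every localization lies inside or on the boundary of the polygon
#' (even-odd rule, boundary-inclusive). Idempotent.
#'
#' @param ts a [trackset()].
#' @param polygon an [roi_polygon()].
#' @return a [trackset()] containing the retained tracks (possibly none).
#' @export
clip_to_roi <- function(ts, polygon) {
  stopifnot(inherits(ts, "trackset"))
  if (!inherits(polygon, "roi_polygon"))
    polygon <- roi_polygon(polygon[, 1], polygon[, 2])
  tr <- ts$tracks
  if (!nrow(tr)) return(ts)
  ok <- point_in_polygon(tr$x_um, tr$y_um, polygon)
  keep_ids <- names(which(tapply(ok, tr$track_id, all)))
  out <- ts
  out$tracks <- tr[tr$track_id %in% keep_ids, , drop = FALSE]
  rownames(out$tracks) <- NULL
  out$roi <- polygon
  out
}
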