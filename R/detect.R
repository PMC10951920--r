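#' Spot-detection parameters
#'
#' @param spot_diameter_px expected spot diameter in pixels (default 3, a
#'   diffraction-limited spot on a dark background).
#' @param threshold_factor detection threshold as a multiple of the robust
#'   background SD (default 5).
#' @param subpixel refine maxima by intensity-weighted centroid
#'   (default TRUE).
#' @return object of class `detection_params`.
#' @export
detection_params <- function(spot_diameter_px = 3, threshold_factor = 5,
                             subpixel = TRUE) {
  if (spot_diameter_px < 1)
    stop_gliotrack("spot_diameter_px must be >= 1", "gliotrack_config_error")
  structure(list(spot_diameter_px = spot_diameter_px,
                 threshold_factor = threshold_factor, subpixel = subpixel),
            class = "detection_params")
}

#' Linking parameters
#'
#' @param max_disp_px maximum displacement per frame, pixels.
#' @param max_gap maximum number of consecutive missed frames bridged
#'   (default 1).
#' @param min_frames minimum localizations per retained track (default 10:
#'   tracks shorter than 10 frames are discarded as uninformative).
#' @return object of class `link_params`.
#' @export
link_params <- function(max_disp_px, max_gap = 1L, min_frames = 10L) {
  assert_scalar_num(max_disp_px, "max_disp_px", 0, strict = TRUE)
  if (max_gap < 0) stop_gliotrack("max_gap must be >= 0", "gliotrack_config_error")
  if (min_frames < 2) stop_gliotrack("min_frames must be >= 2", "gliotrack_config_error")
  structure(list(max_disp_px = max_disp_px, max_gap = as.integer(max_gap),
                 min_frames = as.integer(min_frames)),
            class = "link_params")
}

# separable Gaussian smoothing with replicate-edge padding
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth_1d <- function(m) {
    n <- nrow(m)
    pad <- rbind(m[rep(1L, r), , drop = FALSE], m,
                 m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k))
      out <- out + k[i] * pad[i:(i + n - 1L), , drop = FALSE]
    out
  }
  t(smooth_1d(t(smooth_1d(img))))
}

#' Detect spots in a single frame
#'
#' Blob detection for sparse bright spots on a dark background: the frame
#' is band-pass filtered (difference of Gaussians at scales sigma and
#' 2 * sigma, sigma = diameter / 2.355), local maxima of the filtered image
#' are accepted where the raw intensity exceeds the robust background
#' (median) plus `threshold_factor` times the robust SD (1.4826 * MAD), and
#' positions are optionally refined by the background-subtracted
#' intensity-weighted centroid in a window one pixel wider than the spot
#' diameter + 2 (the extra ring keeps off-centre tails inside the window).
#' Deterministic.
#'
#' @param frame 2D numeric matrix (H x W).
#' @param params a [detection_params()].
#' @return data.frame with columns `x`, `y` (pixel units, 0-based image
#'   coordinates: x along columns, y along rows) and `intensity` (raw value
#'   at the maximum). Possibly zero rows.
#' @export
detect_spots <- function(frame, params = detection_params()) {
  stopifnot(is.matrix(frame))
  sigma <- params$spot_diameter_px / 2.355
  bp <- gaussian_smooth(frame, sigma) - gaussian_smooth(frame, 2 * sigma)
  bg <- stats::median(frame)
  rsd <- stats::mad(frame)
  thr <- bg + params$threshold_factor * rsd
  H <- nrow(frame); W <- ncol(frame)
  if (H < 3 || W < 3) return(data.frame(x = numeric(0), y = numeric(0),
                                        intensity = numeric(0)))
  core <- bp[2:(H - 1), 2:(W - 1)]
  ismax <- core >= bp[1:(H - 2), 2:(W - 1)] & core > bp[3:H, 2:(W - 1)] &
    core >= bp[2:(H - 1), 1:(W - 2)] & core > bp[2:(H - 1), 3:W] &
    core >= bp[1:(H - 2), 1:(W - 2)] & core > bp[3:H, 3:W] &
    core >= bp[1:(H - 2), 3:W] & core > bp[3:H, 1:(W - 2)]
  idx <- which(ismax, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(x = numeric(0), y = numeric(0),
                                    intensity = numeric(0)))
  rr <- idx[, 1] + 1L; cc <- idx[, 2] + 1L
  keep <- frame[cbind(rr, cc)] > thr
  rr <- rr[keep]; cc <- cc[keep]
  if (!length(rr)) return(data.frame(x = numeric(0), y = numeric(0),
                                     intensity = numeric(0)))
  xs <- as.numeric(cc - 1L); ys <- as.numeric(rr - 1L)
  if (params$subpixel) {
    hw <- floor((params$spot_diameter_px + 2) / 2) + 1L
    for (i in seq_along(rr)) {
      # intensity-weighted centroid, iteratively recentring the window so
      # the finite window does not compress off-centre positions
      xc <- xs[i]; yc <- ys[i]
      for (it in 1:3) {
        r0 <- max(1L, round(yc) + 1L - hw):min(H, round(yc) + 1L + hw)
        c0 <- max(1L, round(xc) + 1L - hw):min(W, round(xc) + 1L + hw)
        w <- pmax(frame[r0, c0, drop = FALSE] - bg, 0)
        sw <- sum(w)
        if (sw <= 0) break
        xc <- sum(t(w) * (c0 - 1L)) / sw
        yc <- sum(w * (r0 - 1L)) / sw
      }
      xs[i] <- xc; ys[i] <- yc
    }
  }
  ord <- order(ys, xs)
  data.frame(x = xs[ord], y = ys[ord],
             intensity = frame[cbind(rr, cc)][ord])
}

#' Detect spots in every frame of a stack
#'
#' @param stack a [framestack()].
#' @param params a [detection_params()].
#' @return list of per-frame detection data.frames (see [detect_spots()]),
#'   one element per frame.
#' @export
detect_stack <- function(stack, params = detection_params()) {
  stopifnot(inherits(stack, "framestack"))
  lapply(seq_len(dim(stack$data)[1]),
         function(t) detect_spots(stack$data[t, , ], params))
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour linking: for each frame, candidate pairs
#' between live track ends and new detections within
#' `max_disp_px * frame_gap` pixels are sorted by distance (ties broken by
#' lower track then detection index) and assigned greedily so no detection
#' is used twice. Unmatched detections open new tracks; track ends stay
#' live for `max_gap` missed frames, so bridged gaps appear as missing
#' frames in the output. Deterministic.
#'
#' @param detections list of per-frame data.frames with `x`, `y` in pixels
#'   (frame t = element t, 0-based frame index t - 1), as from
#'   [detect_stack()].
#' @param params a [link_params()].
#' @param frame_interval seconds per frame.
#' @param pixel_size micrometres per pixel (converts output to um).
#' @param cell_id metadata label.
#' @return a [trackset()] (unfiltered; apply [filter_tracks()] next).
#' @export
link_spots <- function(detections, params, frame_interval = 0.03,
                       pixel_size = 0.1, cell_id = "cell") {
  stopifnot(inherits(params, "link_params"))
  ends_x <- numeric(0); ends_y <- numeric(0)
  ends_frame <- integer(0); ends_id <- integer(0)
  next_id <- 1L
  rows <- list()
  for (t in seq_along(detections)) {
    det <- detections[[t]]
    f0 <- t - 1L
    live <- which(ends_frame >= f0 - 1L - params$max_gap)
    assigned_det <- integer(0)
    if (length(live) && nrow(det)) {
      cand <- expand.grid(li = seq_along(live), dj = seq_len(nrow(det)))
      ti <- live[cand$li]
      gapf <- f0 - ends_frame[ti]
      d <- sqrt((ends_x[ti] - det$x[cand$dj])^2 +
                  (ends_y[ti] - det$y[cand$dj])^2)
      ok <- d <= params$max_disp_px * gapf
      cand <- cand[ok, , drop = FALSE]; d <- d[ok]; ti <- ti[ok]
      if (nrow(cand)) {
        ord <- order(d, ti, cand$dj)
        used_t <- logical(length(ends_id)); used_d <- logical(nrow(det))
        for (m in ord) {
          i <- ti[m]; j <- cand$dj[m]
          if (used_t[i] || used_d[j]) next
          used_t[i] <- TRUE; used_d[j] <- TRUE
          id <- ends_id[i]
          rows[[length(rows) + 1L]] <-
            c(id, f0, det$x[j], det$y[j], det$intensity[j])
          ends_x[i] <- det$x[j]; ends_y[i] <- det$y[j]; ends_frame[i] <- f0
        }
        assigned_det <- which(used_d)
      }
    }
    new_d <- setdiff(seq_len(nrow(det)), assigned_det)
    for (j in new_d) {
      id <- next_id; next_id <- next_id + 1L
      rows[[length(rows) + 1L]] <-
        c(id, f0, det$x[j], det$y[j], det$intensity[j])
      ends_x <- c(ends_x, det$x[j]); ends_y <- c(ends_y, det$y[j])
      ends_frame <- c(ends_frame, f0); ends_id <- c(ends_id, id)
    }
  }
  if (!length(rows)) {
    df <- data.frame(track_id = character(0), frame = integer(0),
                     x_um = numeric(0), y_um = numeric(0),
                     intensity = numeric(0))
  } else {
    m <- do.call(rbind, rows)
    df <- data.frame(track_id = sprintf("t%05d", as.integer(m[, 1])),
                     frame = as.integer(m[, 2]),
                     x_um = m[, 3] * pixel_size,
                     y_um = m[, 4] * pixel_size,
                     intensity = m[, 5])
  }
  trackset(df, frame_interval = frame_interval, pixel_size = pixel_size,
           cell_id = cell_id)
}

#' Filter tracks by length and ROI
#'
#' Keeps tracks with at least `min_frames` localizations (the count of
#' detected frames, not the frame span; the boundary is inclusive, i.e. a
#' "shorter than 10 frames" rule keeps length-10 tracks), then optionally
#' restricts to an ROI via [clip_to_roi()]. Never increases the track
#' count; idempotent. Removal counts are attached as attribute
#' `filter_log`.
#'
#' @param ts a [trackset()].
#' @param params a [link_params()] (its `min_frames` is used).
#' @param roi optional [roi_polygon()].
#' @return filtered [trackset()].
#' @export
filter_tracks <- function(ts, params = link_params(3, min_frames = 10L),
                          roi = NULL) {
  stopifnot(inherits(ts, "trackset"))
  tr <- ts$tracks
  n0 <- n_tracks(ts)
  len <- table(tr$track_id)
  keep <- names(len)[len >= params$min_frames]
  out <- ts
  out$tracks <- tr[tr$track_id %in% keep, , drop = FALSE]
  rownames(out$tracks) <- NULL
  n1 <- n_tracks(out)
  if (!is.null(roi)) out <- clip_to_roi(out, roi)
  n2 <- n_tracks(out)
  attr(out, "filter_log") <- c(n_input = n0, removed_short = n0 - n1,
                               removed_roi = n1 - n2, n_kept = n2)
  out
}

#' Localization precision from a stationary-particle series
#'
#' Standard tracking-precision calibration: each particle of a short
#' stationary series contributes the sample SD of its x and of its y
#' positions across frames; the estimate reports the mean and SD of these
#' per-axis values across particles (the "mean (+/- SD) nm" convention).
#'
#' @param ts a [trackset()] of stationary-particle tracks, each with >= 3
#'   points.
#' @return list of class `precision_estimate`: `mean_sd_x`, `mean_sd_y`,
#'   `sd_of_sd_x`, `sd_of_sd_y` (nanometres), `n_particles`.
#' @export
estimate_precision <- function(ts) {
  stopifnot(inherits(ts, "trackset"))
  tl <- track_list(ts)
  if (!length(tl))
    stop_gliotrack("no tracks to estimate precision from",
                   "gliotrack_validation_error")
  short <- vapply(tl, function(tr) length(tr$x) < 3L, logical(1))
  if (any(short))
    stop_gliotrack("every calibration track needs >= 3 points",
                   "gliotrack_validation_error")
  sdx <- vapply(tl, function(tr) stats::sd(tr$x), numeric(1)) * 1000
  sdy <- vapply(tl, function(tr) stats::sd(tr$y), numeric(1)) * 1000
  structure(list(mean_sd_x = mean(sdx), mean_sd_y = mean(sdy),
                 sd_of_sd_x = if (length(sdx) > 1L) stats::sd(sdx) else 0,
                 sd_of_sd_y = if (length(sdy) > 1L) stats::sd(sdy) else 0,
                 n_particles = length(sdx)),
            class = "precision_estimate")
}

#' @export
print.precision_estimate <- function(x, ...) {
  cat(sprintf("<precision_estimate> x: %.1f (+/- %.1f) nm, y: %.1f (+/- %.1f) nm, n = %d\n",
              x$mean_sd_x, x$sd_of_sd_x, x$mean_sd_y, x$sd_of_sd_y,
              x$n_particles))
  invisible(x)
}
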