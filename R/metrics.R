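#' Time-averaged mean-squared-displacement curve of a track
#'
#' For every integer lag k with at least one frame pair (i, i + k) present
#' in the track, MSD(k * dt) is the mean squared Euclidean displacement
#' over all such (overlapping) pairs. Pairs broken by gaps are simply
#' absent; no interpolation is performed.
#'
#' @param track list with vectors `frame`, `x`, `y` (as from
#'   [track_list()]), or a 1-track [trackset()].
#' @param frame_interval seconds per frame (ignored when a trackset is
#'   given).
#' @return data.frame of class `msd_curve` with columns `lag` (s), `msd`
#'   (um^2) and `n_pairs`.
#' @examples
#' tr <- list(frame = 0:3, x = c(0, 1, 2, 3), y = rep(0, 4))
#' msd_curve(tr, frame_interval = 1)
#' @export
msd_curve <- function(track, frame_interval = 0.03) {
  if (inherits(track, "trackset")) {
    frame_interval <- track$frame_interval
    tl <- track_list(track)
    if (length(tl) != 1L)
      stop_gliotrack("msd_curve() takes a single track", "gliotrack_validation_error")
    track <- tl[[1]]
  }
  f <- track$frame; x <- track$x; y <- track$y
  if (length(f) < 2L)
    stop_gliotrack("a track needs >= 2 points", "gliotrack_validation_error")
  span <- max(f) - min(f)
  lags <- integer(0); msd <- numeric(0); np <- integer(0)
  pos <- seq_along(f)
  for (k in seq_len(span)) {
    j <- match(f + k, f)
    ok <- !is.na(j)
    if (!any(ok)) next
    d2 <- (x[j[ok]] - x[ok])^2 + (y[j[ok]] - y[ok])^2
    lags <- c(lags, k); msd <- c(msd, mean(d2)); np <- c(np, length(d2))
  }
  structure(data.frame(lag = lags * frame_interval, msd = msd, n_pairs = np),
            class = c("msd_curve", "data.frame"))
}

#' Diffusion coefficient from an MSD curve
#'
#' The per-track diffusion coefficient is the unweighted mean over all
#' available lags tau of MSD(tau) / (q * tau), with q = 4 the 2D
#' dimensionality constant. Averaging over every available interval keeps
#' tracks of different lengths comparable, at the cost of bias for tracks
#' departing from free diffusion. An optional `max_lags` cap discards the
#' noisiest long lags.
#'
#' @param curve an [msd_curve()].
#' @param q dimensionality constant (default 4 for 2D imaging).
#' @param max_lags if finite, use only the first `max_lags` lags.
#' @return diffusion coefficient, um^2/s.
#' @export
diffusion_coefficient <- function(curve, q = 4, max_lags = Inf) {
  if (!nrow(curve))
    stop_gliotrack("empty MSD curve", "gliotrack_validation_error")
  use <- seq_len(min(nrow(curve), max_lags))
  mean(curve$msd[use] / (q * curve$lag[use]))
}

#' Net and total displacement of a track
#'
#' @param track list with `frame`, `x`, `y`, or a 1-track [trackset()].
#' @param frame_interval seconds per frame.
#' @return list with `d_net` (um, start-to-end straight line), `d_tot`
#'   (um, summed consecutive segment lengths; a gap contributes one
#'   straight segment) and `t_track` (s, frame span times the interval).
#' @export
displacements <- function(track, frame_interval = 0.03) {
  if (inherits(track, "trackset")) {
    frame_interval <- track$frame_interval
    track <- track_list(track)[[1]]
  }
  x <- track$x; y <- track$y; f <- track$frame
  n <- length(x)
  if (n < 2L)
    stop_gliotrack("a track needs >= 2 points", "gliotrack_validation_error")
  d_net <- sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
  d_tot <- sum(sqrt(diff(x)^2 + diff(y)^2))
  list(d_net = d_net, d_tot = d_tot,
       t_track = (f[n] - f[1]) * frame_interval)
}

#' Confinement ratio of a track
#'
#' Ratio of net to total displacement, with three duration conventions:
#' \describe{
#'   \item{as_printed}{(d_net / d_tot) * t_track, t_track in seconds — the
#'     literal published formula (default).}
#'   \item{sqrt_duration}{(d_net / d_tot) * sqrt(t_track) — the
#'     square-root duration correction of the cell-migration literature,
#'     which the published formula cites.}
#'   \item{plain}{d_net / d_tot, dimensionless in [0, 1].}
#' }
#' The printed formula is not bounded by 1 despite the accompanying claim
#' that ratios fall in [0, 1]; the discrepancy is resolved by exposing all
#' three modes rather than silently reinterpreting.
#'
#' @param d_net,d_tot,t_track as from [displacements()].
#' @param mode `"as_printed"`, `"sqrt_duration"` or `"plain"`.
#' @return the ratio; 0 (with a warning) when d_tot is 0.
#' @export
confinement_ratio <- function(d_net, d_tot, t_track,
                              mode = c("as_printed", "sqrt_duration", "plain")) {
  mode <- match.arg(mode)
  if (d_tot == 0) {
    warning("fully stationary track: confinement ratio defined as 0")
    return(0)
  }
  base <- d_net / d_tot
  switch(mode,
         as_printed = base * t_track,
         sqrt_duration = base * sqrt(t_track),
         plain = base)
}

#' Re-origin a track at its first point
#'
#' @param track list with `frame`, `x`, `y`.
#' @return the same structure translated so the first point is (0, 0).
#' @export
zero_origin <- function(track) {
  track$x <- track$x - track$x[1]
  track$y <- track$y - track$y[1]
  track
}

#' Circularity ratio of a polygon
#'
#' `4 * pi * A / p^2`: 1 for a disc, 0 for a degenerate (zero-area)
#' outline. Values are clipped to [0, 1] only for floating-point overshoot
#' below 1e-9.
#'
#' @param A area (>= 0), um^2.
#' @param p perimeter (> 0), um.
#' @return circularity in [0, 1].
#' @export
circularity <- function(A, p) {
  if (p <= 0)
    stop_gliotrack("perimeter must be > 0", "gliotrack_validation_error")
  if (A < 0)
    stop_gliotrack("area must be >= 0", "gliotrack_validation_error")
  r <- 4 * pi * A / p^2
  if (r > 1 && r <= 1 + 1e-9) r <- 1
  r
}

# shoelace area (absolute) and perimeter of a closed polygon given as
# vertex matrix
polygon_area_perimeter <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  A <- abs(sum(x * y[j] - x[j] * y)) / 2
  p <- sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
  list(area = A, perimeter = p)
}

#' Per-cell motion profile
#'
#' Pools the origin-zeroed points of every track of a cell into one
#' displacement cloud, traces its outline, and scores the outline's
#' circularity: an isotropic (random-motion) cell yields a near-circular
#' cloud (circularity near 1), a transport-dominated cell an elongated one
#' (toward 0). The outline is the convex hull by default — deterministic
#' and parameter-free, at the cost of an upward circularity bias for
#' concave clouds.
#'
#' @param ts a [trackset()].
#' @return object of class `motion_profile`: list with `cell_id`, `points`
#'   (zeroed displacement cloud), `outline` (hull vertices), `area`,
#'   `perimeter`, `r_circ`.
#' @export
motion_profile <- function(ts) {
  stopifnot(inherits(ts, "trackset"))
  tl <- track_list(ts)
  if (!length(tl))
    stop_gliotrack("motion profile needs >= 1 track", "gliotrack_validation_error")
  zs <- lapply(tl, zero_origin)
  pts <- cbind(x = unlist(lapply(zs, `[[`, "x"), use.names = FALSE),
               y = unlist(lapply(zs, `[[`, "y"), use.names = FALSE))
  h <- grDevices::chull(pts[, 1], pts[, 2])
  outline <- pts[h, , drop = FALSE]
  if (nrow(outline) < 3L) {
    ap <- list(area = 0,
               perimeter = if (nrow(outline) == 2L)
                 2 * sqrt(sum((outline[1, ] - outline[2, ])^2)) else 0)
  } else ap <- polygon_area_perimeter(outline)
  r <- if (ap$perimeter > 0) circularity(ap$area, ap$perimeter) else 0
  structure(list(cell_id = ts$cell_id, points = pts, outline = outline,
                 area = ap$area, perimeter = ap$perimeter, r_circ = r),
            class = "motion_profile")
}

#' @export
print.motion_profile <- function(x, ...) {
  cat(sprintf("<motion_profile> cell '%s': %d points, A = %.4g um^2, p = %.4g um, circularity = %.3f\n",
              x$cell_id, nrow(x$points), x$area, x$perimeter, x$r_circ))
  invisible(x)
}

#' Net-displacement direction diagram
#'
#' Bins the direction (atan2) of each track's net-displacement vector into
#' `n_sectors` equal angular sectors, sector 0 centred on the +x axis.
#' Tracks with zero net displacement are excluded and counted.
#'
#' @param ts a [trackset()].
#' @param n_sectors number of sectors (default 8).
#' @return list with `sector_mass` (fractions summing to 1), `n_used`,
#'   `n_zero`.
#' @export
direction_vectors <- function(ts, n_sectors = 8L) {
  tl <- track_list(ts)
  ang <- vapply(tl, function(tr) {
    n <- length(tr$x)
    dx <- tr$x[n] - tr$x[1]; dy <- tr$y[n] - tr$y[1]
    if (dx == 0 && dy == 0) NA_real_ else atan2(dy, dx)
  }, numeric(1))
  ok <- !is.na(ang)
  if (!any(ok))
    stop_gliotrack("no track with non-zero net displacement",
                   "gliotrack_validation_error")
  width <- 2 * pi / n_sectors
  sector <- (floor((ang[ok] + width / 2) / width)) %% n_sectors
  mass <- tabulate(sector + 1L, nbins = n_sectors) / sum(ok)
  list(sector_mass = mass, n_used = sum(ok), n_zero = sum(!ok))
}

#' Per-track metric table for a cell
#'
#' Computes, for every track of a trackset: the diffusion coefficient
#' (all-lag MSD average, q = 4), net/total displacement, duration, and the
#' confinement ratio in the requested mode.
#'
#' @param ts a [trackset()].
#' @param confinement_mode passed to [confinement_ratio()].
#' @param q dimensionality constant for [diffusion_coefficient()].
#' @param max_lags optional lag cap for the diffusion estimate.
#' @return data.frame with one row per track: `track_id`, `cell_id`,
#'   `stage`, `n_points`, `D`, `d_net`, `d_tot`, `t_track`, `confinement`;
#'   the mode is recorded in attribute `confinement_mode`.
#' @export
track_metrics <- function(ts, confinement_mode = "as_printed", q = 4,
                          max_lags = Inf) {
  stopifnot(inherits(ts, "trackset"))
  tl <- track_list(ts)
  dt <- ts$frame_interval
  n <- length(tl)
  D <- d_net <- d_tot <- t_track <- conf <- numeric(n)
  npt <- integer(n)
  for (i in seq_len(n)) {
    tr <- tl[[i]]
    npt[i] <- length(tr$frame)
    D[i] <- diffusion_coefficient(msd_curve(tr, dt), q = q,
                                  max_lags = max_lags)
    d <- displacements(tr, dt)
    d_net[i] <- d$d_net; d_tot[i] <- d$d_tot; t_track[i] <- d$t_track
    conf[i] <- if (d$d_tot == 0) 0 else
      confinement_ratio(d$d_net, d$d_tot, d$t_track, confinement_mode)
  }
  out <- data.frame(track_id = names(tl), cell_id = ts$cell_id,
                    stage = ts$stage, n_points = npt, D = D,
                    d_net = d_net, d_tot = d_tot, t_track = t_track,
                    confinement = conf)
  attr(out, "confinement_mode") <- confinement_mode
  out
}
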