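#' Motion model specification
#'
#' One component of a trajectory mixture. `brownian` is isotropic 2D
#' diffusion with per-axis step sd `sqrt(2 * D * dt)`; `directed` adds a
#' constant drift velocity; `confined` reflects the walk at a circular
#' corral of radius `corral_radius` centred on the track's start point.
#'
#' @param kind one of `"brownian"`, `"confined"`, `"directed"`.
#' @param D diffusion coefficient, um^2/s (>= 0).
#' @param drift length-2 drift velocity (vx, vy) in um/s (directed only).
#' @param corral_radius corral radius in um (confined only, > 0).
#' @return object of class `motion_model`.
#' @export
motion_model <- function(kind = c("brownian", "confined", "directed"),
                         D = 0, drift = c(0, 0), corral_radius = NULL) {
  kind <- match.arg(kind)
  assert_scalar_num(D, "D", 0)
  if (kind == "confined") {
    if (is.null(corral_radius))
      stop_gliotrack("confined motion needs a corral_radius",
                     "gliotrack_config_error")
    assert_scalar_num(corral_radius, "corral_radius", 0, strict = TRUE)
  }
  if (kind == "directed" && (length(drift) != 2L || !all(is.finite(drift))))
    stop_gliotrack("directed motion needs drift = c(vx, vy)",
                   "gliotrack_config_error")
  structure(list(kind = kind, D = D, drift = as.numeric(drift),
                 corral_radius = corral_radius),
            class = "motion_model")
}

#' Simulation configuration
#'
#' Describes one cell's worth of synthetic trajectories: a mixture of motion
#' models, a bounding geometry with reflecting walls, per-axis localization
#' noise, memoryless photobleaching, and a seed. Track lengths are
#' 2 + Geometric(bleach_prob) frames, truncated at `max_frames`.
#'
#' @param mixture list of `list(model = motion_model(...), fraction = f)`;
#'   fractions must sum to 1.
#' @param geometry list with `kind` in `"process"` (rectangle, fields
#'   `width`, `length`, um), `"bubble"` or `"sheet"` (disc, field `radius`).
#' @param localization_sigma per-axis localization noise sd, um
#'   (default 0.02, i.e. 20 nm).
#' @param bleach_prob per-frame track-termination probability in [0, 1].
#' @param n_tracks number of tracks to generate.
#' @param frame_interval seconds (default 0.03).
#' @param max_frames maximum track length (default 2500).
#' @param seed integer RNG seed (NULL = use current stream).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(mixture, geometry,
                              localization_sigma = 0.02,
                              bleach_prob = 0.05,
                              n_tracks = 1000,
                              frame_interval = 0.03,
                              max_frames = 2500,
                              seed = NULL) {
  fr <- vapply(mixture, function(m) m$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9)
    stop_gliotrack("mixture fractions must sum to 1", "gliotrack_config_error")
  if (any(fr < 0))
    stop_gliotrack("mixture fractions must be >= 0", "gliotrack_config_error")
  if (bleach_prob < 0 || bleach_prob > 1)
    stop_gliotrack("bleach_prob must lie in [0, 1]", "gliotrack_config_error")
  if (localization_sigma < 0)
    stop_gliotrack("localization_sigma must be >= 0", "gliotrack_config_error")
  if (!geometry$kind %in% c("process", "bubble", "sheet"))
    stop_gliotrack("geometry kind must be process/bubble/sheet",
                   "gliotrack_config_error")
  structure(list(mixture = mixture, geometry = geometry,
                 localization_sigma = localization_sigma,
                 bleach_prob = bleach_prob,
                 n_tracks = as.integer(n_tracks),
                 frame_interval = frame_interval,
                 max_frames = as.integer(max_frames),
                 seed = seed),
            class = "simulation_config")
}

# triangle-wave fold of v into [0, width]; exact reflecting boundary in 1D
fold_reflect <- function(v, width) {
  m <- v %% (2 * width)
  ifelse(m > width, 2 * width - m, m)
}

# reflect points radially into a disc of radius R centred at (cx, cy)
fold_disc <- function(x, y, cx, cy, R) {
  dx <- x - cx; dy <- y - cy
  r <- sqrt(dx^2 + dy^2)
  out <- r > R
  if (any(out)) {
    rn <- fold_reflect(r[out], R)
    sc <- ifelse(r[out] > 0, rn / r[out], 0)
    x[out] <- cx[out] + dx[out] * sc
    y[out] <- cy[out] + dy[out] * sc
  }
  list(x = x, y = y)
}

geometry_start <- function(geometry, n) {
  if (geometry$kind == "process") {
    list(x = stats::runif(n, 0, geometry$length),
         y = stats::runif(n, 0, geometry$width))
  } else {
    r <- geometry$radius * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    list(x = r * cos(th), y = r * sin(th))
  }
}

geometry_fold <- function(x, y, geometry) {
  if (geometry$kind == "process") {
    list(x = fold_reflect(x, geometry$length),
         y = fold_reflect(y, geometry$width))
  } else {
    fold_disc(x, y, rep(0, length(x)), rep(0, length(x)), geometry$radius)
  }
}

#' Simulate a population of particle tracks
#'
#' Draws each track's motion model from the mixture, simulates the walk at
#' the configured frame interval with reflecting corral/geometry boundaries,
#' truncates at a geometric photobleaching length, and finally adds
#' independent Gaussian localization noise per axis per frame. Fully
#' reproducible from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param cell_id,stage metadata labels passed through to the result.
#' @return a [trackset()].
#' @examples
#' cfg <- simulation_config(
#'   mixture = list(list(model = motion_model("brownian", D = 0.01),
#'                       fraction = 1)),
#'   geometry = list(kind = "sheet", radius = 10),
#'   localization_sigma = 0, bleach_prob = 0, n_tracks = 5,
#'   max_frames = 50, seed = 1)
#' simulate_tracks(cfg)
#' @export
simulate_tracks <- function(config, cell_id = "sim", stage = NA_character_) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_tracks
    dt <- config$frame_interval
    fr <- vapply(config$mixture, function(m) m$fraction, numeric(1))
    comp <- sample.int(length(fr), n, replace = TRUE, prob = fr)
    len <- if (config$bleach_prob > 0)
      pmin(2L + stats::rgeom(n, config$bleach_prob), config$max_frames)
    else rep(config$max_frames, n)
    start <- geometry_start(config$geometry, n)

    frames_list <- vector("list", n)
    xs_list <- vector("list", n)
    ys_list <- vector("list", n)

    for (ci in seq_along(config$mixture)) {
      idx <- which(comp == ci)
      if (!length(idx)) next
      mdl <- config$mixture[[ci]]$model
      nb <- length(idx)
      maxL <- max(len[idx])
      sd_step <- sqrt(2 * mdl$D * dt)
      dx_drift <- if (mdl$kind == "directed") mdl$drift[1] * dt else 0
      dy_drift <- if (mdl$kind == "directed") mdl$drift[2] * dt else 0
      x <- matrix(NA_real_, nb, maxL)
      y <- matrix(NA_real_, nb, maxL)
      x[, 1] <- start$x[idx]; y[, 1] <- start$y[idx]
      cx <- x[, 1]; cy <- y[, 1]
      if (maxL >= 2) for (t in 2:maxL) {
        xn <- x[, t - 1] + stats::rnorm(nb, dx_drift, sd_step)
        yn <- y[, t - 1] + stats::rnorm(nb, dy_drift, sd_step)
        if (mdl$kind == "confined") {
          p <- fold_disc(xn, yn, cx, cy, mdl$corral_radius)
          xn <- p$x; yn <- p$y
        }
        p <- geometry_fold(xn, yn, config$geometry)
        x[, t] <- p$x; y[, t] <- p$y
      }
      for (k in seq_len(nb)) {
        i <- idx[k]; L <- len[i]
        frames_list[[i]] <- 0:(L - 1L)
        xs_list[[i]] <- x[k, seq_len(L)]
        ys_list[[i]] <- y[k, seq_len(L)]
      }
    }

    npts <- sum(len)
    df <- data.frame(
      track_id = rep(sprintf("t%05d", seq_len(n)), times = len),
      frame = unlist(frames_list),
      x_um = unlist(xs_list),
      y_um = unlist(ys_list),
      intensity = 0
    )
    if (config$localization_sigma > 0) {
      df$x_um <- df$x_um + stats::rnorm(npts, 0, config$localization_sigma)
      df$y_um <- df$y_um + stats::rnorm(npts, 0, config$localization_sigma)
    }
    ts <- trackset(df, frame_interval = dt, cell_id = cell_id, stage = stage)
    attr(ts, "model_component") <- stats::setNames(
      vapply(config$mixture[comp], function(m) m$model$kind, character(1)),
      sprintf("t%05d", seq_len(n)))
    ts
  })
}

#' Stage presets for oligodendrocyte maturation
#'
#' Ready-made [simulation_config()]s emulating the motion structure of
#' myelin basic protein particles at three maturation stages:
#' \describe{
#'   \item{OPC}{precursor-cell process (narrow rectangle): isotropic mixture
#'     of free, corralled and a minority fast-diffusing population; no
#'     directed transport.}
#'   \item{eOL}{early membrane "bubble" (small disc): free diffusion at a
#'     mildly higher rate, the fast population gone, plus a modest directed
#'     component along a cell axis.}
#'   \item{mOL}{mature membrane sheet (large disc): majority strongly
#'     corralled, a stronger directed component, and a re-introduced fast
#'     population held in wide corrals.}
#' }
#' Directed components come in +/- pairs along a per-cell axis drawn from
#' the seed, so motion profiles elongate without net population drift.
#' Numeric values are package fixtures chosen to reproduce the qualitative
#' stage orderings (circularity OPC > eOL > mOL; confinement ratio
#' eOL > OPC > mOL; a fast category present in OPC and mOL but absent in
#' eOL); they are not measurements.
#'
#' @param stage `"OPC"`, `"eOL"` or `"mOL"`.
#' @param n_tracks tracks per cell (default 1200; after the short-track
#'   filter this lands in the 650-1500 per-cell range typical of curated
#'   single-molecule experiments).
#' @param seed integer seed; also orients the cell's directed axis.
#' @return a [simulation_config()].
#' @export
stage_preset <- function(stage = c("OPC", "eOL", "mOL"), n_tracks = 1200,
                         seed = NULL) {
  if (!is.character(stage) || !stage[1] %in% c("OPC", "eOL", "mOL"))
    stop_gliotrack(paste0("unknown stage: ", stage[1]),
                   "gliotrack_config_error")
  stage <- stage[1]
  theta <- with_seed(if (is.null(seed)) NULL else seed + 7L,
                     stats::runif(1, 0, pi))
  ax <- c(cos(theta), sin(theta))
  dirpair <- function(v, D, f) list(
    list(model = motion_model("directed", D = D, drift = v * ax),
         fraction = f / 2),
    list(model = motion_model("directed", D = D, drift = -v * ax),
         fraction = f / 2))

  mix <- switch(stage,
    OPC = list(
      list(model = motion_model("brownian", D = 2e-3), fraction = 0.55),
      list(model = motion_model("confined", D = 2e-3, corral_radius = 0.25),
           fraction = 0.30),
      list(model = motion_model("brownian", D = 3e-2), fraction = 0.15)),
    eOL = c(list(
      list(model = motion_model("brownian", D = 4e-3), fraction = 0.80)),
      dirpair(0.30, 2e-3, 0.20)),
    mOL = c(list(
      list(model = motion_model("confined", D = 1.5e-3, corral_radius = 0.05),
           fraction = 0.65),
      list(model = motion_model("confined", D = 3e-2, corral_radius = 0.60),
           fraction = 0.12)),
      dirpair(0.45, 1e-3, 0.23)))

  geom <- switch(stage,
    OPC = list(kind = "process", width = 1.2, length = 10),
    eOL = list(kind = "bubble", radius = 2.5),
    mOL = list(kind = "sheet", radius = 6))

  simulation_config(mixture = mix, geometry = geom,
                    localization_sigma = 0.02,
                    bleach_prob = if (stage == "mOL") 0.04 else 0.06,
                    n_tracks = n_tracks, frame_interval = 0.03,
                    max_frames = 2500, seed = seed)
}

#' Point-spread-function and camera model for movie rendering
#'
#' @param sigma_px Gaussian PSF sd in pixels (default 3 / 2.355, i.e. a
#'   3-pixel FWHM spot).
#' @param amplitude peak signal above background, counts.
#' @param background constant background level, counts.
#' @param read_noise_sd Gaussian read noise sd, counts.
#' @return object of class `psf_model`.
#' @export
psf_model <- function(sigma_px = 3 / 2.355, amplitude = 2000,
                      background = 100, read_noise_sd = 5) {
  assert_scalar_num(sigma_px, "sigma_px", 0, strict = TRUE)
  structure(list(sigma_px = sigma_px, amplitude = amplitude,
                 background = background, read_noise_sd = read_noise_sd),
            class = "psf_model")
}

#' Render a trackset as a synthetic time-lapse movie
#'
#' Each localization becomes a 2D Gaussian of sd `psf$sigma_px` on a
#' constant background; optionally Poisson shot noise is applied to
#' signal + background and Gaussian read noise added, then values are
#' clipped to the 16-bit range. Pixel (row r, col c) (1-based) has its
#' centre at x = (c-1) * pixel_size, y = (r-1) * pixel_size, x rightward
#' and y downward from the top-left corner.
#'
#' @param ts a [trackset()] whose `pixel_size` is set.
#' @param psf a [psf_model()].
#' @param shape c(H, W) image size in pixels.
#' @param n_frames number of frames (default: max track frame + 1).
#' @param shot_noise apply Poisson + read noise (default TRUE).
#' @param seed RNG seed for the noise.
#' @return a [framestack()].
#' @export
render_movie <- function(ts, psf = psf_model(), shape = c(64, 64),
                         n_frames = NULL, shot_noise = TRUE, seed = NULL) {
  stopifnot(inherits(ts, "trackset"), inherits(psf, "psf_model"))
  px <- ts$pixel_size
  if (is.na(px))
    stop_gliotrack("trackset pixel_size must be set to render",
                   "gliotrack_config_error")
  H <- shape[1]; W <- shape[2]
  tr <- ts$tracks
  if (nrow(tr)) {
    xp <- tr$x_um / px
    yp <- tr$y_um / px
    bad <- xp < 0 | xp > (W - 1) | yp < 0 | yp > (H - 1)
    if (any(bad))
      stop_gliotrack(paste0("track(s) outside image bounds: ",
                            paste(unique(tr$track_id[bad]), collapse = ", ")),
                     "gliotrack_validation_error")
  } else xp <- yp <- numeric(0)
  if (is.null(n_frames))
    n_frames <- if (nrow(tr)) max(tr$frame) + 1L else 1L

  with_seed(seed, {
    arr <- array(psf$background, dim = c(n_frames, H, W))
    win <- ceiling(4 * psf$sigma_px)
    if (nrow(tr)) for (i in seq_len(nrow(tr))) {
      t <- tr$frame[i] + 1L
      if (t > n_frames) next
      c0 <- floor(xp[i]) + 1L; r0 <- floor(yp[i]) + 1L
      cc <- max(1L, c0 - win):min(W, c0 + win + 1L)
      rr <- max(1L, r0 - win):min(H, r0 + win + 1L)
      gx <- exp(-((cc - 1) - xp[i])^2 / (2 * psf$sigma_px^2))
      gy <- exp(-((rr - 1) - yp[i])^2 / (2 * psf$sigma_px^2))
      arr[t, rr, cc] <- arr[t, rr, cc] + psf$amplitude * outer(gy, gx)
    }
    if (shot_noise) {
      v <- stats::rpois(length(arr), lambda = as.vector(arr)) +
        stats::rnorm(length(arr), 0, psf$read_noise_sd)
      arr <- array(v, dim = dim(arr))
    }
    arr <- round(pmin(pmax(arr, 0), 65535))
    framestack(arr, pixel_size = px, frame_interval = ts$frame_interval)
  })
}

#' Synthesize a stationary-particle calibration stack
#'
#' Emulates the standard localization-precision calibration: a short series
#' of frames (default 20) of immobile emitters whose apparent positions
#' jitter frame-to-frame by Gaussian noise of sd `sigma_nm` per axis.
#' Returns the rendered stack, the ground-truth positions, and the jittered
#' trajectory table so precision can also be estimated without imaging.
#'
#' @param n_particles number of emitters (>= 1).
#' @param sigma_nm per-axis apparent-position jitter, nanometres.
#' @param n_frames number of frames (default 20).
#' @param psf a [psf_model()]; set `read_noise_sd = 0` and
#'   `shot_noise = FALSE` for a noise-free stack.
#' @param shape c(H, W) pixels.
#' @param pixel_size micrometres per pixel.
#' @param shot_noise apply camera noise when rendering.
#' @param min_separation_px minimum centre-to-centre distance between
#'   emitters, pixels (default 8). Calibration fields use isolated
#'   emitters; overlapping spots would contaminate each other's centroids
#'   and overstate the precision figure.
#' @param seed RNG seed.
#' @return list with `stack` ([framestack()]), `truth` (data.frame of true
#'   positions, um) and `tracks` ([trackset()] of jittered positions).
#' @export
make_stationary_stack <- function(n_particles, sigma_nm, n_frames = 20L,
                                  psf = psf_model(), shape = c(64, 64),
                                  pixel_size = 0.1, shot_noise = TRUE,
                                  min_separation_px = 8,
                                  seed = NULL) {
  stopifnot(n_particles >= 1)
  with_seed(seed, {
    H <- shape[1]; W <- shape[2]
    margin <- 5
    px_x <- px_y <- numeric(0)
    tries <- 0L
    while (length(px_x) < n_particles) {
      cx <- stats::runif(1, margin, W - 1 - margin)
      cy <- stats::runif(1, margin, H - 1 - margin)
      if (!length(px_x) ||
          min(sqrt((px_x - cx)^2 + (px_y - cy)^2)) >= min_separation_px) {
        px_x <- c(px_x, cx); px_y <- c(px_y, cy)
      }
      tries <- tries + 1L
      if (tries > 1000L * n_particles)
        stop_gliotrack("cannot place emitters at the requested separation; enlarge the field",
                       "gliotrack_config_error")
    }
    tx <- px_x * pixel_size
    ty <- px_y * pixel_size
    sig <- sigma_nm / 1000
    df <- data.frame(
      track_id = rep(sprintf("p%04d", seq_len(n_particles)), each = n_frames),
      frame = rep(0:(n_frames - 1L), times = n_particles),
      x_um = rep(tx, each = n_frames) +
        stats::rnorm(n_particles * n_frames, 0, sig),
      y_um = rep(ty, each = n_frames) +
        stats::rnorm(n_particles * n_frames, 0, sig),
      intensity = 0)
    ts <- trackset(df, pixel_size = pixel_size, cell_id = "calibration")
    stack <- render_movie(ts, psf = psf, shape = shape, n_frames = n_frames,
                          shot_noise = shot_noise)
    list(stack = stack,
         truth = data.frame(particle = sprintf("p%04d", seq_len(n_particles)),
                            x_um = tx, y_um = ty),
         tracks = ts)
  })
}
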