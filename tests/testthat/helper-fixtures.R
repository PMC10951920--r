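# in-code fixtures shared across test files

make_track_df <- function(id, frames, x, y, intensity = 0) {
  data.frame(track_id = rep(id, length.out = length(frames)),
             frame = frames,
             x_um = rep(x, length.out = length(frames)),
             y_um = rep(y, length.out = length(frames)),
             intensity = rep(intensity, length.out = length(frames)))
}

# straight unit-step track along +x, n_steps segments
straight_ts <- function(n_steps = 10, dt = 0.03) {
  trackset(make_track_df("s", 0:n_steps, as.numeric(0:n_steps), 0),
           frame_interval = dt)
}

unit_square <- function() roi_polygon(c(0, 1, 1, 0), c(0, 0, 1, 1))

brownian_config <- function(D, n_tracks, n_frames, sigma = 0, seed = 1,
                            bleach = 0, radius = 1e4) {
  simulation_config(
    mixture = list(list(model = motion_model("brownian", D = D),
                        fraction = 1)),
    geometry = list(kind = "sheet", radius = radius),
    localization_sigma = sigma, bleach_prob = bleach, n_tracks = n_tracks,
    max_frames = n_frames, seed = seed)
}

random_trackset <- function(n_tracks = 5, seed = 1) {
  set.seed(seed)
  dfs <- lapply(seq_len(n_tracks), function(i) {
    n <- sample(3:12, 1)
    frames <- sort(sample(0:(2 * n), n))
    make_track_df(sprintf("tr%02d", i), frames,
                  stats::rnorm(n), stats::rnorm(n),
                  stats::runif(n, 0, 100))
  })
  trackset(do.call(rbind, dfs), frame_interval = 0.03, pixel_size = 0.1)
}

# consecutive-frame links of a trackset, in pixel units
extract_links <- function(ts, px = 0.1) {
  out <- list()
  for (tr in track_list(ts)) {
    n <- length(tr$frame)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      if (tr$frame[i + 1] - tr$frame[i] != 1L) next
      out[[length(out) + 1L]] <- c(tr$frame[i], tr$x[i] / px, tr$y[i] / px,
                                   tr$x[i + 1] / px, tr$y[i + 1] / px)
    }
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 5))
  do.call(rbind, out)
}

# fraction of true links matched by a recovered link with both endpoints
# within tol pixels
link_recovery <- function(truth, rec, px = 0.1, tol = 1) {
  tl <- extract_links(truth, px)
  rl <- extract_links(rec, px)
  if (!nrow(tl)) return(NA_real_)
  hit <- vapply(seq_len(nrow(tl)), function(i) {
    same <- rl[, 1] == tl[i, 1]
    if (!any(same)) return(FALSE)
    r <- rl[same, , drop = FALSE]
    d1 <- sqrt((r[, 2] - tl[i, 2])^2 + (r[, 3] - tl[i, 3])^2)
    d2 <- sqrt((r[, 4] - tl[i, 4])^2 + (r[, 5] - tl[i, 5])^2)
    any(d1 <= tol & d2 <= tol)
  }, logical(1))
  mean(hit)
}


# translate each track so origins sit on a grid (spacing um), preserving
# its motion; keeps rendered spots well separated for closed-loop tests
grid_respace <- function(ts, spacing = 1.2, origin = 0.7) {
  tl <- track_list(ts)
  ncol_grid <- ceiling(sqrt(length(tl)))
  tr <- ts$tracks
  for (i in seq_along(tl)) {
    id <- names(tl)[i]
    gx <- origin + spacing * ((i - 1) %% ncol_grid)
    gy <- origin + spacing * ((i - 1) %/% ncol_grid)
    sel <- tr$track_id == id
    tr$x_um[sel] <- tr$x_um[sel] - tl[[i]]$x[1] + gx
    tr$y_um[sel] <- tr$y_um[sel] - tl[[i]]$y[1] + gy
  }
  out <- ts
  out$tracks <- tr
  out
}
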