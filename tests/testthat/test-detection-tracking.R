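render_points <- function(pts_px, shape = c(48, 48), pixel_size = 0.1,
                          amplitude = 2000, frames = NULL, ...) {
  # pts_px: data.frame(track_id, frame, x, y) in pixels
  df <- data.frame(track_id = pts_px$track_id, frame = pts_px$frame,
                   x_um = pts_px$x * pixel_size,
                   y_um = pts_px$y * pixel_size, intensity = 0)
  ts <- trackset(df, pixel_size = pixel_size)
  render_movie(ts, psf_model(amplitude = amplitude, background = 100,
                             read_noise_sd = 5),
               shape = shape, ...)
}

test_that("blank frames yield no detections", {
  det <- detect_spots(matrix(100, 32, 32))
  expect_equal(nrow(det), 0L)
})

test_that("two well-separated spots are each localized within 0.2 px", {
  truth <- data.frame(track_id = c("a", "b"), frame = 0,
                      x = c(12.3, 22.3), y = c(20.6, 20.6))
  st <- render_points(truth, seed = 1)
  det <- detect_spots(st$data[1, , ])
  expect_equal(nrow(det), 2L)
  for (i in 1:2) {
    d <- sqrt((det$x - truth$x[i])^2 + (det$y - truth$y[i])^2)
    expect_lt(min(d), 0.2)
  }
})

test_that("integer-pixel localization lands on the argmax when subpixel off", {
  truth <- data.frame(track_id = "a", frame = 0, x = 17, y = 9)
  st <- render_points(truth, shot_noise = FALSE)
  det <- detect_spots(st$data[1, , ],
                      detection_params(subpixel = FALSE))
  expect_equal(nrow(det), 1L)
  expect_equal(det$x, 17)
  expect_equal(det$y, 9)
})

test_that("localization RMSE stays below 0.25 px at high SNR", {
  set.seed(12)
  errs <- c()
  for (rep in 1:20) {
    x0 <- runif(1, 10, 38); y0 <- runif(1, 10, 38)
    st <- render_points(data.frame(track_id = "a", frame = 0, x = x0,
                                   y = y0), seed = 1000 + rep)
    det <- detect_spots(st$data[1, , ])
    expect_gte(nrow(det), 1L)
    errs <- c(errs, min(sqrt((det$x - x0)^2 + (det$y - y0)^2)))
  }
  expect_lt(sqrt(mean(errs^2)), 0.25)
})

test_that("a drifting particle links into one gapless track", {
  pts <- data.frame(track_id = "a", frame = 0:49, x = 5 + (0:49) * 0.7,
                    y = 10)
  st <- render_points(pts, shape = c(24, 48), seed = 3)
  ts <- link_spots(detect_stack(st), link_params(max_disp_px = 3),
                   pixel_size = 0.1)
  expect_equal(n_tracks(ts), 1L)
  expect_equal(track_list(ts)[[1]]$frame, 0:49)
})

test_that("well-separated particles never swap identities", {
  pts <- rbind(
    data.frame(track_id = "a", frame = 0:29, x = 8 + (0:29) * 0.3, y = 8),
    data.frame(track_id = "b", frame = 0:29, x = 8 + (0:29) * 0.3, y = 38))
  st <- render_points(pts, seed = 4)
  ts <- link_spots(detect_stack(st), link_params(max_disp_px = 2),
                   pixel_size = 0.1)
  expect_equal(n_tracks(ts), 2L)
  for (tr in track_list(ts))
    expect_lt(max(tr$y) - min(tr$y), 0.5)  # um; stays on its own row
})

test_that("a missed frame is bridged as a gap when max_gap allows", {
  det <- lapply(0:20, function(f)
    if (f == 10) data.frame(x = numeric(0), y = numeric(0),
                            intensity = numeric(0))
    else data.frame(x = 5 + f * 0.5, y = 7, intensity = 1))
  ts <- link_spots(det, link_params(max_disp_px = 2, max_gap = 1),
                   pixel_size = 0.1)
  expect_equal(n_tracks(ts), 1L)
  f <- track_list(ts)[[1]]$frame
  expect_true(all(c(9L, 11L) %in% f))
  expect_false(10L %in% f)
  # with max_gap = 0 the same scenario splits in two
  ts0 <- link_spots(det, link_params(max_disp_px = 2, max_gap = 0),
                    pixel_size = 0.1)
  expect_equal(n_tracks(ts0), 2L)
})

test_that("short-track filter keeps >= 10 localizations inclusively", {
  lens <- c(5, 9, 10, 25)
  df <- do.call(rbind, lapply(seq_along(lens), function(i)
    make_track_df(paste0("t", i), seq_len(lens[i]) - 1L,
                  stats::runif(lens[i]), stats::runif(lens[i]))))
  ts <- trackset(df)
  out <- filter_tracks(ts, link_params(3, min_frames = 10))
  expect_setequal(unique(out$tracks$track_id), c("t3", "t4"))
  log <- attr(out, "filter_log")
  expect_equal(unname(log["removed_short"]), 2)
  # boundary: all length-10 tracks survive
  df10 <- do.call(rbind, lapply(1:3, function(i)
    make_track_df(paste0("k", i), 0:9, stats::runif(10), stats::runif(10))))
  out10 <- filter_tracks(trackset(df10), link_params(3, min_frames = 10))
  expect_equal(n_tracks(out10), 3L)
  # idempotent, never increases counts
  again <- filter_tracks(out, link_params(3, min_frames = 10))
  expect_equal(again$tracks, out$tracks)
  expect_lte(n_tracks(out), n_tracks(ts))
})

test_that("ROI filtering removes boundary-straddling tracks", {
  inside <- make_track_df("in", 0:10, seq(0.1, 0.9, length.out = 11), 0.5)
  strad <- make_track_df("out", 0:10, seq(0.5, 1.5, length.out = 11), 0.5)
  ts <- trackset(rbind(inside, strad))
  out <- filter_tracks(ts, link_params(3, min_frames = 5),
                       roi = unit_square())
  expect_equal(unique(out$tracks$track_id), "in")
})

test_that("closed-loop tracking recovers at least 95% of true links", {
  # sparse slow emitters; max_disp far above the expected step
  cfg <- simulation_config(
    mixture = list(list(model = motion_model("brownian", D = 5e-3),
                        fraction = 1)),
    geometry = list(kind = "process", width = 3.4, length = 3.4),
    localization_sigma = 0, bleach_prob = 0, n_tracks = 12,
    max_frames = 25, seed = 17)
  truth <- simulate_tracks(cfg)
  # shift into the image interior (pixel_size 0.1 -> 48 x 48 px frame)
  truth <- grid_respace(truth, spacing = 1.2, origin = 0.7)
  truth$pixel_size <- 0.1
  st <- render_movie(truth, psf_model(amplitude = 3000, background = 100,
                                      read_noise_sd = 5),
                     shape = c(48, 48), seed = 18)
  rec <- link_spots(detect_stack(st), link_params(max_disp_px = 3,
                                                  min_frames = 2),
                    pixel_size = 0.1)
  # a true consecutive-frame link counts as recovered when a reconstructed
  # track connects both endpoints within 1 px each
  recovered <- link_recovery(truth, rec, px = 0.1, tol = 1)
  expect_gte(recovered, 0.95)
})

test_that("estimate_precision reports per-axis jitter in mean (+/- SD) form", {
  # perfectly stationary -> 0 +/- 0
  df <- do.call(rbind, lapply(1:3, function(i)
    make_track_df(paste0("p", i), 0:19, i * 1.0, i * 2.0)))
  pe0 <- estimate_precision(trackset(df))
  expect_equal(pe0$mean_sd_x, 0); expect_equal(pe0$sd_of_sd_y, 0)
  # single particle -> sd_of_sd = 0
  pe1 <- estimate_precision(trackset(make_track_df("p", 0:19,
                                                   rnorm(20, 0, 0.02), 0)))
  expect_equal(pe1$sd_of_sd_x, 0)
  expect_equal(pe1$n_particles, 1L)
})

test_that("injected 20 nm jitter is recovered from the trajectory table", {
  cal <- make_stationary_stack(50, sigma_nm = 20, n_frames = 20,
                               shape = c(128, 128), seed = 6)
  pe <- estimate_precision(cal$tracks)
  expect_gt(pe$mean_sd_x, 17); expect_lt(pe$mean_sd_x, 23)
  expect_gt(pe$mean_sd_y, 17); expect_lt(pe$mean_sd_y, 23)
})
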