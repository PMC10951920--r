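test_that("MSD of a collinear unit-step track matches hand computation", {
  tr <- list(frame = 0:3, x = c(0, 1, 2, 3), y = rep(0, 4))
  cv <- msd_curve(tr, frame_interval = 1)
  expect_equal(cv$lag, c(1, 2, 3))
  expect_equal(cv$msd, c(1, 4, 9))
  expect_equal(cv$n_pairs, c(3L, 2L, 1L))
  expect_equal(diffusion_coefficient(cv), mean(c(1 / 4, 4 / 8, 9 / 12)))
})

test_that("stationary tracks give zero MSD and zero diffusion", {
  tr <- list(frame = 0:9, x = rep(2, 10), y = rep(-1, 10))
  cv <- msd_curve(tr, 0.03)
  expect_true(all(cv$msd == 0))
  expect_equal(diffusion_coefficient(cv), 0)
})

test_that("gapped tracks enumerate exactly the existing frame pairs", {
  tr <- list(frame = c(0L, 1L, 3L), x = c(0, 1, 3), y = c(0, 0, 0))
  cv <- msd_curve(tr, 1)
  expect_equal(cv$lag, c(1, 2, 3))
  expect_equal(cv$n_pairs, c(1L, 1L, 1L))  # (0,1), (1,3), (0,3)
  expect_equal(cv$msd, c(1, 4, 9))
})

test_that("median per-track D recovers ground truth within 10%", {
  dt <- 0.03
  for (D in c(1e-4, 1e-3, 1e-2)) {
    cfg <- brownian_config(D = D, n_tracks = 500, n_frames = 100,
                           seed = round(1e6 * D) + 3)
    met <- track_metrics(simulate_tracks(cfg), max_lags = 25)
    expect_lt(abs(stats::median(met$D) / D - 1), 0.10)
  }
  # the all-lag default is mean-unbiased but median-biased low for long
  # tracks: the documented reason max_lags exists
  cfg <- brownian_config(D = 1e-3, n_tracks = 500, n_frames = 100,
                         seed = 1003)
  ts <- simulate_tracks(cfg)
  met_all <- track_metrics(ts)
  expect_lt(abs(mean(met_all$D) / 1e-3 - 1), 0.10)
  expect_lt(stats::median(met_all$D), 1e-3)
  # 20 nm localization noise biases the estimate upward
  D <- 1e-3
  cfgn <- brownian_config(D = D, n_tracks = 300, n_frames = 100,
                          sigma = 0.02, seed = 99)
  metn <- track_metrics(simulate_tracks(cfgn))
  expect_gt(stats::median(metn$D), D)
})

test_that("displacements decompose net and total path length", {
  d <- displacements(list(frame = 0:2, x = c(0, 1, 0), y = c(0, 0, 0)), 1)
  expect_equal(d$d_net, 0); expect_equal(d$d_tot, 2)
  d2 <- displacements(list(frame = 0:2, x = c(0, 3, 3), y = c(0, 0, 4)), 1)
  expect_equal(d2$d_net, 5); expect_equal(d2$d_tot, 7)
  d3 <- displacements(track_list(straight_ts(10))[[1]], 0.03)
  expect_equal(d3$d_net, 10); expect_equal(d3$d_tot, 10)
  expect_equal(d3$t_track, 0.3)
})

test_that("confinement ratio modes agree with hand values", {
  d <- displacements(track_list(straight_ts(10))[[1]], 0.03)
  expect_equal(confinement_ratio(d$d_net, d$d_tot, d$t_track, "as_printed"),
               0.3)
  expect_equal(confinement_ratio(d$d_net, d$d_tot, d$t_track,
                                 "sqrt_duration"), sqrt(0.3))
  expect_equal(confinement_ratio(d$d_net, d$d_tot, d$t_track, "plain"), 1)
  # closed loop -> 0 in every mode
  dc <- displacements(list(frame = 0:2, x = c(0, 1, 0), y = c(0, 0, 0)),
                      0.03)
  for (m in c("as_printed", "sqrt_duration", "plain"))
    expect_equal(confinement_ratio(dc$d_net, dc$d_tot, dc$t_track, m), 0)
  # as_printed is linear in the frame interval
  dhalf <- displacements(track_list(straight_ts(10, dt = 0.015))[[1]], 0.015)
  expect_equal(confinement_ratio(dhalf$d_net, dhalf$d_tot, dhalf$t_track,
                                 "as_printed"), 0.15)
  # stationary track warns and returns 0
  expect_warning(r0 <- confinement_ratio(0, 0, 1), "stationary")
  expect_equal(r0, 0)
})

test_that("zero_origin translates to the origin and is idempotent", {
  tr <- list(frame = 0:2, x = c(5, 6, 7), y = c(5, 4, 3))
  z <- zero_origin(tr)
  expect_equal(c(z$x[1], z$y[1]), c(0, 0))
  expect_equal(zero_origin(z), z)
  shifted <- tr; shifted$x <- tr$x + 11; shifted$y <- tr$y - 3
  expect_equal(zero_origin(shifted), z)
})

test_that("circularity matches closed forms and clips only overshoot", {
  expect_equal(circularity(1, 4), pi / 4)
  expect_equal(circularity(0, 10), 0)
  for (r in c(0.1, 1, 25))
    expect_equal(circularity(pi * r^2, 2 * pi * r), 1)
  expect_error(circularity(1, 0), class = "gliotrack_validation_error")
})

test_that("motion profile hull reproduces square, circle and line values", {
  # zeroed points land on the unit-square corners
  df <- do.call(rbind, lapply(1:4, function(i) {
    dx <- c(0, 1, 1, 0)[i]; dy <- c(0, 0, 1, 1)[i]
    make_track_df(paste0("c", i), 0:1, c(0, dx), c(0, dy))
  }))
  prof <- motion_profile(trackset(df))
  expect_equal(prof$area, 1)
  expect_equal(prof$perimeter, 4)
  expect_equal(prof$r_circ, 4 * pi / 16)

  # fine polygonal circle -> 1.00 at 2 dp
  th <- 2 * pi * (0:255) / 256
  dfc <- do.call(rbind, lapply(seq_along(th), function(i)
    make_track_df(paste0("r", i), 0:1, c(0, cos(th[i])), c(0, sin(th[i])))))
  profc <- motion_profile(trackset(dfc))
  expect_equal(round(profc$r_circ, 2), 1)
  expect_equal(profc$r_circ, (pi / 256) / tan(pi / 256), tolerance = 1e-9)

  # collinear cloud -> area 0, circularity 0
  dfl <- make_track_df("l", 0:49, seq(0, 1, length.out = 50), 0)
  profl <- motion_profile(trackset(dfl))
  expect_equal(profl$area, 0)
  expect_equal(profl$r_circ, 0)
})

test_that("direction vectors resolve drift and stay uniform when isotropic", {
  # all +x drift -> all mass in sector 0
  df <- do.call(rbind, lapply(1:5, function(i)
    make_track_df(paste0("d", i), 0:1, c(0, 1), c(0, 0.01 * i))))
  v <- direction_vectors(trackset(df))
  expect_equal(v$sector_mass[1], 1)
  # opposite pair -> 0.5 / 0.5 in opposing sectors
  df2 <- rbind(make_track_df("a", 0:1, c(0, 1), 0),
               make_track_df("b", 0:1, c(0, -1), 0))
  v2 <- direction_vectors(trackset(df2))
  expect_equal(v2$sector_mass[1], 0.5)
  expect_equal(v2$sector_mass[5], 0.5)
  # isotropic population -> near-uniform sector mass
  cfg <- brownian_config(D = 1e-2, n_tracks = 10000, n_frames = 3, seed = 8)
  v3 <- direction_vectors(simulate_tracks(cfg))
  expect_lt(max(v3$sector_mass) - min(v3$sector_mass), 0.03)
})

test_that("metrics are invariant to translation; D and plain ratio to rotation", {
  set.seed(21)
  ts <- random_trackset(4, seed = 21)
  met <- track_metrics(ts, confinement_mode = "plain")
  # translation
  tr2 <- ts$tracks; tr2$x_um <- tr2$x_um + 13.7; tr2$y_um <- tr2$y_um - 4.2
  met_t <- track_metrics(trackset(tr2, frame_interval = ts$frame_interval),
                         confinement_mode = "plain")
  expect_equal(met_t$D, met$D)
  expect_equal(met_t$confinement, met$confinement)
  # rotation by 37 degrees
  a <- 37 * pi / 180
  tr3 <- ts$tracks
  x <- tr3$x_um; y <- tr3$y_um
  tr3$x_um <- cos(a) * x - sin(a) * y
  tr3$y_um <- sin(a) * x + cos(a) * y
  met_r <- track_metrics(trackset(tr3, frame_interval = ts$frame_interval),
                         confinement_mode = "plain")
  expect_equal(met_r$D, met$D, tolerance = 1e-10)
  expect_equal(met_r$confinement, met$confinement, tolerance = 1e-10)
})

test_that("confined < brownian < directed on median plain confinement", {
  mk <- function(model, seed) {
    cfg <- simulation_config(
      mixture = list(list(model = model, fraction = 1)),
      geometry = list(kind = "sheet", radius = 1e4),
      localization_sigma = 0, bleach_prob = 0, n_tracks = 150,
      max_frames = 60, seed = seed)
    track_metrics(simulate_tracks(cfg), confinement_mode = "plain")$confinement
  }
  conf <- mk(motion_model("confined", D = 5e-3, corral_radius = 0.1), 31)
  brow <- mk(motion_model("brownian", D = 5e-3), 32)
  dir <- mk(motion_model("directed", D = 5e-4, drift = c(0.5, 0)), 33)
  expect_lt(stats::median(conf), stats::median(brow))
  expect_lt(stats::median(brow), stats::median(dir))
  kw <- kruskal_wallis(list(conf, brow, dir))
  expect_lt(kw$p_value, 0.001)
})

test_that("drift-dominated profiles score lower circularity than isotropic", {
  r_iso <- r_drift <- numeric(10)
  for (i in 1:10) {
    iso <- brownian_config(D = 5e-3, n_tracks = 150, n_frames = 40,
                           seed = 300 + i)
    r_iso[i] <- motion_profile(simulate_tracks(iso))$r_circ
    dcfg <- simulation_config(
      mixture = list(
        list(model = motion_model("directed", D = 5e-4, drift = c(0.8, 0)),
             fraction = 0.5),
        list(model = motion_model("directed", D = 5e-4, drift = c(-0.8, 0)),
             fraction = 0.5)),
      geometry = list(kind = "sheet", radius = 1e4),
      localization_sigma = 0, bleach_prob = 0, n_tracks = 150,
      max_frames = 40, seed = 400 + i)
    r_drift[i] <- motion_profile(simulate_tracks(dcfg))$r_circ
  }
  expect_true(all(r_drift < r_iso))
})
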