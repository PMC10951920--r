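#' Plot a motion profile
#'
#' Origin-zeroed displacement cloud of one cell with its traced outline.
#' Requires ggplot2.
#'
#' @param profile a [motion_profile()].
#' @param max_points subsample the cloud for plotting (default 5000).
#' @return a ggplot object.
#' @export
plot_motion_profile <- function(profile, max_points = 5000L) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_gliotrack("ggplot2 is required for plotting", "gliotrack_config_error")
  pts <- as.data.frame(profile$points)
  if (nrow(pts) > max_points)
    pts <- pts[seq(1L, nrow(pts), length.out = max_points), ]
  hull <- as.data.frame(profile$outline)
  ggplot2::ggplot(pts, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point(size = 0.2, alpha = 0.3) +
    ggplot2::geom_polygon(data = hull, fill = NA, colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s (circularity %.2f)",
                                  profile$cell_id, profile$r_circ),
                  x = "x displacement (um)", y = "y displacement (um)")
}

#' Plot MSD-versus-lag curves for a sample of tracks
#'
#' @param ts a [trackset()].
#' @param n_curves number of tracks to draw (default 50).
#' @return a ggplot object.
#' @export
plot_msd_curves <- function(ts, n_curves = 50L) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_gliotrack("ggplot2 is required for plotting", "gliotrack_config_error")
  tl <- track_list(ts)
  ids <- names(tl)[seq_len(min(n_curves, length(tl)))]
  dfs <- lapply(ids, function(id) {
    cv <- msd_curve(tl[[id]], ts$frame_interval)
    cv$track_id <- id
    cv
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = lag, y = msd,
                                   group = track_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = "lag (s)", y = "MSD (um^2)",
                  title = sprintf("MSD curves, cell %s", ts$cell_id))
}

#' Plot a frequency distribution
#'
#' @param fd a [frequency_distribution()].
#' @param log_y log-scale the frequency axis (default FALSE).
#' @return a ggplot object.
#' @export
plot_frequency_distribution <- function(fd, log_y = FALSE) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_gliotrack("ggplot2 is required for plotting", "gliotrack_config_error")
  g <- fd$graphed
  g$mid <- (g$lower + g$upper) / 2
  p <- ggplot2::ggplot(g, ggplot2::aes(x = mid, y = percent)) +
    ggplot2::geom_col(width = (g$upper - g$lower) * 0.9) +
    ggplot2::labs(x = "bin", y = "% of particle population")
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

# write the standard figure set for a pipeline run
write_pipeline_figures <- function(report, out_dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    warning("ggplot2 not available; skipping figures")
    return(invisible(NULL))
  }
  fig_dir <- file.path(out_dir, "figures")
  dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)
  for (cell_id in names(report$profiles)) {
    p <- plot_motion_profile(report$profiles[[cell_id]])
    ggplot2::ggsave(file.path(fig_dir, paste0("profile_", cell_id, ".png")),
                    p, width = 4, height = 4, dpi = 120)
  }
  for (qty in names(report$distributions)) {
    for (st in names(report$distributions[[qty]])) {
      p <- plot_frequency_distribution(report$distributions[[qty]][[st]],
                                       log_y = qty == "diffusion")
      ggplot2::ggsave(file.path(fig_dir, sprintf("dist_%s_%s.png", qty, st)),
                      p, width = 4, height = 3, dpi = 120)
    }
  }
  # ECDF overlays per quantity
  met <- report$metrics
  for (qty in c("confinement", "D")) {
    df <- data.frame(value = met[[qty]], stage = met$stage)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = value,
                                          colour = stage)) +
      ggplot2::stat_ecdf() +
      ggplot2::labs(x = qty, y = "cumulative frequency")
    ggplot2::ggsave(file.path(fig_dir, sprintf("ecdf_%s.png", qty)), p,
                    width = 4, height = 3, dpi = 120)
  }
  invisible(NULL)
}

utils::globalVariables(c("x", "y", "lag", "msd", "track_id", "mid",
                         "percent", "value", "stage"))
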