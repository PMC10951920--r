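#' Pipeline configuration
#'
#' Parameters for a full simulate -> filter -> metrics -> distributions ->
#' compare run over one or more maturation-stage presets.
#'
#' @param stages character vector of stage presets to simulate.
#' @param n_cells simulated cells per stage (default 10).
#' @param n_tracks tracks generated per cell before filtering
#'   (default 1200).
#' @param seed master seed; every cell derives its own stream from it.
#' @param confinement_mode passed to [track_metrics()].
#' @param min_frames short-track filter threshold (default 10).
#' @param n_conf_bins,n_diff_bins frequency-bin counts (defaults 10 and
#'   12).
#' @param drop_first_diffusion_bin graph diffusion distributions without
#'   the (dominant) first bin while keeping it in the statistics
#'   (default TRUE).
#' @param out_dir optional directory for per-cell CSVs, the report and
#'   figures.
#' @param make_plots write diagnostic figures (requires ggplot2;
#'   default FALSE).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("OPC", "eOL", "mOL"),
                            n_cells = 10L, n_tracks = 1200L, seed = 1L,
                            confinement_mode = "as_printed",
                            min_frames = 10L,
                            n_conf_bins = 10L, n_diff_bins = 12L,
                            drop_first_diffusion_bin = TRUE,
                            out_dir = NULL, make_plots = FALSE) {
  stopifnot(length(stages) >= 1L, n_cells >= 1L, n_tracks >= 1L)
  structure(list(stages = stages, n_cells = as.integer(n_cells),
                 n_tracks = as.integer(n_tracks), seed = as.integer(seed),
                 confinement_mode = confinement_mode,
                 min_frames = as.integer(min_frames),
                 n_conf_bins = as.integer(n_conf_bins),
                 n_diff_bins = as.integer(n_diff_bins),
                 drop_first_diffusion_bin = drop_first_diffusion_bin,
                 out_dir = out_dir, make_plots = make_plots),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on simulated stage populations
#'
#' For each stage and cell: simulate trajectories from the stage preset,
#' apply the short-track filter, compute per-track metrics and the
#' per-cell motion profile. Then, across stages: pooled-range frequency
#' distributions (with fast/slow categories), per-particle and per-cell
#' group summaries, Kruskal-Wallis + Dunn's post hoc, and pairwise
#' two-sample KS tests at the Bonferroni-corrected alpha. Deterministic
#' given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return list of class `stage_report`; see [emit_report()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  lp <- link_params(3, min_frames = config$min_frames)
  per_cell <- list()
  metrics_all <- list()
  counts <- list()
  for (si in seq_along(config$stages)) {
    stage <- config$stages[si]
    for (ci in seq_len(config$n_cells)) {
      cell_seed <- config$seed + 10000L * si + ci
      cell_id <- sprintf("%s_cell%02d", stage, ci)
      preset <- stage_preset(stage, n_tracks = config$n_tracks,
                             seed = cell_seed)
      ts <- simulate_tracks(preset, cell_id = cell_id, stage = stage)
      fts <- filter_tracks(ts, lp)
      if (!n_tracks(fts))
        stop_gliotrack(sprintf("pipeline stage '%s' cell '%s': no tracks survived filtering",
                               stage, cell_id), "gliotrack_pipeline_error")
      met <- track_metrics(fts, confinement_mode = config$confinement_mode)
      prof <- motion_profile(fts)
      per_cell[[cell_id]] <- list(stage = stage, cell_id = cell_id,
                                  n_tracks_pre = n_tracks(ts),
                                  n_tracks_post = n_tracks(fts),
                                  r_circ = prof$r_circ,
                                  profile = prof,
                                  median_conf = stats::median(met$confinement),
                                  median_D = stats::median(met$D))
      metrics_all[[cell_id]] <- met
      counts[[cell_id]] <- c(pre = n_tracks(ts), post = n_tracks(fts))
    }
  }
  metrics <- do.call(rbind, metrics_all)
  rownames(metrics) <- NULL
  cells <- data.frame(
    cell_id = vapply(per_cell, `[[`, character(1), "cell_id"),
    stage = vapply(per_cell, `[[`, character(1), "stage"),
    n_tracks_pre = vapply(per_cell, `[[`, numeric(1), "n_tracks_pre"),
    n_tracks_post = vapply(per_cell, `[[`, numeric(1), "n_tracks_post"),
    r_circ = vapply(per_cell, `[[`, numeric(1), "r_circ"),
    median_conf = vapply(per_cell, `[[`, numeric(1), "median_conf"),
    median_D = vapply(per_cell, `[[`, numeric(1), "median_D"))
  rownames(cells) <- NULL

  stages <- config$stages
  by_stage <- function(df, col) split(df[[col]], factor(df$stage, stages))
  conf_groups <- by_stage(metrics, "confinement")
  D_groups <- by_stage(metrics, "D")
  circ_groups <- by_stage(cells, "r_circ")
  conf_cell_groups <- by_stage(cells, "median_conf")
  D_cell_groups <- by_stage(cells, "median_D")

  conf_scheme <- pooled_range_bins(metrics$confinement, config$n_conf_bins)
  conf_scheme <- assign_categories(conf_scheme,
                                   labels = c("high", "medium", "light"))
  diff_scheme <- pooled_range_bins(metrics$D, config$n_diff_bins)
  diff_scheme <- assign_categories(diff_scheme,
                                   labels = c("slow", "intermediate", "fast"))
  distributions <- list(
    confinement = lapply(conf_groups, frequency_distribution,
                         scheme = conf_scheme),
    diffusion = lapply(D_groups, frequency_distribution,
                       scheme = diff_scheme,
                       drop_first_bin = config$drop_first_diffusion_bin))
  fast_fraction <- vapply(D_groups, category_fraction, numeric(1),
                          scheme = diff_scheme, label = "fast")

  summarize_groups <- function(gl) lapply(gl, group_summary)
  pairwise_ks <- function(gl) {
    if (length(gl) < 2L) return(NULL)
    pr <- utils::combn(names(gl), 2)
    out <- lapply(seq_len(ncol(pr)), function(m)
      ks_two_sample(gl[[pr[1, m]]], gl[[pr[2, m]]], alpha = 0.05,
                    n_tests = 2L))
    names(out) <- paste(pr[1, ], pr[2, ], sep = "_vs_")
    out
  }
  omnibus <- function(gl) {
    if (length(gl) < 2L) return(NULL)
    list(kw = kruskal_wallis(gl), dunn = dunns_posthoc(gl))
  }

  tests <- list(
    circularity = omnibus(circ_groups),
    confinement_particle = c(omnibus(conf_groups),
                             list(ks = pairwise_ks(conf_groups))),
    confinement_cell = omnibus(conf_cell_groups),
    diffusion_particle = c(omnibus(D_groups),
                           list(ks = pairwise_ks(D_groups))),
    diffusion_cell = omnibus(D_cell_groups))

  report <- structure(list(
    config = config,
    seed = config$seed,
    cells = cells,
    summaries = list(
      circularity = summarize_groups(circ_groups),
      confinement_particle = summarize_groups(conf_groups),
      confinement_cell = summarize_groups(conf_cell_groups),
      diffusion_particle = summarize_groups(D_groups),
      diffusion_cell = summarize_groups(D_cell_groups)),
    distributions = distributions,
    fast_fraction = fast_fraction,
    tests = tests,
    metrics = metrics,
    profiles = lapply(per_cell, `[[`, "profile")),
    class = "stage_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics,
                     file.path(config$out_dir, "track_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(cells, file.path(config$out_dir, "cell_summary.csv"),
                     row.names = FALSE)
    emit_report(report, "json",
                path = file.path(config$out_dir, "report.json"))
    emit_report(report, "markdown",
                path = file.path(config$out_dir, "report.md"))
    if (isTRUE(config$make_plots)) write_pipeline_figures(report, config$out_dir)
  }
  report
}

#' @export
print.stage_report <- function(x, ...) {
  cat("<stage_report>\n")
  cat("  stages:", paste(names(x$summaries$circularity), collapse = ", "), "\n")
  cat("  cells:", nrow(x$cells), " tracks (post-filter):",
      sum(x$cells$n_tracks_post), "\n")
  med <- vapply(x$summaries$circularity, `[[`, numeric(1), "median")
  cat("  median circularity:", paste(sprintf("%s = %.3f", names(med), med),
                                     collapse = ", "), "\n")
  invisible(x)
}

report_payload <- function(report) {
  num_summary <- function(s) lapply(unclass(s), unname)
  test_json <- function(tr) {
    if (is.null(tr)) return(NULL)
    list(statistic = tr$statistic, p_value = tr$p_value, df = tr$df,
         alpha_used = tr$alpha_used, corrected = tr$corrected)
  }
  tests_json <- function(block) {
    if (is.null(block)) return(NULL)
    out <- list()
    if (!is.null(block$kw)) out$kruskal_wallis <- test_json(block$kw)
    if (!is.null(block$dunn)) out$dunn <- block$dunn
    if (!is.null(block$ks)) out$ks <- lapply(block$ks, test_json)
    out
  }
  dist_json <- function(fd) list(
    edges = fd$scheme$edges, counts = fd$counts, percent = fd$percent,
    n_total = fd$n_total, drop_first_bin = fd$drop_first_bin)
  cfg <- report$config
  cfg_flat <- cfg[setdiff(names(unclass(cfg)), c("out_dir", "make_plots"))]
  list(
    seed = report$seed,
    config = cfg_flat,
    config_hash = {
      s <- paste(deparse(cfg_flat), collapse = "")
      sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97)) %%
                .Machine$integer.max)
    },
    n_cells = nrow(report$cells),
    cells = report$cells,
    summaries = lapply(report$summaries,
                       function(g) lapply(g, num_summary)),
    fast_fraction = as.list(report$fast_fraction),
    distributions = lapply(report$distributions,
                           function(g) lapply(g, dist_json)),
    tests = lapply(report$tests, tests_json))
}

#' Serialize a stage report
#'
#' JSON (machine-readable) and Markdown (human-readable) renderings carry
#' the same numbers; the JSON additionally records the full configuration
#' and seed so runs can be reproduced.
#'
#' @param report a `stage_report` from [run_pipeline()].
#' @param fmt `"json"` or `"markdown"`.
#' @param path output file (NULL = return the text).
#' @return the rendered text, invisibly if written to `path`.
#' @export
emit_report <- function(report, fmt = c("json", "markdown"), path = NULL) {
  stopifnot(inherits(report, "stage_report"))
  if (!is.character(fmt) || !fmt[1] %in% c("json", "markdown"))
    stop_gliotrack(paste0("unknown report format: ", fmt[1]),
                   "gliotrack_config_error")
  fmt <- fmt[1]
  payload <- report_payload(report)
  txt <- if (fmt == "json") {
    as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                  null = "null", pretty = TRUE))
  } else {
    md <- c("# Stage comparison report", "",
            sprintf("Seed: %d; cells: %d; stages: %s", report$seed,
                    nrow(report$cells),
                    paste(unique(report$cells$stage), collapse = ", ")), "",
            "## Medians (IQR) by stage", "")
    for (metric in names(report$summaries)) {
      md <- c(md, sprintf("### %s", metric), "")
      for (st in names(report$summaries[[metric]])) {
        s <- report$summaries[[metric]][[st]]
        md <- c(md, sprintf(
          "- %s: n = %d, median = %.6g (IQR %.6g-%.6g, 95%% CI %.6g-%.6g)",
          st, s$n, s$median, s$q1, s$q3, s$ci95_lo, s$ci95_hi))
      }
      md <- c(md, "")
    }
    md <- c(md, "## Fast-category fraction by stage", "",
            vapply(names(report$fast_fraction), function(st)
              sprintf("- %s: %.6g", st, report$fast_fraction[[st]]),
              character(1)), "")
    for (metric in names(report$tests)) {
      blk <- report$tests[[metric]]
      if (is.null(blk)) next
      md <- c(md, sprintf("## Tests: %s", metric), "")
      if (!is.null(blk$kw))
        md <- c(md, sprintf("- Kruskal-Wallis H = %.6g, df = %g, p = %.3g",
                            blk$kw$statistic, blk$kw$df, blk$kw$p_value))
      if (!is.null(blk$dunn))
        md <- c(md, vapply(seq_len(nrow(blk$dunn)), function(i)
          sprintf("- Dunn %s vs %s: z = %.6g, adjusted p = %.3g",
                  blk$dunn$group1[i], blk$dunn$group2[i], blk$dunn$z[i],
                  blk$dunn$p_adjusted[i]), character(1)))
      if (!is.null(blk$ks))
        md <- c(md, vapply(names(blk$ks), function(nm)
          sprintf("- KS %s: D = %.6g, p = %.3g (alpha %.4g)", nm,
                  blk$ks[[nm]]$statistic, blk$ks[[nm]]$p_value,
                  blk$ks[[nm]]$alpha_used), character(1)))
      md <- c(md, "")
    }
    paste(md, collapse = "\n")
  }
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
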