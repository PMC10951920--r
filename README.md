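# gliotrack

Single-particle tracking (SPT) analysis of membrane-protein mobility in
live cells, built around the workflow used to study myelin basic protein
(MBP) in oligodendrocytes: sparse photoswitched emitters imaged at 30 ms
per frame are detected and linked into tracks, and each cell's particle
population is characterized by three statistics —

- **diffusion coefficient** per track, from the time-averaged
  mean-squared displacement: `D = mean over lags of MSD(tau) / (4 tau)`
  (the dimensionality constant 4 is the 2D value);
- **confinement ratio** per track: `(d_net / d_tot) * t_track`, net over
  total displacement with a duration correction (square-root and plain
  variants are also provided);
- **circularity** per cell: all tracks re-plotted from a common origin
  form a "motion profile", whose traced outline scores
  `r_circ = 4 * pi * A / p^2` — 1 for isotropic (random) motion, 0 for
  linear (directed) motion.

Populations are compared with the field's nonparametric toolkit:
pooled-range frequency bins (10 for confinement, 12 for diffusion),
medians + IQR + distribution-free 95 % CIs, Kruskal–Wallis with Dunn's
post hoc, and pairwise two-sample Kolmogorov–Smirnov tests at a
Bonferroni-corrected alpha.

The package is self-contained: a trajectory simulator (Brownian /
corral-confined / directed mixtures with reflecting boundaries,
geometric photobleaching, 20 nm localization noise) and a movie renderer
(Gaussian PSF, Poisson + read noise) generate populations with the
motion structure of the three oligodendrocyte maturation stages (OPC
processes, eOL membrane bubbles, mOL membrane sheets), so every stage of
the pipeline — including the spot detector and greedy
nearest-neighbour linker — is tested closed-loop against known ground
truth. See `vignettes/gliotrack-methods.Rmd` for the models,
parameter choices and their rationale.

## Worked example

Simulate one mature-oligodendrocyte cell, filter short tracks, and
compute its metrics:

```r
library(gliotrack)

cfg <- stage_preset("mOL", n_tracks = 300, seed = 42)
ts  <- simulate_tracks(cfg, cell_id = "mOL_demo", stage = "mOL")
fts <- filter_tracks(ts)          # drop tracks with < 10 localizations
fts
#> <trackset> cell 'mOL_demo' [mOL]: 226 tracks, 7744 localizations, dt = 0.03 s

met <- track_metrics(fts)         # per-track D, displacements, confinement
group_summary(met$confinement)
#> n = 226, median = 0.05387 (IQR 0.03075-0.1288, 95% CI 0.04471-0.06204)

motion_profile(fts)               # per-cell displacement cloud + outline
#> <motion_profile> cell 'mOL_demo': 7744 points, A = 1.629 um^2, p = 5.828 um, circularity = 0.603
```

The median confinement ratio (0.054, `as_printed` mode) reflects the
mostly corralled population, and the circularity of 0.60 the cell's
directed component elongating the motion profile. A full three-stage
comparison runs the whole chain and reports summaries, distributions and
tests:

```r
rep <- run_pipeline(pipeline_config(n_cells = 3, n_tracks = 300, seed = 42))
rep
#> <stage_report>
#>   stages: OPC, eOL, mOL
#>   cells: 9  tracks (post-filter): 1725
#>   median circularity: OPC = 0.820, eOL = 0.682, mOL = 0.543
```

Circularity falls with maturation (motion becomes directed), the
eOL-stage fast-diffusing class is absent while OPC and mOL retain one
(`rep$fast_fraction`: OPC 0.0037, eOL 0, mOL 0.0063 here), and
`rep$tests` holds the Kruskal–Wallis/Dunn and pairwise KS results.
`emit_report(rep, "json")` / `"markdown"` serialize the report;
`pipeline_config(out_dir = ...)` additionally writes per-track metrics
and per-cell summary CSVs.

A thin command-line wrapper lives at `inst/cli/gliotrack.R`
(`simulate`, `metrics`, `detect-track`, `run` subcommands).

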