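---
title: "Motion metrics for single-particle tracking in oligodendrocytes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion metrics for single-particle tracking in oligodendrocytes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliotrack)
```

## The problem

Myelin basic protein (MBP) is a key structural protein of CNS myelin. In
live oligodendrocytes expressing a photoswitchable MBP fusion (e.g.
Dendra2::MBP), sparse photoconversion yields isolated single-molecule
signals that can be tracked frame by frame under TIRF/HILO illumination.
The scientific questions are about how MBP *moves* at three maturation
stages — precursor-cell processes (OPC), early myelinating membrane
"bubbles" (eOL), and mature membrane sheets (mOL) — quantified by three
per-track or per-cell statistics:

* a **diffusion coefficient** per track, from the time-averaged
  mean-squared displacement (MSD):
  \[D \;=\; \frac{1}{K}\sum_{k=1}^{K} \frac{\mathrm{MSD}(\tau_k)}{q\,\tau_k},
  \qquad q = 4 \text{ (2D imaging)}\]
* a **confinement ratio** per track, net over total displacement with a
  duration correction:
  \[r_{\mathrm{conf}} \;=\; \frac{d_{\mathrm{net}}}{d_{\mathrm{tot}}}\cdot t_{\mathrm{track}}\]
* a **circularity ratio** per cell: all of a cell's tracks are re-plotted
  from a common origin ("motion profile"), the cloud's outline is traced,
  and
  \[r_{\mathrm{circ}} \;=\; \frac{4\pi A}{p^2} \in [0, 1]\]
  with \(A\) the outline's area and \(p\) its perimeter — 1 for an
  isotropic (circular) cloud, 0 for a purely linear one.

`gliotrack` implements these metrics, the frequency-binning and
nonparametric statistics used to compare stages, a spot-detection /
linking front-end, and a trajectory/movie simulator so the whole chain is
testable without any microscope data.

## Units and conventions

All coordinates are micrometres, time is seconds; pixel coordinates are
converted at I/O using the pixel size (which has no universal default and
must be supplied). Images use the array convention: origin at the top
left, x rightward along columns, y downward along rows, 0-based frames.
Gaps inside tracks (missed detections bridged by the linker) are kept as
missing frames and never interpolated — interpolation would deflate
displacement variance and bias the MSD.

## The MSD and the diffusion coefficient

`msd_curve()` is the standard time-averaged estimator: for each integer
lag \(k\) the mean of the squared displacement over **all overlapping
frame pairs** \((i, i+k)\) present in the track. Overlapping (rather than
disjoint) pairs use the data maximally and match common SPT practice;
pairs broken by gaps are simply absent from the average.

`diffusion_coefficient()` averages \(\mathrm{MSD}(\tau)/(4\tau)\) over
lags, unweighted. By default **every** available lag enters the average,
which is the literal published protocol and keeps worked examples exact
(a collinear unit-step track of 4 points gives
\(D = \mathrm{mean}(1/4,\, 4/8,\, 9/12) = 0.5\)). This default has a
documented cost: per-lag estimates at long lags average very few
independent segments, so the per-track \(\hat D\) distribution is
right-skewed — its *mean* is unbiased but its *median* sits roughly 15 %
below the true \(D\) for 100-frame Brownian tracks. The `max_lags`
argument exists for exactly this reason: restricting the average to the
first quarter of lags (e.g. `max_lags = 25` on 100-frame tracks) brings
the median within a few percent of truth, and is the setting we recommend
— and use in our own recovery tests — when absolute \(D\) values matter.
Comparative analyses between conditions with similar track-length
distributions are insensitive to this choice, so the pipeline keeps the
all-lag default.

With localization noise of per-axis sd \(\sigma\), the ensemble MSD is
\(4D\tau + 4\sigma^2\); the resulting positive bias in \(\hat D\) is a
property of the estimator, not removed here (no intercept fitting), and
is asserted directionally in the tests.

## The confinement ratio and its three modes

The published formula multiplies \(d_{\mathrm{net}}/d_{\mathrm{tot}}\) by
the track duration in seconds, yet the accompanying text asserts the
ratios "naturally fall between 0 and 1" — which the printed formula does
not guarantee (a straight 0.3-second track scores 0.3; a straight
3-second track scores 3). Rather than silently reinterpreting,
`confinement_ratio()` exposes three modes and records the choice in its
output: `as_printed` (the literal formula; default), `sqrt_duration`
(the square-root correction of the cell-migration literature that the
formula cites, which equalizes the expected ratio of Brownian tracks of
different lengths), and `plain` (the bare ratio in \([0,1]\)). Stationary
tracks (\(d_{\mathrm{tot}} = 0\)) are defined as ratio 0 with a warning.

## Motion profiles and circularity

`motion_profile()` pools every track's origin-zeroed points into one
cloud per cell and traces its outline as the **convex hull** — a
deterministic, parameter-free choice. The hull's shoelace area and summed
edge lengths feed \(4\pi A/p^2\). The hull overestimates circularity for
concave clouds (it cannot trace indentations); since all stages are
scored with the same outline rule, between-stage comparisons are
conservative with respect to this bias. A collinear cloud has zero area
and is defined to score exactly 0; values may exceed 1 only by float
round-off and are clipped within 1e-9.

## The synthetic-data generator

`simulate_tracks()` draws each track's motion model from a mixture:

* `brownian` — isotropic steps, per-axis sd \(\sqrt{2D\,\Delta t}\);
* `directed` — Brownian plus constant drift \(v\,\Delta t\);
* `confined` — Brownian reflected at a circular corral of radius \(R\)
  centred on the track's start.

Reflections (corral and the bounding cell geometry — a rectangle for
processes, discs for bubbles and sheets) use an exact triangle-wave fold
of the radial or axial coordinate; reflecting rather than absorbing or
periodic walls keeps particles inside the region, as curated experimental
tracks are. Track lengths are \(2 + \mathrm{Geometric}(p_{\mathrm{bleach}})\)
frames (memoryless photobleaching), truncated at the acquisition length
(2500 frames at 30 ms by default). Independent Gaussian localization
noise (default 20 nm per axis, matching the tracking-precision scale of
single-molecule experiments) is added to coordinates *after* the
trajectory is built, so trajectory-level tests can switch it off without
touching the camera model. Movie rendering (`render_movie()`) is a
separate layer: Gaussian PSF (3-pixel FWHM by default), Poisson shot
noise and Gaussian read noise, clipped to the 16-bit range.

### Stage presets

`stage_preset()` encodes one cell's study conditions per maturation
stage. The numeric values are package fixtures — chosen once to reproduce
the qualitative stage structure, *not* measurements:

| stage | geometry | mixture |
|---|---|---|
| OPC | 1.2 × 10 µm rectangle | 55 % free (D = 2e-3 µm²/s), 30 % corralled (R = 0.25 µm), 15 % fast free (D = 3e-2) |
| eOL | disc r = 2.5 µm | 80 % free (D = 4e-3), 20 % directed (v = 0.20 µm/s) |
| mOL | disc r = 6 µm | 65 % tightly corralled (R = 0.05 µm, D = 1.5e-3), 12 % fast corralled (R = 0.60 µm, D = 3e-2), 23 % directed (v = 0.45 µm/s) |

Bleaching is 0.06 per frame (0.04 for mOL, whose sheets give longer-lived
tracks), and 1200 tracks are generated per cell so that roughly 650–1500
survive the short-track filter, the curated per-cell scale of such
experiments. Directed components always come in ±v pairs along a per-cell
axis drawn from the seed: profiles elongate (the observed linear motion
profiles) without a net population drift. Three mechanisms make the
presets behave:

* a corral only *registers* in the confinement ratio if its exploration
  time \(R^2/4D\) is shorter than a typical track — mOL's 0.05 µm corral
  binds within a few frames, OPC's 0.25 µm corral barely binds at all;
* the fast class is *shared* between OPC and mOL (same D), so when the
  pooled diffusion range is cut into twelfths both stages populate the
  top third, while eOL — with the fast class removed and only weak drift
  — cannot reach it;
* mOL's drift is large enough that drift × (longest track duration)
  exceeds the fast component's diffusive spread (elongated hull), yet
  small enough that the drift-inflated per-track \(\hat D\) of long
  directed tracks stays below the fast-category boundary.

### What the generator does not emulate

Dendra2 blinking/photophysics, 3D motion and defocus, anomalous
(non-Brownian) diffusion exponents, motion-model switching within a
track, cell-shape irregularity and drift of the field of view. Passing
tests on these synthetic populations therefore validate the *analysis
chain* — estimators, binning, statistics, orderings — not any biological
claim about real MBP data.

## Detection and linking

`detect_spots()` band-passes each frame with a difference of Gaussians at
scales \(\sigma\) and \(2\sigma\) (\(\sigma\) = diameter/2.355), accepts
local maxima whose raw intensity exceeds median + 5 × (1.4826 · MAD) —
robust statistics suit sparse bright spots on a dark background — and
refines positions by a background-subtracted intensity-weighted centroid.
The centroid window is one pixel wider than diameter + 2 and is recentred
iteratively (3 passes): a window clipped tightly around the initial
integer maximum systematically compresses off-centre positions, which
both inflates the localization RMSE and adds spurious frame-to-frame
jitter for stationary emitters.

`link_spots()` is a deliberately simple greedy nearest-neighbour linker
(the multiple-hypothesis trackers of interactive software are out of
scope and their published parameter tables are not text-reproducible):
per frame, candidate pairs within `max_disp_px × frame-gap` pixels are
assigned in order of distance (ties: lower track index, then lower
detection index), unmatched detections open tracks, and ends stay alive
for `max_gap` frames so bridged gaps appear as missing frames. All
closed-loop guarantees (≥ 95 % link recovery, ≤ 0.25 px RMSE) are
established on sparse synthetic movies where emitters are placed with
enough separation that the sparse-field premise holds.

`filter_tracks()` implements the "shorter than 10 frames" curation rule
literally: *frames* counts localizations, and the boundary is inclusive —
a 10-localization track survives. `estimate_precision()` reproduces the
standard calibration: per stationary particle, the sample SD of x and y
across a short series (20 frames by default), reported as mean ± SD
across particles in nanometres. The calibration generator places emitters
with a minimum separation (default 8 px) because overlapping spots
contaminate each other's centroids and corrupt the precision figure.

## Binning and categories

Frequency distributions are comparable across conditions only on a
common scale, so bin edges span the pooled min–max of all conditions:
10 equal bins for confinement, 12 for diffusion. Bins are
left-inclusive/right-exclusive except the last (right-inclusive), so the
pooled maximum is counted. For heavily zero-inflated quantities the first
bin can be dropped *from the graph only* (`drop_first_bin`): percentages
remain percentages of the full population and every statistic uses all
values. Category labels (slow/intermediate/fast; high/medium/light
confinement) default to equal thirds of the bins, are user-overridable,
and are consumed by nothing in the statistics layer — a property the
tests enforce bit-for-bit.

## Statistics

Medians with interquartile ranges summarize every group;
the 95 % CI of the median is the distribution-free binomial
order-statistic interval (conservative, guaranteed ≥ 95 % coverage). A
one-sample Kolmogorov–Smirnov screen against a fitted Normal routes
analyses to nonparametric tests; its p-value is approximate (parameters
estimated from the sample) and is never reported as an inference.
Three-group comparisons use Kruskal–Wallis (tie-corrected H, chi-square
reference) with Dunn's post hoc z-tests, Bonferroni-adjusted over all
pairs — the standard Dunn adjustment, since the original software's
adjustment convention is not documented. Pairwise distribution
comparisons use the two-sample KS test with the asymptotic p-value
(effective \(n = n_a n_b/(n_a+n_b)\); exact small-sample p-values are out
of scope) at a Bonferroni-corrected alpha of 0.05/2 = 0.025, matching a
design in which each sample enters two planned comparisons. Two
replication levels are supported and never mixed within one test: tracks
as replicates (particle-level) or cell medians as replicates
(cell-level, "median of medians").

## Pipeline and reproducibility

`run_pipeline()` chains simulate → filter → metrics → profiles →
distributions → statistics for any set of stage presets. Every cell
derives its own seed from the master seed, so a run is byte-reproducible
(the JSON report embeds the seed and a config hash); the trajectory-level
path is the default, with rendering/detection an explicit opt-in, so
detection noise never silently enters metric-level results. The report
carries, per stage: track counts before/after filtering, median/IQR/CI
summaries at both replication levels, frequency tables, fast-category
fractions, KW + Dunn and pairwise KS results.

Default problem sizes — 10 cells per stage × 1200 tracks per cell for a
full comparison run, 500 tracks × 100 frames for estimator-recovery
checks, 500 replicates for type-I-error calibration — were chosen as the
smallest sizes at which the quantities being checked are stable to well
within their test tolerances.

## Known limitations

* The all-lag \(D\) default is median-biased for long tracks (see above);
  use `max_lags` for absolute quantification.
* The convex-hull outline biases circularity upward for concave motion
  profiles.
* The `as_printed` confinement mode is not bounded by 1 and scales with
  track duration; cross-study comparisons should state the mode.
* The greedy linker has no merging/splitting and will swap identities in
  dense fields; its guarantees hold for sparse single-molecule densities.
* KS p-values are asymptotic; at very small n they are approximate.
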