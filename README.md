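# sptnano

Single-particle tracking and nanoscale-organization analysis for
VA-TIRFM movies of plasma-membrane proteins.

Membrane receptors are organized laterally: some concentrate in
sub-micron, laterally stable nanodomains, others diffuse freely, and
perturbations shift proteins between these regimes.  `sptnano` is an R
package for quantifying both sides of this behaviour from
single-channel fluorescence time series:

* **Mobility** — Laplacian-of-Gaussian spot detection with sub-pixel
  quadratic refinement, exact frame-to-frame linear-assignment linking
  under a hard distance gate (no gap closing), and per-track diffusion
  coefficients `D = slope/4` from an ordinary least-squares fit of the
  first four points of the time-averaged mean square displacement
  (MSD), plus an anomalous exponent α flagging confinement.
* **Organization** — rolling-ball background correction, temporal
  maximum projections, randomized 8-µm intensity line profiles, and the
  spatial clustering index
  `SCI = mean(top 5% of samples) / mean(bottom 5%)`, which is exactly
  invariant to overall intensity scaling, together with an
  intensity-vs-SCI Spearman audit and kymographs.
* **Statistics** — two-tailed Mann–Whitney U, Kruskal–Wallis with
  Dunn's Bonferroni-adjusted pairwise comparisons, and compact letter
  displays.
* **Ground truth** — a simulator of VA-TIRFM-like movies (Brownian,
  confined, and static-clustered particles; integrated Gaussian PSF;
  Poisson noise) that powers the package's parameter-recovery
  validation.

Audience: microscopists and image analysts doing single-particle
tracking of membrane proteins who want a scripted, reproducible,
fully tested alternative to interactive tools for this specific
detection → linking → MSD / SCI → statistics workflow.

## Worked example

Simulate one "cell" of freely diffusing particles (D = 0.05 µm²/s,
20 fps, peak SNR ≈ 10), run the full analysis, and read off both
readouts:

```r
library(sptnano)

cell <- simulate_cell("mobile_dispersed", seed = 7, n_frames = 50)
mv <- cell$movie
mv
#> <spt_movie> 128 x 128 px, 50 frames, 0.1 um/px, 0.05 s/frame

thr <- auto_quality_threshold(mv, diameter = 0.4)
spots <- detect_spots(mv, diameter = 0.4, quality_threshold = thr)
tracks <- filter_tracks(link_spots(spots, max_link_distance = 0.4),
                        min_points = 10, frame_interval = mv$frame_interval)
dt <- track_diffusion(tracks, mv$frame_interval, n_lags = 4)
head(dt, 3)
#>   track_id n_points    D_um2_s intercept_um2     alpha flags
#> 1        1       50 0.05037070 -0.0002066575 0.9969806
#> 2        2       50 0.03394350  0.0007396829 0.9341843
#> 3        3       50 0.06615176 -0.0024989163 1.0184310
median(dt$D_um2_s)
#> [1] 0.0504

proj <- sci_projection(mv, n_frames = 20)
sci_table(proj, mv$pixel_size, cell_id = "demo", seed = 7)[,
    c("cell_id", "line_id", "sci", "mean_intensity")]
#>   cell_id line_id      sci mean_intensity
#> 1    demo       1 12.11323       51.34510
#> 2    demo       2 10.80438       30.16629
#> 3    demo       3  7.12393       15.49346
```

The 59 retained trajectories recover the simulated mobility (median
D̂ = 0.0504 µm²/s vs 0.05 true); each SCI row is one random 8-µm line
on the background-corrected projection — a dispersed mobile protein
scores low compared to the static clustered scenario, where the same
measurement yields SCI medians several-fold higher (run
`simulate_cell("static_clustered", ...)` to see the contrast).

Whole runs — simulation through group statistics, with every
intermediate table, a log, and a manifest — go through
`run_pipeline(default_pipeline_config())` or the command-line wrapper
`inst/cli/sptnano.R` (subcommands `simulate`, `detect`, `track`,
`mobility`, `sci`, `kymo`, `stats`, `all`; YAML configs via
`--config`).

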