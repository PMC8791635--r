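---
title: "Quantifying membrane-protein dynamics and nanoscale organization with sptnano"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-protein dynamics and nanoscale organization with sptnano}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

Variable-angle TIRF microscopy (VA-TIRFM) images the thin optical
section at the plasma membrane, so individual fluorescently tagged
membrane proteins appear as diffraction-limited spots.  Two
complementary readouts characterize how a protein behaves there:

* **Lateral mobility** — detect spots frame by frame, link them into
  trajectories, and estimate a per-particle diffusion coefficient *D*
  from the mean square displacement (MSD).
* **Lateral organization** — proteins concentrated in membrane
  nanodomains produce a punctate, heterogeneous image; the spatial
  clustering index (SCI) quantifies this from intensity line profiles
  of a temporal maximum projection.

`sptnano` implements both readouts end to end, together with the
nonparametric statistics used to compare conditions, and a simulator of
VA-TIRFM-like movies with known ground truth used to validate every
stage.

# Pipeline model and assumptions

## Spot detection

Each frame is convolved with a negated, scale-normalized
Laplacian-of-Gaussian (LoG) kernel.  For a bright disc of diameter $d$
the maximal response is obtained at $\sigma = d / (2\sqrt{2})$, so the
user supplies the expected particle diameter (default 0.4 µm) rather
than a filter width.  Local maxima of the response above a quality
threshold, after non-maximum suppression within one particle radius,
become detections.  Sub-pixel positions come from fitting a 2-D
quadratic to the 3×3 response neighbourhood of the maximum and taking
its stationary point; a refinement displacing by more than one pixel is
considered unstable and falls back to the integer maximum.  The
quadratic scheme is deterministic and, on rendered ground truth at peak
signal-to-noise ratio around 10, localizes to better than 0.1 px RMSE
(~10 nm at 0.1 µm/px); its noiseless sub-pixel bias is below 0.01 px.

The quality threshold is data-dependent and must be supplied;
`auto_quality_threshold()` offers a labelled heuristic (Otsu split of
the LoG local-maxima responses).  Detection runs on raw frames:
background subtraction is a display/SCI operation here, and the
zero-mean LoG kernel already removes local offsets.

## Trajectory linking

Detections in consecutive frames are linked by solving the linear
assignment problem with cost equal to squared Euclidean distance,
under a hard gate (default 0.4 µm): candidate pairs beyond the gate are
forbidden, and every spot owns a "no-link" alternative priced at the
squared gate, the standard augmented-matrix construction.  A link is
therefore made exactly when it is cheaper than leaving both spots
unlinked.  The solver is an exact $O(n^3)$ shortest-augmenting-path
implementation; because links across different connected components of
the within-gate candidate graph are impossible, each frame pair is
first decomposed into components and solved piecewise, which keeps
dense frames fast without approximation.  There is no gap closing: a
missed detection terminates the track, and the particle's later
reappearance starts a new one.  Tracks with fewer than 10 points are
discarded; the track duration convention is
`n_points × frame_interval`, so a 10-point track at 20 fps lasts
500 ms.

## MSD and diffusion

The default MSD estimator is the time-averaged form over all
overlapping pairs,

$$\mathrm{MSD}(k\,\Delta t) = \frac{1}{n-k}\sum_{i=1}^{n-k}
  \left[(x_{i+k}-x_i)^2 + (y_{i+k}-y_i)^2\right],$$

the standard estimator in single-particle tracking.  The
origin-displacement form $(x_k - x_0)^2 + (y_k - y_0)^2$ — one
displacement per lag, all measured from the first point — is also
implemented (`method = "origin"`) because printed formulas in the
field often use it; the time-averaged form is the default since it has
far lower variance and matches how MSD *plots* are produced in
practice.

The diffusion coefficient is a quarter of the slope of an ordinary
least-squares fit of MSD on time lag over the first four lags, with a
**free intercept**: static localization error adds a constant
$4\sigma_{\mathrm{loc}}^2$ to every MSD value, which the intercept
absorbs so the slope (and hence $D$) stays unbiased.  Negative fitted
slopes on noisy short tracks are reported as-is and flagged — clamping
them to zero would bias group medians upward.  A log–log slope over the
same lags gives a coarse anomalous exponent $\alpha$ ($\approx 1$ free,
$< 1$ confined, $\approx 2$ ballistic).

## SCI and kymographs

Each frame is background-corrected by subtracting its grayscale
morphological opening with a 30-px disc (the rolling-ball estimate),
clipping at zero, and 3×3 mean smoothing; the first 20 corrected frames
are max-projected (`sci_projection()`).  Correcting **before**
projecting keeps the shot-noise residual as a strictly positive floor,
so the bottom intensity tail measures the inter-domain level; opening a
projection instead zeroes the bottom tail and degenerates the ratio.
Three 8-µm lines per cell are placed at seeded random positions and
orientations (rejection-sampled inside the cell mask, or inside a 10-px
border margin without one) and sampled at one-pixel spacing by bilinear
interpolation — 81 samples at 0.1 µm/px.  For each profile,

$$\mathrm{SCI} = \frac{\text{mean of the top } k \text{ samples}}
                      {\text{mean of the bottom } k \text{ samples}},
  \qquad k = \max(1, \mathrm{round}(0.05\,n)),$$

which is exactly invariant under multiplicative rescaling of the image;
the package audits this on data with `intensity_sci_correlation()`
(Spearman rank correlation of mean line intensity vs SCI).  If the
bottom-tail mean is zero the measurement is floored at one intensity
quantum and flagged rather than reported infinite.  Kymographs stack
the bilinear line profile across frames: static particles draw vertical
stripes, particles moving along the line draw stripes of slope
$v\,\Delta t / \text{pixel size}$ px per frame.

## Group statistics

Two groups are compared with the two-tailed Mann–Whitney U test (exact
enumeration for combined n ≤ 20 without ties, tie- and
continuity-corrected normal approximation otherwise).  Three or more
groups use the tie-corrected Kruskal–Wallis test followed by Dunn's
pairwise z comparisons on the pooled ranks, Bonferroni-adjusted over
all pairs — the behaviour of GraphPad-style "Dunn's multiple
comparison test" (Šidák is available as an option).  A deterministic
insert-and-absorb compact letter display summarizes the pairwise
pattern, with groups ordered by decreasing mean rank so the letter "a"
marks the highest group.  Both tests depend on the data only through
ranks and are invariant under strictly monotone transforms.

# The synthetic-data generator

`simulate_tracks()` draws per-axis Gaussian increments of variance
$2 D \Delta t$ (Brownian), the same increments reflected at the walls
of a square domain of side $L$ centered on the start position
(confined; the stationary MSD plateau is $L^2/3$, the sum of two
per-axis uniform-difference variances $L^2/6$), or constant positions
(static).  Every particle consumes its own random sub-stream derived
from the run seed and the particle index, so adding or removing
particles never perturbs the others.  `render_movie()` deposits an
integrated Gaussian PSF per emitting particle (exact per-pixel
integral, so photons are conserved) and draws pixel values from
Poisson(background + signal).

Defaults, chosen once as a realistic VA-TIRFM acquisition and used as
the study conditions throughout validation:

| parameter | default | rationale |
|---|---|---|
| pixel size | 0.1 µm/px | 160× objective, 16-µm EMCCD pixels |
| frame interval | 0.05 s | 20 fps acquisition |
| PSF σ | 0.4/2.355 µm | 0.4 µm apparent particle size, FWHM convention |
| photons/particle/frame | 2000 | peak SNR ≈ 10 over background |
| background | 10 photons/px | typical camera + cellular background |
| mobile D | 0.05 µm²/s | membrane-receptor scale mobility |
| confinement side L | 0.4 µm | nanodomain scale |

Scenario presets model whole cells: `"static_clustered"` places 100
four-molecule foci (~0.6 foci/µm², dense punctate organization),
`"mobile_dispersed"` and `"confined"` place 50 single particles
(~0.3/µm², sparse as in the low-expression lines used for tracking).

**What the simulator does not emulate:** motion blur within an
exposure, photobleaching and complex blinking kinetics, EMCCD
multiplication noise, uneven illumination, cell borders and
out-of-focus haze, and protein exchange between domains.  Passing the
validation suite therefore demonstrates the correctness of the
algorithms under the stated image-formation model, not performance on
any particular real data set.

# Numerical choices and edge cases

* LoG kernels are sampled over ±4σ and made exactly zero-mean, so a
  constant image yields a numerically zero response; boundaries are
  replicated.
* Ties in non-maximum suppression are broken deterministically
  (quality, then row, then column); equal-cost assignments resolve by
  the solver's fixed scan order.
* `filter_tracks()` requires `min_points ≥ 2`; `compute_msd()` rejects
  lags beyond the track length; degenerate (all-equal) lags are
  rejected in the diffusion fit; α is skipped with a flag when any MSD
  value is non-positive.
* Line placement fails loudly after a bounded number of rejection
  attempts when no 8-µm line fits the mask.
* All movie exchange is 16-bit TIFF with a plain-text calibration
  sidecar; intensities are photon counts throughout.

# Validation problem sizes

The shipped validation uses: 500 simulated Brownian tracks of 50 points
for diffusion recovery (ground-truth route, and a rendered 500-emitter
movie for the imaging route); 200 confined and 200 free tracks for the
confinement signature; 10 synthetic cells per scenario (×5 seeds in the
test suite) for the organization-vs-mobility contrast; 64 emitters ×3
frames for detection quality; and 2000 null simulations per test for
type-I calibration.  These sizes give Monte-Carlo standard errors
comfortably below the tolerances they are checked against.

# Known limitations

* At the default confined conditions (L = 0.4 µm, D = 0.05 µm²/s,
  50 ms frames) the median four-lag α is ≈ 0.80: the first four lags
  only partially resolve the plateau, so α is a coarse confinement
  descriptor at this confinement ratio.  Larger D/L²·Δt (stronger felt
  confinement) lowers it sharply.
* The exact Mann–Whitney test is discrete: for n = 10 vs 10 its
  attainable level at nominal 0.05 is ≈ 0.043.
* Dunn's z for adjacent groups of three fully separated n = 10 groups
  is bounded at 2.54 by rank arithmetic, so Bonferroni-adjusted p
  cannot fall below ≈ 0.01 in that design — a property of the test, not
  of the implementation.
* No gap closing, merging, splitting, or motion-model prediction by
  design; blinking particles yield split tracks.
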