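---
title: "Quantifying apical–basal nuclear dispersion from 3D time-lapse microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying apical–basal nuclear dispersion from 3D time-lapse microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucdyn)
```

## The measurement problem

During germband extension in the early *Drosophila* embryo, the columnar
epithelium (cells roughly 30–35 µm deep) remodels by cell intercalation, and
nuclei that start in a common apical plane disperse basally. Microtubule
populations — centrosomal arrays and a perinuclear, non-centrosomal pool —
drive and constrain this motion. Quantifying the process from spinning-disk
time-lapse volumes requires a chain of measurements:

1. **Segmentation and tracking** of nuclei in 3D over time.
2. **Positioning**: the depth of each nucleus below the apical surface, and
   the fractions of the population in the apical-most 2 µm (the *exclusion
   zone*, normally nucleus-free), in the apical 10 µm (the apical third of
   the cell), and below it.
3. **Kinematics**: apical–basal velocities and the detection of *active*
   (directed) motion episodes from mean-squared displacement.
4. **Turnover**: FRAP recovery half-times and immobile fractions of the
   microtubule populations.
5. **Intensities**: background-corrected, bleach-corrected, t0-normalized
   ROI measurements around centrosomes, nuclei, and apical cell regions.

`nucdyn` implements this chain and pairs it with a synthetic-scene generator
with full ground truth, so every stage is testable without any raw embryo
data (which the originating studies distribute only on request).

## Segmentation model

Volumes are acquired anisotropically (fine xy, ~1 µm z). The pipeline first
resamples along z by linear interpolation so voxels are isotropic
(`resample_isotropic()`); label volumes use nearest-neighbour resampling
because label identities must never blend. A separable 3D Gaussian
(`gaussian_sigma`, default 0.7 µm) suppresses read noise.

A *rough mask* marks a voxel as nuclear when its intensity exceeds the local
mean over a cubic window (`local_window`, default 8 µm, about 1.5 nuclear
diameters) plus `local_offset` (default 0.4) times the robust 1st–99th
percentile intensity range. The offset is deliberately high: for a bright
object blurred by the PSF, a threshold near half the plateau amplitude
recovers the true object boundary (the half-max contour of a step edge under
a symmetric PSF is the edge), whereas lower offsets sweep in the PSF halo
and inflate every nucleus. These defaults were calibrated on synthetic
scenes; nothing in the source protocol fixes them.

Seeds are obtained by eroding the mask with a ball (`erosion_radius`,
default 1.2 µm), implemented exactly as a Euclidean-distance-transform
threshold. Two automated repairs replace the interactive seed editing of the
original workflow:

* a component whose core erodes away entirely is re-seeded at its internal
  distance-transform maximum — thin objects never silently disappear;
* a component with several well-separated distance-transform maxima is
  split into one seed per maximum (fused nuclei). A maximum counts only if
  it is at least `peak_separation` (default one nuclear radius, 2.2 µm) from
  a stronger one **and** the distance transform dips below 0.7 of the weaker
  peak along the line between them. The valley condition matters: the
  distance-transform ridge of a single elongated ellipsoid offers many
  near-maximal points one radius apart, and without it roughly half of all
  healthy nuclei would be split in two. Both repairs are flagged in the
  per-frame `seed_info` metadata.

The final labels come from a marker-imposed watershed on the
gradient-magnitude volume (nuclear edges are where fluorescence changes
fastest), flooded only inside the rough mask: the background is never
claimed, every seed grows into exactly one label, and labels partition the
mask. The flood is a priority queue keyed by gradient value with FIFO
tie-breaking, so the result is deterministic.

Tracking links each label at frame *t+1* to the frame-*t* label with maximal
voxel overlap, accepted when overlap ≥ `min_overlap_fraction` (default 0.3)
of the new label's size; competing claims resolve by larger overlap, then
smaller centroid distance; anything unmatched starts a new track rather than
guessing.

## Midplane positioning

Nuclei in this tissue are top-heavy, so the widest z-section is a biased
positional readout. Instead, for each nucleus the per-plane cross-sectional
area profile is computed and the *midplane* is defined as the midpoint
between the two half-maximum crossings of that profile, with sub-slice
precision from linear interpolation between adjacent planes. Plateau maxima
use the plateau midpoint; when several crossings exist the outermost ones
are taken. A nucleus whose profile is cut by the imaging volume above
half-max has an untrackable flank and is excluded (`NA`) rather than
assigned a biased depth.

Depths are measured from the apical reference — by default the tissue-wide
apical-most z slice containing foreground at that frame, with a per-label
(per-cell) option; whether the original analysis referenced per cell or per
tissue is not recorded, and on synthetic data the two agree by construction
at t = 0. Each valid nucleus then falls into the exclusion zone (≤ 2 µm,
which also counts as apical), the apical 10 µm, or below; fractions divide
by the valid population per time point, so `apical10 + basal = 1` holds
exactly at every frame.

## Active-motion detection

Depth trajectories are first cleaned with a fifth-order sliding median
(edges padded by repeating end values) — a spike of one point in five
vanishes while ramps pass through. Apical–basal velocity is the
central-difference displacement over a 1-minute window in µm/min; each
nucleus contributes one mean and one peak speed.

For motion classification, a rolling window of `W` points (default 15; at
15 s sampling ≈ 3.5 min) moves along each trajectory. Within each window the
time-averaged MSD uses all overlapping pairs, and the anomalous-diffusion
exponent γ is the ordinary least-squares slope of log MSD versus log τ over
integer lags 4 … ⌊3(W−1)/4⌋ (lags 1–3 are excluded as localization-noise
artifacts; for W = 15 the range is [4, 10]). The fit is unweighted — a
linear fit in log space, not a nonlinear power-law fit. On exact power laws
the estimator returns the exponent to machine precision for any γ in
[0, 2]; it is invariant to rescaling the MSD. Windows with a nonpositive
MSD anywhere in the lag range yield no exponent and are excluded.

A window is *active* when γ > 1 (super-diffusive). Because adjacent windows
share W − 1 points, γ errors are strongly serially correlated: a confined
nucleus that fluctuates above γ = 1 once typically stays there for several
windows. Requiring only two consecutive active windows therefore mislabels
the large majority of confined nuclei as active under realistic localization
noise (0.05 µm SD). The package instead requires a run of `min_run = W`
active windows — sustained super-diffusivity over about one full window
correlation length (~3.5 min) — before a nucleus counts as active; the
permissive single-window call is reported alongside
(`active_single_window`). With this rule, simulated half-ballistic /
half-confined populations are recovered within a few percentage points,
which the test suite verifies.

## FRAP model

Raw measurements are normalized by the two-region formula
`N = ((Ip − b)·Ap) / ((Inp − b)·Anp)` (photobleached region intensity and
area over reference region intensity and area, both background-subtracted);
two reference regions are averaged after background subtraction and area
weighting, correcting focal and biological drift. Time points where the
reference falls to background are dropped and flagged. Both prebleach
conventions are available: raw N, or N rescaled so prebleach = 1.

Recovery is fitted post-bleach (the bleach-frame acquisition itself is
excluded) to the one-phase association
`N(t) = N0 + (plateau − N0)(1 − e^{−kt})`, giving `t50 = ln 2 / k`.
Initialization is derivative-free (plateau from the last-quartile mean, N0
from the first post-bleach point, k from the time to half recovery), and the
Levenberg–Marquardt fit retries from a small ladder of starts with a
port-algorithm fallback, because exponential fits that wander toward k → 0
degenerate numerically. Non-convergence is reported with the solver message,
never papered over with defaults. The immobile fraction is
`(prebleach − plateau)/prebleach`, which reduces to the plain subtraction
when prebleach is normalized to 1 and stays a fraction when it is not;
overshoots (plateau above prebleach) come back negative with a flag.

## ROI quantitation

All ROI membership is pixel-center inclusion with no anti-aliasing, so every
mean equals an exhaustive pixel enumeration exactly — the test suite holds
each operator to a brute-force oracle at 1e−9. Available geometries: disks
(e.g. 2.02 µm centrosome circles), rectangles (1 × 5 µm apical boxes), ring
strokes of 3-pixel width around nuclear contours, and 3-pixel-wide line
scans sampled at pixel pitch. The centrosomal annulus correction subtracts
the local background `(ID_large − ID_small)/(A_large − A_small)` computed
from two concentric disks (15 and 25 px at 0.168 µm/px, rescaled to the
image resolution) from the small-disk mean, and is exactly invariant to
adding a constant to the image. Time series are corrected for
photobleaching by fitting frame means to `a·e^{−bt} + c` and dividing by
`fit(t)/fit(0)` (ratio fallback, flagged, if the fit degenerates), and
normalized so the background-subtracted t0 population mean is 1.

Outlier pruning follows the ROUT idea restricted to the constant
(location) model, which is how it is applied to univariate intensity
samples: robust center (median), robust residual scale (68.27th percentile
of absolute residuals with a small-sample correction), t-distribution
p-values, and a Benjamini–Hochberg step-up at FDR `Q` (default 1%), capped
at 30% of the sample. Samples under 10 points are returned untouched and
flagged. The exact procedure in the commercial implementation is
proprietary; this is documented as an approximation, and removed points are
always reported.

## The synthetic generator: what it emulates, and what it does not

`scene_config()` describes a columnar epithelium of default height 32 µm
(within the 30–35 µm range of the tissue) with ellipsoidal nuclei
(semi-axes 2.5 × 2.2 × 2.2 µm) starting near a common apical plane.
Trajectories mix three classes: *active* nuclei move basally in
constant-velocity runs broken by pauses and brief diffusive interludes (a
3-state process with exponential dwells; defaults 90 s runs at 0.7 µm/min
against 45 s pauses give time-averaged speeds around 0.45 µm/min, the scale
reported for unperturbed embryos — the dwell statistics themselves are
stand-ins, not estimates, since no protocol reports them); *diffusive*
nuclei follow a Gaussian random walk (default D = 0.1 µm²/min); *confined*
nuclei follow a mean-reverting Ornstein–Uhlenbeck walk with stationary SD of
half the confinement radius and a 30 s relaxation time. Depth reflects at
the apical surface z = 0 (so exclusion-zone invasion remains simulable) and
at the basal cell boundary.

Rendering rasterizes unit-amplitude ellipsoids over a dim background on an
anisotropic grid (default 0.5 × 0.5 µm laterally, 1 µm axially), blurs with
a Gaussian PSF (default σ = 0.9 µm axial, 0.35 µm lateral), applies optional
exponential photobleaching, then Poisson shot noise and additive Gaussian
read noise. Ground-truth labels are returned unblurred and noise-free, with
overlapping-nucleus voxel counts flagged. Identical seeds give bit-identical
scenes.

Deliberately not modeled: spherical aberration or depth-dependent PSFs,
camera gain maps, nuclear shape changes (grooves, cortical deformation),
membrane channels, and cell intercalation itself. Passing the recovery tests
therefore demonstrates correctness of the measurement chain under a
well-behaved optical model, not robustness to every artifact of live embryo
imaging.

## Numerical choices and validation sizes

* Resampling preserves the physical z extent to within half a voxel and
  clamps at the boundary slices; constants pass through exactly.
* The distance transform is the exact squared Euclidean transform
  (separable lower-envelope algorithm), so ball erosion is exact.
* Watershed ties break by insertion order (FIFO), making the whole
  segmentation path deterministic; the test suite hash-compares repeated
  runs and full pipeline reruns.
* γ fitting is a closed-form OLS slope; no iterative optimizer is involved.
* Nonlinear fits (FRAP, bleach) use Levenberg–Marquardt with multiple
  starts and a `port` fallback; the failure mode this guards against is a
  rate parameter at its bound, where the Jacobian is singular.
* The validation suite exercises: 40-nucleus scenes at SNR 5 for
  segmentation recovery (precision/recall ≥ 0.95, mean IoU ≥ 0.7), 20-frame
  12-nucleus scenes for link accuracy (≥ 99%), 100-trajectory populations
  per motion class for exponent calibration (ballistic mean γ in
  [1.6, 2.2], Brownian in [0.7, 1.3], confined < 1), 50-replicate FRAP
  recovery at 5% noise (median t50 error ≤ 10%, immobile-fraction error
  ≤ 0.05), and brute-force oracles for every ROI operator. These sizes keep
  the whole suite under a minute while leaving the statistical margins
  comfortable.

## Worked example

```{r example, eval = FALSE}
cfg <- scene_config(grid_shape = c(33L, 96L, 96L), n_frames = 20L,
                    n_nuclei = 9L, rng_seed = 1L)
truth <- generate_trajectories(cfg)
scene <- render_volume(truth)

seg <- segment_series(scene$volume)
metrics <- midplane_metrics(seg$labels)
category_fractions(setNames(metrics[metrics$valid, c("frame", "midplane_um")],
                            c("frame", "depth_um")))

motion <- analyze_motion(seg$tracks)
motion$percent_active

frap <- analyze_frap(generate_frap(frap_truth_config(k = log(2) / 10,
                                                     plateau = 0.8,
                                                     noise_sd = 0.02)))
frap$t50; frap$immobile_fraction
```

## Known limitations

* The apical reference on real data depends on the foreground threshold of
  the segmentation; a systematic segmentation bias shifts all depths
  together (category fractions are robust to this only insofar as the bias
  is small against the 2 µm and 10 µm boundaries).
* The active-motion call depends on `W` and `min_run`; both are exposed, and
  cross-condition comparisons should hold them fixed.
* The ROUT implementation is a location-model approximation at the stated
  FDR, not a reimplementation of the proprietary original.
* Track linking is overlap-only; it does not handle division, long
  occlusion, or objects leaving and re-entering the volume.
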