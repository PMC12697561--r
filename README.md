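# nucdyn

Quantitative analysis of apical–basal **nuclear dispersion** in columnar
epithelia imaged by 3D fluorescence time-lapse microscopy — the kind of
measurement used to study how microtubule populations reposition nuclei
during *Drosophila* germband extension. The package is aimed at cell and
developmental biologists who need reproducible, scriptable versions of the
measurements usually assembled by hand from FIJI, MATLAB and Prism:

* **3D nuclear segmentation**: isotropic z-resampling, Gaussian
  preprocessing, local-threshold rough masks, erosion-derived seeds, and a
  marker-imposed **watershed on the intensity gradient** (nuclear edges are
  where fluorescence changes fastest), with automated splitting of fused
  seeds.
* **Tracking** by maximal voxel overlap between consecutive frames.
* **Positioning**: the nuclear **midplane** — the midpoint between the two
  half-max flanks of the per-plane cross-sectional-area profile — and the
  population fractions in the apical-most 2 µm (exclusion zone), the apical
  10 µm, and below.
* **Kinematics**: 1-minute-window apical–basal velocities (per-nucleus mean
  and peak, µm/min) and rolling-window MSD classification of **active
  motion**: within each window of W points, MSD(τ) ∝ τ^γ is fitted as an
  OLS slope in log–log space over lags 4 … ⌊3(W−1)/4⌋, and γ > 1 marks
  super-diffusive (actively transported) episodes.
* **FRAP**: two-region normalization N = ((Ip−b)·Ap)/((Inp−b)·Anp),
  one-phase association fit N(t) = N0 + (plateau−N0)(1−e^(−kt)),
  t50 = ln 2 / k, and immobile fraction = prebleach − plateau (relative to
  prebleach).
* **ROI quantitation**: disk/ring/rectangle/line-scan means with
  pixel-center inclusion (exactly reproducible by brute-force enumeration),
  concentric-annulus background correction, exponential bleach correction,
  t0 normalization, and ROUT-style FDR outlier removal.
* A **synthetic-microscopy generator** (`scene_config()`,
  `generate_trajectories()`, `render_volume()`, `generate_frap()`) with
  complete ground truth, so the whole chain is validated end-to-end without
  any proprietary imaging data.

See `vignettes/nuclear-dispersion-analysis.Rmd` for the models, parameter
choices, and validation design.

## Worked example

Simulate a small epithelium, segment and track it, and compute the dispersion
metrics:

```r
library(nucdyn)

cfg <- scene_config(grid_shape = c(33L, 96L, 96L), n_frames = 20L,
                    n_nuclei = 9L, rng_seed = 1L)
truth <- generate_trajectories(cfg)
scene <- render_volume(truth)
scene$volume
#> <volume_series> 20 frame(s), 33 x 96 x 96 (z,y,x) voxels of 1 x 0.5 x 0.5 um, dt = 15 s

seg <- segment_series(scene$volume)
metrics <- midplane_metrics(seg$labels)
head(metrics, 4)
#>   track_id frame t_s midplane_um valid category
#> 1        1     1   0    4.416667  TRUE apical10
#> 2        2     1   0    4.434211  TRUE apical10
#> 3        3     1   0    4.326389  TRUE apical10
#> 4        4     1   0    4.381579  TRUE apical10
```

All nine nuclei sit 4–5 µm deep — in the apical 10 µm but outside the 2 µm
exclusion zone, as configured:

```r
fr <- category_fractions(setNames(metrics[metrics$valid, c("frame", "midplane_um")],
                                  c("frame", "depth_um")))
head(fr, 3)
#>   frame n_valid exclusion apical10 basal
#> 1     1       9         0        1     0
#> 2     2       9         0        1     0
#> 3     3       9         0        1     0

motion <- analyze_motion(seg$tracks)
motion$percent_active
#> [1] 77.77778
summary(motion$per_track$mean_speed_um_min)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.1475  0.2480  0.4121  0.3771  0.4940  0.6629
```

78% of nuclei show sustained super-diffusive (γ > 1) episodes — the scene
was generated with a 70/15/15 active/diffusive/confined mix — and median
speeds land near the 0.4–0.5 µm/min scale typical of unperturbed embryos.
A synthetic FRAP experiment closes the loop on the recovery fit:

```r
frap <- analyze_frap(generate_frap(frap_truth_config(k = log(2) / 10,
                                                     plateau = 0.8,
                                                     noise_sd = 0.02)))
frap$fit
#> <frap_fit> plateau = 0.8074, k = 0.06703 1/s, t50 = 10.34 s (converged, n = 59)
as.numeric(frap$immobile_fraction)
#> [1] 0.1946567
```

The generative truth was t50 = 10 s and immobile fraction 0.2; the fit
recovers both within the 2% measurement noise.

A thin command-line front end over the same functions lives at
`inst/cli/nucdyn.R` (`simulate`, `segment`, `metrics`, `msd`, `frap`,
`run-all` subcommands), and `run_pipeline()` drives the whole chain with a
manifest and per-stage CSV artifacts.

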