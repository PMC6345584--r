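# fluorquant

Quantitative analysis of receptor-trafficking fluorescence microscopy
experiments, built for studies that follow a membrane receptor through
detection at the cell surface, internalization into vesicles, routing to
lysosomes, and exchange at the plasma membrane — the kind of evidence
that combines confocal imaging, FRAP, single-cell migration assays,
FLIM-FRET and microscale thermophoresis in one paper. Every analysis is
paired with a seeded synthetic-data generator with recorded ground
truth, so the whole pipeline is testable end to end without any external
data.

## What it computes

**Vesicle detection** (`detect_vesicles`, `vesicle_timecourse`).
Diffraction-limited puncta are isolated with the undecimated B3-spline
(à trous) wavelet transform: detail plane *j* is the difference of
successive smooths with the kernel `[1,4,6,4,1]/16` dilated by
`2^(j-1)`. Each plane in `scales_used` is hard-thresholded at
`k · MAD/0.6745` of the plane, the support mask is where the product of
retained planes is positive, touching spots are split by a seeded
watershed on the multiscale product, and per-vesicle area, centroid and
intensity are measured on the raw image.

**Colocalization** (`pearson_coloc`, `vesicle_overlap`,
`leading_edge_roi`, `membrane_band`, `intensity_levels`,
`facs_surface_level`). Pearson correlation of paired pixel intensities
within whole-cell or leading-edge ROIs; object-pixel overlap
`|A∩B| / |A|` between segmented channels; surface vs total receptor
levels from membrane-band and whole-cell masks; flow-cytometry
background subtraction.

**FRAP kinetics** (`normalize_trace`, `fit_recovery`). Traces are
normalized to the prebleach mean and corrected for acquisition fading by
the whole-image ratio, then fitted to
`F(t) = plateau − (plateau − floor)·e^(−kt)`, reporting
`t½ = ln 2 / k` and the percentage mobile fraction
`100·(plateau − floor)/(1 − floor)`.

**Migration speeds** (`track_speed`, `condition_summary`). Per-cell mean
speed as total path length over elapsed time (10-min frame interval by
default), aggregated per condition with cells as the experimental unit.

**Binding affinity** (`fit_kd`, `fraction_bound`). The quadratic
single-site mass-action model with ligand depletion,
`f = [(K_d + L + T) − √((K_d + L + T)² − 4LT)] / 2T`
at fixed labeled-target concentration (50 nM default), fitted to
thermophoresis titrations with the two plateaus profiled out linearly
and K_d searched deterministically in log space.

**FLIM-FRET** (`fit_lifetime`, `fret_efficiency`). Mono-exponential
tail fit of photon-decay histograms by Poisson maximum likelihood, and
`E = 1 − τ_DA / τ_D`.

**Synthetic data** (`make_vesicle_scene`, `make_frap_series`,
`make_tracks`, `make_titration`, `make_decay`). Gaussian-spot
two-channel scenes with an exact colocalized fraction, FRAP recoveries
with photofading, persistent random walks, saturation titrations and
multinomial photon decays — all seeded, all with the generating truth
returned alongside the data.

**Orchestration** (`run_config`, `run_pipeline`, `read_image_stack`).
YAML-configurable staged runs with strict config validation, 16-bit
TIFF / CSV / JSON I/O, and a manifest of MD5 checksums that is
byte-identical across reruns of the same config and seed. A thin CLI
lives at `inst/scripts/fluorquant.R`.

## Worked example

```r
library(fluorquant)

# a two-channel scene: 20 spots, half duplicated into channel B, SNR 10
truth <- scene_truth(n_vesicles = 20, shape = c(128, 128),
                     coloc_fraction = 0.5, vesicle_amplitudes = 100,
                     noise_sigma = 10, seed = 3)
scene <- make_vesicle_scene(truth)
va <- detect_vesicles(scene$channel_a)
va
#> <vesicle_set> 20 vesicles in 128 x 128 px image
#>   area: median 20.0 px (range 18-24)
vesicle_overlap(va, detect_vesicles(scene$channel_b))$overlap_fraction
#> [1] 0.4716049

# FRAP: recovery at k = 0.0231/s from floor 0.2 to plateau 0.8
trace <- make_frap_series(frap_truth(rate_k = 0.0231, mobile_fraction = 0.75,
                                     postbleach_floor = 0.2), n_post = 36)
fit_recovery(normalize_trace(trace))
#> Mono-exponential FRAP recovery fit
#>   rate k          : 0.0231 /s
#>   t1/2            : 30.01 s
#>   plateau / floor : 0.8 / 0.2
#>   mobile fraction : 75.0 %
#>   residual RMS    : 5.55e-17 (36 points)

# binding affinity from a 16-point titration at 50 nM labeled protein
series <- make_titration(binding_truth(kd = 250e-9), 1e-9 * 2^(0:15))
fit_kd(series)
#> Quadratic mass-action binding fit
#>   Kd               : 2.5e-07 M (250 nM)
#>   plateaus         : unbound 800, bound 860
#>   residual RMS     : 1.38e-09 (16 points)
```

The detected overlap fraction (0.47) sits near the generating truth of
0.5 — the residual gap is segmentation noise at spot boundaries — and
the noiseless FRAP and K_d fits return their generating parameters to
numerical precision.

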