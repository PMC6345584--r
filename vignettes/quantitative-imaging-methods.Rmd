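---
title: "Models and methods behind fluorquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fluorquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorquant)
```

fluorquant packages the bespoke quantitative analyses of a
receptor-trafficking imaging study — vesicle detection and
colocalization, FRAP kinetics, migration speeds, binding affinity and
FLIM-FRET — together with the synthetic generators needed to validate
each of them against known ground truth. This vignette explains the
models, the tunable parameters, and the design choices that were
genuinely open, and states what the passing tests do and do not show
about real data.

## Vesicle detection

The detector assumes vesicles are diffraction-limited puncta: isotropic
intensity peaks a few pixels wide on a slowly varying cytoplasmic
background with pixel-scale noise. The undecimated (à trous) B3-spline
wavelet transform separates these regimes by scale. Detail plane $j$ is
the difference between successive smooths with the separable kernel
$[1,4,6,4,1]/16$ whose taps are spaced $2^{j-1}$ pixels apart, with
mirror boundary handling; the planes plus the coarse residual
reconstruct the image exactly (a telescoping identity the test suite
asserts to below $10^{-9}$ relative error). Spot-sized structure
concentrates in the mid-scale planes; plane 1 is pixel-noise dominated
and the residual carries the background.

Detection proceeds by hard-thresholding each detail plane in
`scales_used` at `threshold_k` times the plane's robust noise scale,
estimated as $\mathrm{MAD}/0.6745$ so it is calibrated to the standard
deviation under Gaussian noise. Because the threshold scales with the
data, the detected label map is invariant to any positive rescaling of
the image — one of the tested properties. The support mask is where the
product of the retained planes is positive; touching spots are split by
a seeded watershed (region growing on the multiscale product), with
seeds at local maxima of the product no closer than 2 px. Photometric
peaks separate abutting near-circular spots better than the distance
transform, which is blind to intensity. Per-vesicle intensities are
always measured on the raw image, never on wavelet coefficients, which
are not proportional to fluorophore amount; centroids are
intensity-weighted.

Defaults — `n_scales = 3`, `threshold_k = 3`, `scales_used = {2, 3}`,
`min_area = 4` — are calibration choices for spots of point-spread
width $\sigma \approx 1.5$ px at signal-to-noise ratios (peak amplitude
over noise standard deviation) of about 10 and above. At those
conditions the suite requires recall and precision of at least 0.95
with sub-pixel centroid error over 20 seeded scenes. Whether watershed
splitting should run on all components or only large ones is not
resolvable from typical method descriptions; here it is a global
switch, `split_touching`.

## Colocalization and intensity levels

Pearson colocalization is the correlation of paired pixel intensities
inside an ROI, computed on raw intensities without Costes
auto-thresholding: raw-pixel Pearson is the exactly testable headline
statistic, and automatic thresholding variants are left as future work.
ROIs are either whole-cell masks, a fixed-width band around a
leading-edge polyline (every pixel within half the width, Euclidean, of
the path; default width 10 px), or a membrane band. The membrane band
is the cell mask minus its inward erosion, with a box structuring
element so a width-3 band of a $21\times21$ square is exactly
$21^2-15^2$ pixels; the default width of 3 px for "surface" levels is a
declared choice, since the physical band a manual analysis integrates
over is rarely stated. Manual thresholding of cells is operationalized
as an explicit user-supplied mask, recorded in the run config.

Object overlap is asymmetric — the fraction of channel-A vesicle pixels
lying inside channel-B vesicle pixels — matching the reading of
"receptor-positive vesicles colocalizing with the lysosome channel",
with B the reference compartment. On synthetic scenes where a known
fraction of channel-A vesicles is duplicated exactly into channel B,
the measured overlap tracks the truth closely but carries a downward
bias that grows with the colocalized fraction: the two channels are
segmented independently under independent noise, and each ~20 px spot
mask disagrees with its twin on roughly two boundary pixels, because
the threshold decision at the mask edge flips with probability near
one-half where the wavelet coefficient sits at the threshold. At SNR 10
this boundary-noise floor is about 0.07 at full colocalization and
scales roughly linearly with the colocalized fraction. Mask
regularization (morphological closing, hysteresis thresholding) does
not remove it. Users comparing overlap across conditions are unaffected
(the bias is common mode), but absolute overlap values should be read
with this floor in mind.

Flow-cytometry surface levels subtract the mean (or, by flag, median)
of a background event population from the sample population, floored at
zero; the statistic is a choice, since method texts rarely state it.

## FRAP kinetics

Traces are normalized as
$f(t) = \dfrac{\mathrm{roi}(t)}{\overline{\mathrm{roi}}_{pre}} \cdot
\dfrac{\overline{\mathrm{whole}}_{pre}}{\mathrm{whole}(t)}$,
with prebleach means over the first three frames by default (a
parameter). Because the correction is a ratio, any fading common to the
ROI and the whole image cancels exactly; the synthetic generator
composes fading multiplicatively on both traces in absolute acquisition
time precisely so that this inversion is exact on noise-free data, and
the suite asserts it to $10^{-9}$.

The recovery model is $F(t) = P - (P - F_0)e^{-kt}$ with the
post-bleach floor $F_0$ fitted rather than pinned to the first
post-bleach frame, reducing single-frame noise sensitivity. Reported
are $k$, $t_{1/2} = \ln 2 / k$, the plateau, and the percentage mobile
fraction $100\,(P - F_0)/(1 - F_0)$ — the recovered span over the
bleached span, the standard definition where a method text says only
"percentage mobile fraction (plateau)". The initializer is
deterministic (floor from the first post-bleach point, plateau from the
mean of the last three, $k$ from the midpoint-crossing time by linear
interpolation), so refitting identical data gives identical answers; a
perfectly flat trace short-circuits to a flagged non-recovering fit
rather than a singular least-squares problem. Fits with plateau below
floor are flagged non-recovering; mobile fractions outside $[0, 100]$
are clipped and flagged, with the raw value retained. A residual
bootstrap (`frap_boot_ci`) provides percentile intervals for $k$.

Default acquisition geometry follows the emulated experiment: 5 s
frames, 3 prebleach frames, a 25 px diameter circular bleach ROI for
the stack-extraction helper, and 3 minutes of post-bleach imaging (36
frames) in the test conditions.

## Migration speeds

A cell's mean speed is total path length over elapsed time, from
Euclidean steps between consecutive frame positions at a 10-minute
default frame interval. Missing frames are bridged with one straight
step over the full gap duration and flagged, matching how trackers
export dropped frames; for gap-free tracks this coincides with the mean
of instantaneous speeds, so the ambiguity between the two conventions
is moot. Condition summaries average per-cell means with the SEM over
cells — cells, not steps, are the experimental unit. Exclusion of
dividing or colliding cells is an upstream human step; the module
consumes the tracks it is given.

The generator produces persistent random walks: gamma-distributed step
lengths (mean speed times interval; coefficient of variation 0.3 by
default, a realistic within-cell speed variability) and wrapped-normal
heading increments whose angular spread is set so the expected
step-direction correlation equals the persistence parameter
(default 0.7, an ordinary value for migrating epithelial cells).
Neither value is critical to the speed estimator, which is exact per
track by construction.

## Binding affinity and FLIM-FRET

Thermophoresis titrations at fixed labeled-protein concentration $T$
(default 50 nM) are fitted with the quadratic mass-action model with
ligand depletion:
$f(L) = \dfrac{(K_d + L + T) - \sqrt{(K_d + L + T)^2 - 4LT}}{2T}$,
the physical root of single-site equilibrium, which reduces to the
hyperbola $L/(L + K_d)$ as $T \to 0$ — so using it is conservative even
when depletion is negligible. The response is
$u + (b - u)\,f(L)$; at any fixed $K_d$ the plateaus $(u, b)$ enter
linearly and are profiled out by linear least squares, leaving a
one-dimensional profile over $\log_{10} K_d$ that is scanned on a fixed
grid over $[10^{-10}, 10^{-3}]$ M (with three fixed anchor points) and
polished by golden-section search — deterministic, with no random
starts. A $K_d$ landing on a search bound is flagged as unresolved
affinity. Raw-versus-normalized response units are deliberately not
modeled: the fit estimates both plateaus from whatever monotone signal
is supplied.

Fluorescence lifetimes are fitted as a mono-exponential tail by Poisson
maximum likelihood over bins at or beyond `fit_start` (default 0.5 ns),
which must be past the instrument-response region — full IRF-convolved
or multi-exponential decay analysis is out of scope. For multinomial
counts the likelihood depends on $\tau$ only through the bin
probabilities renormalized over the fitted window, so an
exact-exponential histogram returns its generating $\tau$ to numerical
precision, and a flat histogram drives $\tau$ to the search bound and
is flagged rather than silently returned. FRET efficiency is
$E = 1 - \tau_{DA}/\tau_D$; the donor-only reference lifetime is an
explicit input, since the reference used by any particular instrument
analysis is rarely recoverable from a paper. Per-cell mean efficiency
is computed from the cell's fitted mean lifetime (aggregation order is
otherwise unstated in typical reports); a per-pixel mode can be built
from the same primitives.

## Synthetic data: what it does and does not emulate

The generators cover the study's input space with exact bookkeeping:
Gaussian spots of $\sigma = 1.5$ px (the spot model the à trous
detector assumes), additive Gaussian noise (simpler SNR bookkeeping
than Poisson; SNR is defined as peak amplitude over noise sigma),
colocalized duplicates sharing centers exactly by default so overlap
truth is exact (jitter is optional), uniform background. Imaging SNR
and vesicle density of the emulated experiments are unstated in the
source material; SNR 10 and up to 25 spots per $128^2$ px are declared
calibration conditions. Not emulated: realistic optics beyond the
Gaussian PSF, camera gain/offset, Poisson-dominated shot noise (an
option exists in spirit but defaults are Gaussian), cell-shape
morphodynamics, vesicle motion within a frame. Passing tests therefore
demonstrate algorithmic correctness and calibrated accuracy under these
conditions — not performance on arbitrary real microscopes, where
background texture and clumped vesicles will dominate the error budget.

Seeds are mandatory arguments everywhere, never global state: the
caller's RNG is saved and restored, the RNG kind is pinned, and every
generator derives named substreams from its seed, so identical truth
plus seed is bit-identical output. The pipeline runner derives each
stage's seed from the single config seed the same way, which is what
makes whole runs byte-identical — the manifest records MD5 checksums
keyed by file name (timestamps go to the log, not the manifest, so
manifests compare equal across reruns).

## Numerical choices and problem sizes

Mirror (whole-sample reflect) boundaries everywhere in the transform;
0-based (row, col) pixel coordinates; areas in pixels, converted to
$\mu m^2$ only when a pixel size is provided. Tied twin peaks in the
watershed seeding are accepted within a $10^{-9}$ relative tolerance so
exactly symmetric doublets seed both maxima. The Kd profile tolerance
is $10^{-10}$ in $\log_{10}$ space; the lifetime search spans
$[10^{-4}, 10^{3}]$ times the fit window.

The validation suite uses 20-seed batches for imaging recovery
statistics, 100 seeds for the FRAP and Kd noise-recovery medians, 50
for lifetime recovery, 200 cells for migration-speed recovery, and
$128 \times 128$ px scenes throughout — sizes chosen to give stable
medians and means for the quantities checked while keeping the full
suite interactive.

## Known limitations

No Manders coefficients or Costes randomization; no FCS binary parsing
(events arrive as CSV); no reaction–diffusion or two-component FRAP
models; no vesicle tracking across frames (per-frame counts only); no
3-D segmentation; no hypothesis testing (that belongs to downstream
statistics tools). The object-pixel overlap bias at high colocalization
described above is the one accuracy limit of practical note.
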