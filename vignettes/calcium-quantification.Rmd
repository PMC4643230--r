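---
title: "Quantifying global calcium responses in single cells: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying global calcium responses in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Non-excitable cells such as T lymphocytes signal through transient,
cell-wide ("global") rises of cytoplasmic Ca²⁺. Loaded with a
non-ratiometric indicator such as Fluo-4 — whose emission can grow up to
~100-fold on calcium binding — and dropped onto a stimulating surface,
each cell produces a characteristic intensity history: a dim, mobile
phase while it floats above the focal plane; a small step up in
brightness when it *lands* (enters the focal plane at the glass) and
stops moving; and, if receptor triggering succeeds, a sharp
calcium-driven rise followed by a slow decay. From a single wide-field
time-lapse movie containing hundreds of such cells one wants, per cell,
the landing time, whether and when it triggered, and the response shape;
and per population, the responder fraction, the mean aligned response
curve and the distribution of the triggering interval
$T = t_{\mathrm{triggering}} - t_{\mathrm{landing}}$.

`calquant` implements this pipeline end to end:
segmentation and tracking → landing detection and inclusion filters →
trace extraction, smoothing and normalization → derivative-based event
detection and responder classification → population summaries, plus a
synthetic-movie generator with per-cell ground truth so that every
stage can be validated by parameter recovery without any external data.

## Trace model and normalization

Each cell's per-frame intensity $I(t)$ is the arithmetic mean of the
movie over the cell's mask. Traces are smoothed with a Savitzky–Golay
filter (default window 7 frames, polynomial order 2: the smallest
window that suppresses single-frame shot noise at 2 Hz without
flattening a rise of a few seconds), then normalized as
$R(t) = I(t)/I_{\max}$ so every curve peaks at exactly 1. The baseline
$I_0$ is the median intensity over a short window (default 5 s)
immediately *after* landing and before any triggering candidate;
pre-landing samples are deliberately excluded because the cell is then
below the focal plane and artificially dim. The absolute quantities
$I_0$ and $dI = I_{\max} - I_0$ are kept alongside the normalized
curve: the fold-increase $dI/I_0$ is both the responder criterion and a
dye-loading/background robustness metric, being invariant under any
global intensity rescaling.

The baseline window is specified in seconds, not samples, so that when
a trace is decimated to emulate a slower camera the baseline does not
stretch across the transient itself.

## Event detection

Both landing (small step) and triggering (large rise) appear as peaks
in $\mathrm{d}R/\mathrm{d}t$ (central differences on the uniform frame
grid). Landing itself is detected from motion, the more direct signal:
it is the first frame from which the centroid displacement stays below
`motion_stop_threshold` (default 0.25 px/frame) for
`motion_stop_frames` (default 8) consecutive frames, with the cell
persisting to the end of the movie. The defaults separate the two step
populations cleanly in the synthetic regime: stationary centroid jitter
stays below ~0.15 px/frame at typical signal-to-noise, while a mobile
cell rarely produces eight consecutive sub-quarter-pixel steps, so
false early landings are negligible. Data with different noise or
mobility may need these re-tuned; both are exposed in `run_config()`.

The triggering peak is the largest local maximum of
$\mathrm{d}R/\mathrm{d}t$ after the landing peak with topographic
prominence at least `peak_min_prominence`; by default the floor adapts
per cell to 3 robust standard deviations of the pre-landing derivative,
since the landing step is small and cell-dependent. The triggering
*time* is taken at transient onset — the sample where the derivative
last rises through 10 % of the peak height before the peak — because
the quantity of interest is the beginning of the calcium response, not
its steepest point. On synthetic movies at 2 Hz this onset estimate
sits half a frame early on average and within one second of the truth
for essentially all responders.

A responder must satisfy all three of: a triggering peak exists;
$dI/I_0$ exceeds `response_threshold` (default 5, i.e. a >500 %
increase over background — a user-settable convention); and $R(t)$
subsequently decreases, shedding at least `decrease_fraction`
(default 0.2) of its above-baseline excursion before the movie ends. A
monotone drift upward therefore never counts, however large. The
alternative reading of the threshold as $I_{\max}/I_0 > 5$ is available
via `threshold_mode = "ratio"`.

For population averaging, every curve's time axis is aligned with zero
placed `align_offset` (default 2 s) after its landing event.

## Segmentation and tracking

Per frame, candidate cells are connected components above an intensity
threshold, gated by area. The threshold is the frame median plus 4
robust SDs (MAD): a histogram-valley (Otsu) rule is selectable but
fails on exactly the frames that matter here, because one triggered
cell can stretch the dynamic range 20–100-fold and push the valley
above the dim, freshly landing cells. Background is removed as a
per-frame spatial median rather than a temporal median per pixel — a
landed cell occupies one spot for most of the movie, so a temporal
median would absorb the cell itself.

Masks are linked across frames by nearest-centroid association with a
gate of one cell diameter per frame (ties broken toward the smaller
cell id). Two tracks competing for the same nearest region, or a mask
whose area suddenly jumps by more than half, indicate touching cells;
such cells are flagged and later excluded, mirroring the exclusion of
events where cell boundaries overlap. Cells are further excluded when
they land after `landing_window` (default 300 s) or sit closer than one
own diameter to the image border at landing.

Each included cell's mask is refined once, at its landing frame, by
distance-regularized level-set evolution (DRLSE) and — the cell being
stationary from landing onward — reused for all later frames. The
implementation follows the standard edge-based DRLSE energy: a
double-well distance regularizer (weight `mu`) that keeps the level-set
function a signed distance function near its zero level without
re-initialization, an edge-weighted length term (`lambda_`) and an
edge-weighted area/balloon term (`alpha`, negative = inflate), with the
edge indicator $g = 1/(1+|\nabla G_\sigma * I|^2)$. Evolution runs in
two phases: a balloon phase (defaults `alpha = -5`, `sigma = 0.8`, 200
steps) grows the seed toward the boundary, then a refinement phase (100
steps with the area term off and the Dirac band widened to 2.5 px) lets
the edge-attraction term settle the contour onto the gradient ridge.
The refinement phase matters: the balloon alone stalls at the foot of
the edge-indicator moat, typically a fraction of a pixel to two pixels
inside the true boundary. After evolution the mean of
$||\nabla\phi| - 1|$ over the narrow band is checked to stay below 0.2,
the defining distance-regularity property; divergence (an emptied or
flooded contour) is reported as an error naming the parameter set.

## The synthetic scene generator

`generate_movie()` renders cells as uniform-intensity disks over a
constant background with Gaussian camera noise (Poisson shot noise
optional). Each cell random-walks (mean step `diffusion_step_px`)
until its landing frame, is strictly stationary afterwards, and is
dimmed by `landing_step_factor` (default 1.3) before landing to
reproduce the small focal-plane step. A responder's mean intensity then
follows $I_0 + dI\, g(t - t_{\mathrm{trigger}})$ with the normalized
saturating-exponential-rise/exponential-decay shape

$$g(t) \propto \bigl(1 - e^{-t/\tau_r}\bigr)\, e^{-t/\tau_d}, \qquad
  \max_t g = 1 .$$

Defaults describe the reference acquisition regime: a 512 × 512 px
field, 600 frames at 2 Hz, ~200 cells of radius ~5 px, 60 % responders
with $dI/I_0$ uniform on [5.5, 20], landing uniformly within the first
50 s and triggering 50–200 s after landing. Kinetic constants
($\tau_r = 3$ s, $\tau_d = 40$ s) are assumptions chosen to give the
characteristic sharp-rise/slow-decay shape; published sources describe
that shape only qualitatively, so these are package choices, not
measured values. Landing times are kept early enough that the full
transient, including the decay needed by the "subsequent decrease"
criterion, fits inside the 300 s movie. One transient per responder is
modeled; oscillatory responses are out of scope. Initial placements
are rejection-sampled at one-diameter centroid separation and the
density/mobility defaults keep mask-overlap exclusions a small
minority, emulating an experiment run at a suitable cell density; an
infeasible packing request fails explicitly.

What the generator does *not* emulate — optics (PSF, out-of-focus
light), photobleaching, intensity gradients, cell deformation,
sub-cellular calcium structure — bounds what passing recovery tests
prove: they validate the analysis logic (event geometry, normalization,
classification, aggregation), not robustness to every artifact of real
microscopy.

## Robustness analyses

`resolution_scan()` re-analyzes each smoothed trace after decimation to
emulate frame intervals from 0.5 s to 60 s. Because decimation keeps
nested sample subsets, the measured $I_{\max}$ — and with it the
responder call — can only degrade as sampling coarsens; at 60 s
intervals most transients are missed entirely. `dye_loading_report()`
tabulates $dI/I_0$ per cell, and `pixel_subsample_report()` recomputes
$R(t)$ from random mask subsets down to ~20 pixels per cell, where for
near-uniform cells the curves change by well under 5 % RMS.

## Numerical conventions

Frame indices are 0-based; times are seconds with
$t = \mathrm{origin} + k\,\Delta t$; pixel coordinates are (row, col),
1-based as in R matrices. The TIFF interchange format is multi-page
16-bit unsigned grayscale, written without compression and validated to
round-trip integer counts exactly; out-of-range values are an error,
never clipped silently. All randomness (scene generation, pixel
subsampling) is seeded and restores the caller's RNG state, and a fixed
configuration plus seed reproduces every CSV byte-for-byte.

Population error bars are s.d.m. (standard deviation of the mean,
SD/√n; plain SD selectable), the responder fraction carries the
binomial standard error $\sqrt{p(1-p)/n}$, and the mean aligned
response is averaged over responders only (all cells via
`mean_r_responders_only = FALSE`), at aligned times covered by at least
two contributing cells. The triggering-time summary is reported as mean
± s.d.m. over responders.

## Problem sizes used in the shipped checks

The package's own validation runs the reference scene above
(~200 cells, 600 frames, one CPU, a few minutes), a medium 256 × 256
scene for integration tests, and closed-form or brute-force oracles for
the per-operation checks (trace averaging, Savitzky–Golay, derivatives,
disk segmentation). These sizes were chosen to make the binomial band
on the recovered fraction usefully narrow while keeping a full
validation cycle fast on a laptop.

## Known limitations

Global responses only: sub-cellular sparks and absolute calcium
concentrations are out of scope by design. Tracking is
nearest-neighbour with a coasting gap of a few frames — dense fields
with long occlusions need a proper multi-hypothesis tracker. The
responder criterion depends on a user-set threshold; reported fractions
should always be quoted together with it. Landing detection assumes
cells genuinely stop on contact; surfaces permitting post-contact
crawling would need a looser motion model.
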