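---
title: "Quantifying DSB repair foci and colocalization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DSB repair foci and colocalization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focikit)
```

# The measurement problem

A cell nucleus with DNA double-strand breaks displays discrete
immunofluorescent foci of γH2AX and of recruited repair proteins. Three
quantities summarise such images: the number of foci per nucleus (a proxy
for unrepaired breaks), the projected area of each focus (PAF, µm², whose
distribution shifts as damage matures), and the degree to which a repair
protein's signal colocalizes with γH2AX (recruitment). focikit computes
all three from multichannel 2-D images or z-stacks with a DNA
counterstain channel, and ships a ground-truth synthetic generator so the
pipeline's accuracy can be measured rather than assumed.

# Pipeline

## Projection and nucleus masking

Z-series are collapsed by per-pixel maximum projection (`max_project()`)
before any measurement; focus counting on projections, never per slice.
Nuclei are masked from the DNA channel (`segment_nuclei()`): Gaussian
smoothing at σ = 2 px, Otsu's threshold, hole filling, connected
components, and a minimum-area filter (default 200 px). Otsu on the
smoothed channel was chosen as a deterministic, parameter-light default
where interactive ROI drawing is not reproducible; a contrast-free image
yields an empty mask rather than an error. Anisotropic pixels are
rejected at I/O time because all area conversions assume square pixels.

Coordinates are row-major and 0-offset-free: pixel centres sit at integer
(row, col); one convention across all modules.

## Focus detection and areas

Within each nucleus the focal channel is binarized at

    cutoff = background + threshold × (max − background)

with background and max taken from that nucleus's pixels and
`threshold = 0.5` by default. Being relative to the in-nucleus dynamic
range makes counts invariant under multiplying the image by a positive
constant, so one setting generalises across acquisitions with different
gains. Suprathreshold pixels are grouped into 8-connected components
(diagonal contact joins a blob, matching common blob-measurement tools;
EBImage's 4-connected labeling is augmented by a diagonal-merge step),
and components under 3 px — 0.24 µm² at the 0.285 µm projection pixel —
are discarded as noise. Areas convert to µm² by the squared pixel size.

The per-nucleus relative rule has one known failure mode: a nucleus that
has lost *all* its foci has no signal, so its threshold lands inside the
noise band and random noise clusters can be counted. When several images
form one experiment series (a repair timecourse), the correct procedure
is a single fixed threshold for the whole series: `series_cutoff()`
derives an absolute cutoff from the reference image's in-mask dynamic
range and `detect_foci(absolute_cutoff=)` applies it everywhere.
`recovery_experiment()` does exactly this, deriving the cutoff at the
reference timepoint.

PAF histograms use half-open 0.1 µm² bins starting at 0.2 µm² (so the
3-px floor falls in the first bin and bin labels read 0.40–0.49 style),
an open top bin at ≥ 5 µm², and an explicit underflow bin for the small
areas that arise at very fine pixel sizes.

## Pan-nuclear exclusion

Apoptotic-type cells show homogeneous dense staining rather than discrete
foci and must not enter focus counts. `flag_pan_nuclear()` flags a
nucleus when more than `coverage_cutoff = 0.5` of its area exceeds an
*image-wide* cutoff (same relative form as above but over all in-mask
pixels): a per-nucleus relative cutoff cannot flag uniform staining
because inside such a nucleus max ≈ min. The 0.5 coverage default is
deliberately conservative — discrete foci cover a few percent of a
nucleus, dense staining close to all of it — replacing the by-eye
exclusion such cells traditionally get.

## DoG enhancement and colocalization

Focal signals are band-pass enhanced by difference of Gaussians:
`blur(σ_small) − blur(σ_big)`, negatives clipped to zero, pixels outside
the nucleus mask zeroed, and (by default) the image rescaled so the
in-mask maximum is 1. Defaults σ_small = 1 px and σ_big = 30 px suit
30-nm-pixel acquisitions where single-pixel spikes are noise and focal
signals reach ~25–30 px. "Radius" here means the Gaussian's standard
deviation, the reading consistent with common image-processing tools;
both radii are configurable. Three numerical choices are documented
rather than implied: negatives are clipped *before* normalization (the
minimal reading of "noise and background removed"), normalization is to
in-mask max = 1 (coefficients are scale-free, so any positive scaling
works; max-normalization keeps images comparable on one display scale),
and convolution uses mirror-reflected boundaries so border-adjacent foci
are not darkened by zero padding. A floor of 1e-9 × the channel maximum
zeroes FFT round-off, so a featureless channel stays exactly zero and is
reported as an undefined coefficient instead of amplified noise.

Pearson (Rr) and Manders overlap (R) coefficients, plus split
coefficients M1/M2 at zero intensity thresholds, are computed per nucleus
on the enhanced images (a raw-intensity mode exists for comparison), then
summarised as group mean ± SE. Per-cell-then-average, not pooled pixels:
biological replication is the cell. Undefined coefficients (constant or
zero-energy channel in a nucleus) are returned as `NA`, excluded from
means, and counted in a QC column — silent zeros would bias group means
downward.

`plateau_check()` re-runs the DoG at a series of big radii (default
10–55 px in 5-px steps) and reports the maximum relative deviation of the
mean coefficients from the 30-px reference over a stated window; values
within a few percent over 30–55 px confirm the segmentation scale is not
driving the result.

## Kinetics and statistics

`kinetics_summary()` turns per-nucleus counts into group × time means ±
SE and percentages of the group's reference mean; the reference defaults
to the time of maximum mean (shortly after treatment) rather than a
hard-coded hour, and `percent_repaired = 100 − percent_of_max` exactly.
`compare_groups()` is the classic pooled-variance two-sample two-tailed
Student's t-test, preceded by per-sample Shapiro–Wilk checks; non-normal
samples are flagged but the parametric result is still reported — the
gate is surfaced, never silently swapped for a nonparametric test. A
Welch option exists but is not the default. No multiple-testing
correction is applied by the comparison itself.

# The synthetic generator

`scene_spec()`/`generate_scene()` render: elliptical nuclei with
independently drawn semi-axes (enlarged/flattened nuclei vary; convexity
keeps masking simple) placed without overlap by rejection sampling (a
bounded number of attempts, then an explicit placement error); isotropic
2-D Gaussian foci *added* onto the background (linear optics — overlapping
foci sum); colocalized pairs sharing the exact centre with an optional
jitter parameter for robustness tests; pan-nuclear nuclei filled
uniformly at 1.5 × the focus amplitude (so the exclusion rule has
something realistic to catch); optional Poisson shot noise and Gaussian
read noise; clipping (never wrap-around) to 8- or 16-bit.

Default conditions emulate the counting-scale acquisitions: 0.285 µm
pixels, nuclei of ~4.5–7.5 µm semi-axis, 10 foci per nucleus, focus σ of
1–1.8 px (half-maximum footprints of ~0.35–1.15 µm², bracketing the
0.40–0.49 µm² histogram peak observed for γH2AX), background 1000, focus
amplitude 10000 and read noise 500 on the 16-bit scale. No noise or SNR
figures are available for the original acquisitions, so the noise
defaults are chosen for plausibility (amplitude-to-noise 20) rather than
fidelity. `coloc_scene_spec()` is the high-resolution preset:
single-nucleus 256 × 256 fields at 30-nm pixels, focus σ 4–8 px so
footprints reach the ~25–30 px focal-signal maximum, and noise at a tenth
of the amplitude.

`min_focus_spacing` (default 0) enforces a minimum centre-to-centre
distance between same-channel foci in a nucleus. Validation of counting
uses spacing ≥ 8 px: the recovery claim is about *resolvable* foci — the
cells analysed in practice are those with "countable" discrete foci — and
two Gaussians closer than ~4σ merge into one blob for any
threshold-based detector. The spacing sampler is best-effort (200 draws,
then the farthest candidate), so infeasibly dense requests degrade
gracefully.

`generate_timecourse()` models repair by independently retaining each
planted focus with probability `retention(t)` (reference time = 1);
channel-B duplicates of dropped foci vanish with them. Survival is
Bernoulli per focus, so planted "percent repaired" carries binomial
sampling noise of order `100·sqrt(p(1−p)/n_foci)` that validation
tolerances must include.

## What passing the synthetic tests does and does not show

The generator produces convex, uniformly stained nuclei, isotropic
Gaussian foci of equal amplitude, and stationary Gaussian/Poisson noise.
Real confocal data add texture inside nuclei, touching nuclei (no
watershed splitting is attempted here), irregular focus shapes,
amplitude variation over orders of magnitude, bleed-through and uneven
illumination — none of which are modelled. Recovery of planted truth
therefore demonstrates the correctness of the algorithms, not the
field-readiness of the default thresholds on any particular microscope's
output; thresholds remain per-experiment settings.

# Validation problem sizes

The shipped test-suite runs: plateau stability on five single-nucleus
30-nm scenes over σ_big ∈ {30…55}; Pearson/Manders against brute-force
loop oracles on 200 random ≤ 8×8 masked images (tolerance 1e-12);
exact planted-count recovery on noise-free 8-nucleus scenes with
pan-nuclear exclusion; Rr monotonicity over planted colocalized fractions
{0, 0.25, 0.5, 0.75, 1} with 25 nuclei per level; t-test type-I error
over 2000 null replicates at n = 25 (within three binomial SDs of 0.05);
and kinetics recovery at 37 % retention with ~200 nuclei across 8 scenes
(estimate within 5 percentage points of the planted 63 % repaired).
`scripts/acceptance.R` recomputes the plateau deviation on 10 seeded
nuclei.

# Known limitations

No 3-D focus volumes or sub-pixel localization; no watershed separation
of touching nuclei; no Costes-style randomization or automatic
thresholding for colocalization significance; no bi-exponential repair
model fitting — the kinetics table stops at model-free percentages.
Pan-nuclear flagging presumes the image contains its usual intensity
context (an image that is *only* pan-nuclear nuclei of identical
intensity has no contrast to flag against, though the contrast-free case
is handled).
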