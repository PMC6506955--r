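---
title: "Quantifying peri-plaque pathology: methods and design choices"
author: "periplaque"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying peri-plaque pathology: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periplaque)
```

## The measurement problem

In amyloid mouse models (5xFAD and similar) and in human Alzheimer tissue,
reactive astrocytes and microglia organize into a "glial net" around amyloid
plaques. Multi-channel immunofluorescence of brain sections carries the
evidence: Aβ and thioflavin S delineate plaques and their compaction state,
GFAP marks astrocyte processes, Iba1 marks microglia, NeuN marks neuronal
somata, synaptophysin marks presynaptic dystrophies, and AQP4 reports the
polarization of astrocyte water channels between perivascular endfeet and
parenchymal processes.

This package turns those images into per-plaque, per-neuron and per-animal
numbers:

1. **Plaque morphometry** — intensity thresholding, 8-connected labelling,
   and a strict $> 50\ \mu m^2$ object filter give plaque count, mean size,
   density per $mm^2$, and amyloid load (plaque area fraction).
2. **Plaque classification** — dense-core, fibrillar or mixed, from the
   relative Aβ / thioflavin S staining intensity.
3. **Peri-plaque band metrics** — a band of fixed physical width (5 μm by
   default) built by exact Euclidean distance transform around each plaque;
   GFAP enrichment is the mean GFAP intensity of the plaque interior or band
   divided by the mean over the surrounding non-plaque field.
4. **Microglial metrics** — Iba1-positive cell density, and the fraction of
   each plaque's boundary within a fixed distance of thresholded Iba1
   signal ("coverage").
5. **Neuropathology** — the fraction of peri-plaque NeuN somata containing
   ≥ 3 intracellular Aβ puncta, and the fraction of plaques with ≥ 4 large
   presynaptic dystrophies in the interior-plus-band region.
6. **AQP4 polarization** — background-corrected AQP4 intensity in
   perivascular or peri-plaque ROIs over non-plaque parenchyma.
7. **Group statistics** — per-animal aggregation, unpaired t-tests, two-way
   ANOVA with Bonferroni post-tests, and pooled cumulative distributions.

All geometric parameters live in micrometres and convert to pixels only at
the point of use (round-half-up, floor one pixel), so one configuration
applies across 4x/20x/100x acquisitions. Pixel size is mandatory — from
OME-TIFF metadata or an explicit override — because running uncalibrated
silently invalidates every printed constant.

## Segmentation and the two thresholding protocols

Plaque boundaries for band construction follow the high-magnification
protocol: Gaussian smoothing with a 2 μm radius, then thresholding. The
"radius" is interpreted as the Gaussian σ, the reading ImageJ's Gaussian
Blur dialog gives that word. Plain size/number morphometry of
low-magnification surveys thresholds the raw image; `blur_radius_um = 0`
selects that behaviour. The threshold method defaults to Otsu on a 256-bin
histogram of the min–max normalized image — parameter-free and invariant
under positive rescaling — with `fixed_percentile` and `fixed_value`
alternatives for protocols that pinned a manual threshold.

The $> 50\ \mu m^2$ filter is strict and applied in calibrated units after
labelling. Components touching the image border are kept but flagged;
`exclude_border_plaques` drops them from summaries. Connectivity is
8-connected to match standard particle analysis. A global Otsu threshold is
a single cut: when an image carries both very bright cores and much dimmer
fibrillar material, the dimmest objects can fall below it. The synthetic
scenes keep class contrast within the range a single threshold separates;
on real data a fixed-percentile threshold may be the safer choice, which is
why the threshold block is per-channel configurable.

## Plaque classification

The field describes three 5xFAD plaque types: dense-core (compact, very
bright thioflavin S), fibrillar (weaker thioS), and mixed (compact core in
a fibrillar halo); classical diffuse thioS-negative plaques are not part of
the scheme, so thioS-negative objects are reported "unclassified" rather
than given a class. The published criterion is visual; the package's rule
is a reproducible surrogate with every cutoff exposed in
`classification_params()`:

1. Candidate core pixels: within-plaque thioS at or above the within-plaque
   0.90 quantile. Under camera noise that cut selects scattered bright
   pixels rather than a region, so the candidate is grown to the midpoint
   between the candidate mean and the remainder mean, then morphologically
   opened (1 μm) to remove speckle.
2. The core is *very bright* when its mean thioS is ≥ 2× the halo mean
   (infinite when the halo is empty). A bright-cored plaque is **mixed**
   when the halo occupies ≥ 25% of the plaque, else **dense-core**.
3. A plaque with no internal bright core is homogeneous, and internal
   contrast cannot say whether it is uniformly bright or uniformly weak —
   any purely internal rule is scale-invariant. Such plaques are classified
   by the relative staining intensity of the two channels, each normalized
   to its own field mean so per-channel gain cancels: thioS enrichment at
   or above Aβ enrichment ⇒ **dense-core**, below ⇒ **fibrillar**.

Classification is evaluated on the plaque mask eroded by the opening radius:
the outermost pixel ring carries the PSF edge rolloff, which otherwise
mimics a weak halo on small dense plaques. All criteria are quantiles and
ratios, so the assigned class is invariant under joint positive rescaling
of both channels. The defaults (quantile 0.90, ratio 2, fractions 0.25,
opening 1 μm) are this package's choices, not published values, and cannot
be validated against published class fractions.

## Band ROIs and enrichment

`make_band()` reproduces the fixed-width annulus ("make band") semantics
exactly: the periphery is every pixel whose exact Euclidean distance to the
plaque component lies in $(0, w]$ pixels-converted, clipped at the image
border, minus pixels of any other plaque. The distance transform
(EBImage's exact Euclidean `distmap`) is verified in the test suite against
a brute-force all-pairs oracle, pixel for pixel.

GFAP enrichment divides the band (or interior) mean by the mean over the
*field*: everything farther than the band width from every plaque. The
published wording is just "surrounding field of view"; excluding all plaque
interiors and bands keeps plaque signal out of the denominator, making the
statistic a true contrast against non-plaque tissue. The choice is recorded
in the output metadata.

## Microglial coverage

The published measurement traced plaque perimeters and microglial processes
manually. The automated surrogate: boundary pixels of the plaque mask
(8-exposed to background), scored covered when any thresholded Iba1 pixel
lies within `coverage_distance_um` (default 2 μm, the package's choice).
Coverage is the covered fraction of boundary pixels — a ratio, so the
boundary-length estimator bias cancels. The measure is monotone in the
Iba1 mask by construction.

## Neuronal Aβ uptake and dystrophies

NeuN somata: threshold, fill holes, split touching somata by
distance-transform watershed, keep areas within 40–400 μm². Intracellular
Aβ puncta are detected within the soma only: the image outside the mask is
flattened to the soma median (so external structure cannot leak through the
filter), white top-hat with a 1.5 μm structuring radius, and a contrast
cut: pedestal-corrected top-hat above `(factor − 1) ×` soma median, with
`factor = 2.5`. The pedestal subtraction matters: the opening baseline of a
noisy image sits below the noise floor, so the raw top-hat of pure noise is
positive everywhere. Punctum components must fall in 0.2–5 μm². A neuron is
Aβ-positive at ≥ 3 puncta; the positivity fraction is computed over neurons
within 50 μm of the nearest plaque (the published wording, "surrounding
plaques", fixes no radius; 50 μm is configurable and recorded).

Dystrophies: synaptophysin components of ≥ 3 μm² ("large" is the only
published qualifier; the area floor is this package's proxy) within the
plaque interior ∪ band region; a plaque is dystrophic at ≥ 4. Both flags
are pure functions of their counts and thresholds and can be re-derived
from the CSVs alone.

## AQP4 polarization

Background correction subtracts a low percentile of the image (default p1)
and clips at zero — robust, parameter-light, and standard for fluorescence
background. The polarization ratio divides background-corrected means of an
ROI (perivascular band around a vessel mask, the peri-plaque band, or an
imported hand-drawn mask/polygon) by non-plaque parenchyma. One edge case
is handled explicitly: on an exactly flat image the percentile floor equals
the image and correction annihilates it; the ratio then falls back to raw
intensities so a uniform field reports the well-defined value 1.

## The synthetic scene generator

No raw images accompany the published analyses, so validation uses
`generate_scene()` / `generate_cohort()`: multi-channel renders with fully
known ground truth, exercising exactly the structure the measurements
assume.

- **Plaques**: disks with lognormal radii (median 7 μm, sdlog 0.2 by
  default), floored at 4.2 μm so every planted plaque passes the 50 μm²
  filter by construction; class-dependent rendering (dense: uniformly
  bright thioS; fibrillar: weak textured thioS; mixed: bright core of 0.4×
  the radius in a weak halo).
- **GFAP**: a web of short strokes (4 × 0.6 μm, random position and
  orientation). Enrichment multiplies stroke *density* inside the band and
  interior — more processes, not brighter ones — via thinning of an
  oversampled candidate set. Because of the flat background haze and stroke
  bleed across region edges, the *measured* noise-free enrichment is lower
  than the planted density factor; recovery targets are therefore the
  noise-free measured reference, not the factor itself.
- **Microglia**: somata (radius 3.5 μm) kept clear of plaque boundaries,
  plus coverage arcs hugging each plaque. The planted coverage fraction is
  defined as the fraction of boundary within the association distance of
  the arc, so arc ends are trimmed by that reach — this makes the planted
  fraction well-defined under the measurement's own semantics.
- **Neurons**: 8 μm somata with a planted Bernoulli positivity among
  peri-plaque neurons; positive somata receive 3–7 well-separated 1 μm
  puncta at 5× the soma Aβ floor, negative ones 0–2.
- **Dystrophies**: 2.5 μm blobs placed wholly inside the band annulus.
- **Vessels/AQP4**: straight tubes with a dark lumen, a perivascular rim at
  4× parenchymal AQP4, and peri-plaque AQP4 enrichment in the band.
- **Optics and camera**: Gaussian PSF (σ 0.3 μm), then
  `Poisson(scale · signal)/scale` photon noise and Gaussian read noise
  (σ 2), the standard two-parameter fluorescence camera model.

All randomness flows from a single seed; identical spec + seed is
bit-identical. Cohorts draw per-animal lognormal multipliers (sdlog 0.15)
for each effect knob and label animals by condition; condition effects are
multipliers on plaque count, plaque area, enrichment excess, coverage and
positivity. `pair_conditions = TRUE` reuses scene seeds across conditions
for matched-construction checks; the default keeps animals independent, as
null-calibration requires.

What the generator does *not* emulate: real tissue texture and
autofluorescence, anisotropic or saturated optics, 3D structure,
section-to-section variation, and segmentation errors that correlate across
channels. Passing recovery tests therefore demonstrates the correctness of
the measurement definitions and their noise robustness at realistic SNR —
not performance on degraded real-world histology.

## Statistics

Per-animal summaries pool plaques across the animal's images and
area-weight image-level densities. Animals below 10 analyzed plaques are
flagged, not dropped. Two-group comparisons default to the Student
(equal-variance) unpaired t-test — the convention of the graphing software
named in the original protocol — with Welch as an option; a zero-variance
degenerate case is reported with an explicit flag instead of an error from
`t.test`. Class fractions are analyzed as condition × class with type II
sums of squares (the standard choice for unbalanced 8-vs-5 cohorts,
computed via `car::Anova`), followed by per-class contrasts on the pooled
residual error with Bonferroni adjustment, `min(1, k·p)` exactly. ECDFs are
exported as sorted value / step-height tables.

## Numerical choices and problem sizes

- μm→px for structuring elements: round-half-up, minimum 1 px.
- Otsu runs on a 256-bin histogram of the min–max normalized image;
  a constant image thresholds to an empty mask.
- Labels are renumbered in column-major scan order of each component's
  first pixel, making label maps deterministic.
- Label masks are written 16-bit when labels fit, 32-bit float otherwise
  (lossless below $2^{24}$); measurement CSVs are written at full precision
  in a deterministic row order.
- The validation suite runs scenes of 128–300 μm at 0.5 μm/px (256–600 px),
  cohorts of 8 vs 5 animals with one image each, 20 replicate cohorts for
  direction checks, and 201 metric-replicates for the null-calibration
  check; these sizes were chosen so the whole suite completes in minutes on
  one core while keeping every statistical band meaningful.

## Known limitations

- A single global threshold per channel; no adaptive/local thresholding.
- The classifier's numeric cutoffs cannot be checked against published
  class fractions (the published criterion is visual).
- Coverage measured on blurred-boundary masks is biased low relative to the
  planted arcs when the segmented boundary departs from the true edge; the
  bias is condition-independent and cancels in group contrasts.
- Iba1 "cell" counting by component area will count large process
  fragments (e.g. coverage arcs) that fall inside the soma window.
- No mixed-effects modelling; animals are the unit of analysis throughout.
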