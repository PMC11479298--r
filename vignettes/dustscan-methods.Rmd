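---
title: "Particle counting on paper air-quality sensors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle counting on paper air-quality sensors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dustscan)
```

## The measurement problem

A do-it-yourself paper air sensor is a 6 cm × 6 cm paper square coated with
petroleum jelly. Exposed outdoors for about a week, it captures airborne
particulate matter (PM) as dark dots; a photograph of the sensor is then a
record of deposition. Counting those dots by eye is slow and subjective, so
`dustscan` automates the chain: it converts dot counts into a density in
dots per cm² and a four-level pollution rating, and it sizes each dot in
micrometres so that particles can be attributed to the standard PM classes
(PM1 ≤ 1 µm, PM2.5 ≤ 2.5 µm, PM10 ≤ 10 µm by equivalent diameter — classes
nest, every PM1 particle is also a PM2.5 and PM10 particle).

Field photographs of such sensors are scarce, and a pipeline cannot be
validated without known ground truth. The package therefore ships a
first-class synthetic generator: images with exact per-particle annotations,
plus camera-degradation models that emulate what a smartphone does to such a
photograph. The detection pipeline is evaluated against the generator's
ground truth under systematically varied degradations.

## The synthetic scene model

`sensor_image_spec()` fixes geometry and background. The working resolution
is 1 pixel per micrometre; a full 6 cm frame would be 60,000 px across, so
images are sub-frame crops and `imaged_area_cm2()` tracks the physical area
(`width_px * height_px / (r² · 10⁸)` cm² at resolution `r` px/µm). The
default experiment crop is 2000 × 2000 px (0.04 cm²); the 10,000-particle
condition uses 4000 × 4000 px so that its dot density stays comparable.

The background is near-white paper: mean grey level 245 with Gaussian
texture jitter of σ = 2 digital numbers (DN). Real paper-fibre texture is
deliberately out of scope; the jitter only prevents a degenerate constant
background.

`sample_particles()` draws, per particle:

* a **PM class** from mixture weights. For ground-truth sampling the classes
  are disjoint strata — PM1 in (0, 1] µm, PM2.5 in (1, 2.5] µm, PM10 in
  (2.5, 10] µm — with the diameter uniform within the stratum. The default
  mixture is uniform across the three strata.
* a **grey level** uniform on 0–120 DN (black and grey dots against white
  paper).
* a **centre** uniform over the image interior, accepted only if every disk
  pair keeps an edge-to-edge gap of at least `min_gap_px` (default 1 px, so
  particles never touch and a count-based metric is well defined; passing 0
  explicitly permits overlap). Placement is bounded rejection sampling over
  a spatial grid; an infeasible density raises an error rather than looping
  forever.

`render_sensor_image()` paints each particle as an anti-aliased filled disk
of pixel diameter `diameter_um × resolution`. Coverage is estimated on a
16 × 16 subpixel grid for boundary pixels, so a disk's summed darkening
equals its analytic area πr² to well under a pixel; irregular blob shapes
are not modelled. Output is always 8-bit RGB with three equal channels.

Everything is seeded: the same spec, particles and seed reproduce every
image and annotation byte for byte. That determinism is load-bearing — the
evaluation harness derives all of its per-run seeds from one master seed.

## Camera degradation models

Three models emulate a smartphone capture, composed by
`compose_degradations()` in the physical order optics → in-camera processing
→ sensor electronics (focus blur, then white balance, then Gaussian noise).
Each model is the identity at its null parameter, and all outputs are
clipped to [0, 255] and re-quantized to 8 bits.

* **Gaussian noise** (`add_gaussian_noise()`): per-pixel, per-channel i.i.d.
  N(mean, variance) in DN, the standard model for sensor/electronic noise.
  The studied range is mean 1–5 DN, variance 4–8 DN²; those magnitudes are
  only plausible on the 0–255 scale, which is how the package interprets
  them.
* **Focus blur** (`apply_focus_blur()`): a centred rectangle covering
  `focus_area` percent of each image dimension stays sharp; outside it a
  Gaussian blur of σ = `strength` px (kernel truncated at 4σ, reflected
  borders) applies, with a raised-cosine transition band 3σ wide so no seam
  appears. The studied range is focus area 100 → 70, strength 1 → 4. The
  geometry (a percentage of each dimension, Chebyshev-combined distance
  outside the rectangle) is this package's definition; only the two knobs
  and their ranges are given by the study design.
* **White balance** (`adjust_white_balance()`): a signed temperature knob
  with linear channel gains — red × (1 + 0.01 t), blue × (1 − 0.01 t),
  green untouched, gains clamped at zero. Negative temperatures therefore
  cool the image. The studied range is t = −1 to −20. The 0.01/unit gain
  slope is a package choice; the green channel being bit-identical is a
  tested invariant.

Not modelled (non-goals): shot/salt-and-pepper noise, motion blur,
vignetting, geometric distortion, JPEG artefacts.

## The detection pipeline

`detect_particles()` is deterministic and parameter-light
(`detection_params()`):

1. **Grayscale** via Rec. 601 luma (0.299 R + 0.587 G + 0.114 B), rounded
   to integer DN.
2. **Gaussian pre-blur**, σ = 1 px, to suppress single-pixel noise before
   thresholding.
3. **Bicubic upscaling** to the working resolution of 1 px/µm when the
   native calibration is coarser (skipped otherwise — synthetic images are
   already at 1 px/µm). The resampler is the classic cubic-convolution
   scheme over the 16 nearest neighbours with kernel parameter a = −0.5
   (Catmull–Rom), centre-aligned mapping, replicated borders; tests pin it
   to a brute-force per-pixel oracle.
4. **Adaptive thresholding**: a pixel is foreground iff it lies below its
   35 × 35 px local mean minus 10 DN (dark-on-light convention, reflected
   borders). Local-mean thresholding with a modest offset tolerates the
   smooth illumination and white-balance shifts that a global threshold
   would not.
5. **8-connected component extraction**, discarding components below
   0.5 px² (a floor that still admits 1 µm particles at 1 px/µm). Touching
   particles merge into one component by construction; no watershed
   splitting is attempted, and the count-based accuracy metric absorbs the
   occasional merge.
6. **Sizing**: each component's area is re-measured at the half-contrast
   level — the count of its pixels below the midpoint between the local
   background and the component's darkest pixel. The detection mask itself
   is dilated by the pre-blur and the threshold offset (roughly +1.5 px per
   side, which would inflate a diameter by ~3 µm); the half-contrast contour
   of a blurred disk tracks the true edge instead, and measured equivalent
   diameters (2√(area/π)) stay within ±1 µm of truth for disks ≥ 3 µm.
   `extract_particles()` without a grey image falls back to the raw mask
   area.
7. **Classification and density**: `pm_class()` with inclusive upper bounds
   (≤ 1, ≤ 2.5, ≤ 10 µm; anything larger is OVERSIZE — reported in
   `n_total` but excluded from `n_pm10`), and `dots_per_cm2 =
   n_total / area_cm2` with the dust-scale rating.

Calibration (`calibration_info()`) is supplied as metadata — either
px-per-cm directly or the known frame size and its pixel extent. Automatic
localisation of the printed frame in a photograph is out of scope.

### The dust scale

`dust_scale_level()` maps density to the published four-level scale:
fewer than 11 dots/cm² Low, 11–25 Medium, 26–50 High, above 50 Very high.
The published bands are stated on integers; for real-valued densities the
package uses half-open bands [0, 11), [11, 26), [26, 51), [51, ∞), the only
convention that reproduces the integer table exactly while partitioning the
non-negative reals with no gaps. Whether fractional densities occur in
practice is unknown; the convention is declared, not inferred.

## Evaluation

The only accuracy metric is count-based:
`accuracy = 100 × detected / actual`. No spatial matching of detections to
ground-truth particles is attempted; over-detection (> 100%) is reported
as-is and flagged per run. `run_sweep()` executes
(condition × particle count × seed) cells: generate a clean scene, degrade,
detect, record. Failures are recorded per cell, never dropped silently.

The default study conditions (`sweep_config()`):

* particle counts 100–800 in steps of 100 on 2000 × 2000 px images, plus
  10,000 on 4000 × 4000 px for the white-balance family;
* the five noise families — Gaussian only, focus blur only, white balance
  only, Gaussian + white balance, and all three — each at the mild and harsh
  endpoints of the studied parameter ranges (`noise_endpoint_grid()`);
* 10 replicate seeds per condition (replication count is this package's
  choice);
* a PM10-only mixture. The evaluated experiments count a pre-known quantity
  of PM10 particles, so the sweep samples diameters from the PM10 stratum
  (2.5–10 µm). This matters physically: at 1 px/µm a sub-pixel PM1 particle
  (d ≲ 0.8 µm) is unresolvable in principle, so a uniform mixture would cap
  count accuracy far below what any detector could achieve — the exact
  count-recovery contract is correspondingly stated for diameters ≥ 2 µm.

At these conditions the clean pipeline recovers counts exactly in ≥ 99% of
seeds at the study density (~100 particles per 0.04 cm² crop; merges from the
mask dilation dominate the residual misses, and their rate grows with
density — that is also why the 10,000-particle condition loses a few
percent). Monotonicity properties — accuracy non-increasing in blur
strength and in white-balance magnitude — are asserted on medians over 20
seeds, allowing ties, because mild settings often leave accuracy at exactly
100%.

## Numerical choices and edge cases

* Pixel convention: 0-based (row, column), origin top-left; a pixel covers
  a unit square and its centre is at (+0.5, +0.5). All output files state
  this.
* All blurs and local means use symmetric (half-sample) border reflection;
  the bicubic resampler replicates its border instead, matching common
  resize implementations.
* Clipping always precedes re-quantization; no gamma model.
* Degenerate inputs fail loudly: non-positive diameters, negative densities
  and variances, even threshold blocks, infeasible placements, out-of-bounds
  particle centres, missing calibration.
* Sub-seeds for multi-stage runs are drawn from the master seed with R's
  RNG and kept below 2³¹.
* Test problem sizes: unit tests run on 64–1000 px images; the full-scale
  acceptance suite uses the 2000/4000 px study conditions above.

## What passing tests do and do not show

The generator emulates dark, roughly circular, non-touching particles on
clean near-white paper, degraded by three specific camera effects. Passing
sweeps therefore demonstrate robustness of the counting pipeline to those
effects at the studied magnitudes. They do not demonstrate performance on
real photographs, which add paper fibre texture, irregular particle shapes,
agglomerates and overlaps, uneven jelly reflectance, perspective and lens
distortion, and JPEG compression. The reference comparison reported for the
physical sensor (a moderate correlation with instrument-based PM10
measurements) bounds what any image pipeline can deliver from this medium.
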