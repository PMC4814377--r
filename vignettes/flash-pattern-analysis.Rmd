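---
title: "Flash pattern analysis from time-lapse video: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flash pattern analysis from time-lapse video: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flashtrace)
```

## The measurement problem

A flashing firefly in a night recording is a small, moving, blinking
point source on a dark, noisy background. The quantities of scientific
interest are per individual: when each flash starts and ends, where its
intensity peaks are, how flashes of one individual space themselves in
time, and how flashes of different individuals relate (synchrony). None
of these are properties of single frames; all require following one
individual through the video and reducing its pixels to a single
intensity number per frame first. `flashtrace` is organised around that
chain:

    video -> tracks -> intensity traces -> flash events -> pattern metrics

Each link is an exported function with a plain data structure on either
side, so any stage can be replaced by external data (e.g. a manually
traced path imported from CSV) and every stage can be validated in
isolation against simulated ground truth.

## Conventions

Pixels use 0-based coordinates, origin top-left, x rightward, y
downward, pixel centers at integer coordinates; frame `i` (0-based) has
timestamp `t0 + i / frame_rate`. Timestamps are derived from the frame
rate rather than per-frame container metadata because the recording
instruments involved are constant-rate and an explicit rate is testable.
Color input is reduced to Rec. 601 luminance at load; all analysis is
single-channel. The frame rate of a recording is never guessed: it
comes from the AVI header or must be supplied for frame stacks.

## Tracking

A region of interest (ROI) is a circle: pixel `p` belongs to it iff
`|p - center| <= radius`. The radius is a user choice (the shape and
size of ROIs is not standardised in this field); the default of a few
pixels should comfortably contain the point-spread function of an
in-focus source. Two ROIs may overlap — when two flight paths coincide
the tracks are traced superpositionally, and a warning notes that their
light is no longer separable.

Automated tracking thresholds each frame (a robust
median + 8 MAD default via `suggest_threshold()`), labels connected
components, and takes brightness-weighted centroids. Linking is greedy
nearest-neighbour: closest (track, detection) pairs are accepted first,
pairs farther than `max_jump` are refused, leftover detections found
new tracks, and a track unmatched for more than `max_gap` frames is
closed. Ties are broken toward the lower track id, then the earlier
detection, making linking a pure function of its input. On well
separated sources this greedy scheme provably coincides with
minimum-total-displacement matching, and the tests check that agreement
exhaustively on small instances.

Two parameters deserve comment for *flashing* sources. A firefly is
invisible between flashes, so the tracker must bridge dark gaps much
longer than the 2-frame default: for the bundled presets (flash period
1.2–1.9 s at 30 fps, dark phase up to ~0.6 s ≈ 19 frames) the pipeline
uses `max_gap = 30` frames, and `max_jump = 15` px accommodates the
drift a slowly flying individual accumulates while dark. Positions
inside bridged gaps are linearly interpolated so the intensity trace
stays aligned to the frame clock; interpolated entries are flagged
`is_gap` in every export.

## Photometry

The trace value at a frame is the sum over ROI pixels of
`pixel - background`, clipped at zero (emitted light is nonnegative).
Sum, not mean: total flux is insensitive to the exact radius once the
source is enclosed, while a mean dilutes with every extra background
pixel (a mean option exists). The background is the median of the
annulus between `radius` and `2 * radius`, excluding pixels inside any
other track's ROI so a neighbour's flash cannot inflate the estimate;
when clipping and exclusions empty the annulus the whole-frame median is
used and flagged. Subtracting a per-frame local median makes the trace
exactly invariant to a constant offset on all pixels, and on noise-free
synthetic scenes the trace reproduces the injected flux to well under
1% (the residual is the Gaussian PSF mass outside the ROI). Display
adjustment (`adjust_display()`) is a rendering aid only; photometry
reads raw frames by construction.

## Flash segmentation and metrics

The trace baseline is its 10th percentile — robust against isolated
dark-noise samples, and close to the dark level whenever the trace
spends at least ~10% of its time dark. Flash boundaries sit where the
trace crosses `baseline + onset_frac * (peak - baseline)` with
`onset_frac = 0.1`: a 10%-of-peak criterion approximates visible onset
better than half-max for asymmetric pulses, and half-max is available by
setting `onset_frac = 0.5`. Segmentation is two-pass: a coarse pass with
the global maximum finds candidate bursts, then each burst is re-bounded
against its *own* peak so flashes of unequal amplitude are measured
consistently. Boundaries are interpolated linearly between samples, so
durations are not quantized to whole frames.

Three rules matter in edge cases:

- **Merging.** Bursts separated by a dark gap shorter than `merge_gap`
  (0.3 s default) merge into one flash whose peaks are pooled — this is
  what turns a "twinkling" flash into a single bimodal double-pulsed
  event rather than two short flashes.
- **Truncation.** A burst touching the first or last trace sample was
  cut off by the recording window; its duration is unknowable, so such
  events are dropped (`drop_truncated = TRUE`). Without this rule the
  clipped final flash of a long train biases mean duration low by tens
  of milliseconds.
- **Peaks.** Local maxima count as peaks when their topographic
  prominence reaches `min_prominence_frac` of the trace range; plateau
  maxima report their center time. Prominence, not height, is what
  separates a genuine sub-pulse dip from sensor noise; the pipeline
  default of 0.1 rejects noise excursions several sigma tall while
  keeping the pronounced dip of a bimodal flash. An optional boxcar
  smoothing exists for pathological noise but is off by default —
  sub-pulse peaks can sit only 3–4 frames apart at 30 fps, and smoothing
  at that scale erases exactly the structure being counted.

The summary reports mean flash duration, mean peak interval (first
peaks of successive flashes), mean interflash interval (offset to next
onset — with the peak-to-peak reading also exported), mean within-flash
sub-pulse interval, and the per-flash pulse counts. Interval means need
at least two flashes; absent values are `NA`, never 0. All time metrics
are equivariant under time shifts and invariant under positive
amplitude scaling, and the tests assert both properties on simulated
traces.

## Synchrony, spectra, path geometry

`cross_correlate()` computes the Pearson correlation of two traces at
every integer-frame lag within `±max_lag`, each over the overlapping
window; `best_lag` is the argmax with ties resolved toward zero lag.
Correlating raw traces (not binarized flash trains) is the default
because amplitude carries signal; `binarize_trace()` provides the 0/1
alternative. For groups, all pairs are reported and the mean pairwise
zero-lag correlation serves as the group synchrony index — a deliberate
minimal choice, not a phase-oscillator model.

`power_spectrum()` is the one-sided periodogram of the mean-removed
trace, normalised so the summed power equals the trace's mean square —
Parseval's identity then holds by construction and is asserted to 1% in
the tests; spectral density per Hz is `power / df`. A Hann taper is
optional and off by default.

`fractal_dimension()` implements box counting: the path is densified by
linear interpolation (≤ 0.5 px steps) so sparse sampling cannot starve
small boxes, boxes sit on a grid anchored at the bounding-box corner
(fixed anchor for determinism; anchor averaging would be a refinement),
and sizes form a dyadic ladder from the bounding box's larger side down
six halvings, never below 2 px. The dimension is the least-squares
slope of log count vs log(1/size) with its fit R². Straight paths score
≈1, a filled square scores 2, and the estimate is invariant under
translation and uniform scaling of the path within fit tolerance.

## Rendering

The orbit-line figure quantizes a trace into `n_steps = 7` ordinal
levels — equal-width bins over the observed range by default ("optimal"
allocation is not standardised, so an equal-quantile option exists),
minimum mapping to step 1, maximum to step 7, a constant trace wholly
to step 1 — and draws a circle of radius `2 + 2 (step - 1)` px at each
sample along the path polyline. Step-1 circles can be suppressed to
de-clutter dark phases (off by default). The time-course figure colors
tracks red, brown, green, purple, blue (cycling) with an optional red
vertical frame cursor. The overlay video burns ROI circles (dashed at
interpolated gap positions) and trailing paths into the frames at the
sequence's maximum value, optionally with a `sec.msec` timer stamp, and
preserves frame count, size and rate exactly.

## The scene simulator

`make_scene()` renders each individual as an isotropic Gaussian of
`psf_sigma` pixels whose integrated excess flux follows its flash
envelope, over a constant background with Gaussian read noise, optional
Poisson shot noise, and integer (ADU) digitization. The kernel is
normalised over its rendered patch, so on a noise-free, undigitized
scene the frame's summed excess flux equals the envelope value exactly
— the photometric oracle. Identical seeds give bit-identical scenes.

Flash envelopes:

- **Rectangular** — `n` disjoint rectangular pulses; the truth duration
  is the support.
- **Raised cosine, single pulse** — one smooth bump whose *10%-level
  width* is the stated duration, deliberately matching the 10% onset
  criterion so recovery tests compare like with like.
- **Raised cosine, multi-pulse** — a broad raised-cosine pedestal
  (relative amplitude 0.45) whose 10%-level width is the flash duration,
  carrying narrow bumps of full width equal to the sub-pulse interval.
  This shape is forced by arithmetic: a 566 ms flash with peaks 140 ms
  apart cannot be two disjoint pulses (their widths would have to be
  negative), so the bimodal flash must be one continuous envelope with a
  dip; the pedestal construction gives a pronounced (~55%) dip, which is
  what "double-pulsed, visible by eye in the trace" implies, and keeps
  both printed quantities exact in the truth.

Trajectory models: stationary (optionally jittered), linear with border
reflection, Gaussian random walk, and a sinusoidal "weave" in separate
lanes — the weave is non-crossing by construction and is used wherever a
test needs unambiguous identity. Default scene parameters (PSF sigma
1.5 px, amplitude 800 ADU, background 20 ADU, read noise 1.5 ADU, 8-bit
presets) describe a bright in-focus source against a clean night sky at
high SNR, chosen once as representative of an intensified or modern
low-light recording.

Two presets encode classic demonstration conditions: `cruciata_like`
(five weaving individuals, single-peak 1.3 s flashes every 1.9 s, fixed
small phase offsets of ±0.15 s — loosely synchronous) and
`lateralis_pair` (two near-stationary individuals: a 566 ms bimodal
flash with 140 ms sub-pulse interval and 624 ms dark gap, against a
350 ms triple pulse). `truth_summary()` returns the exact metrics the
pipeline should recover.

What the simulator does *not* emulate — and therefore what passing
recovery tests do not show about field data: vegetation occlusion,
camera motion and rolling shutter, defocus variation, overlapping
flight paths with identity exchange, amplitude variation within a
train, non-periodic flashing, and compression artifacts. Results on
real video depend on threshold and radius choices in ways the synthetic
tests cannot certify.

## Numerical choices and degenerate inputs

Boundaries and peak plateaus interpolate linearly; the box-count grid
and the linker break ties by fixed rules, never iteration order; a
constant trace yields no peaks and no events (not an error), a
zero-variance trace makes correlation an error, a single-point path
makes fractal dimension an error, and an empty detection frame is an
empty table. Negative photometry sums clip to zero. CSV exports go
through `readr` at full (round-trip-exact) precision; the AVI dialect
is uncompressed RIFF/DIB, written and parsed by the package itself, and
a directory of numbered TIFF/PNG frames is accepted anywhere an AVI is.

## Problem sizes used by the test-suite

The bundled validation runs at deliberately modest scale: 20 s of
synthetic video at 30 fps and 192×192 px for the five-individual scene
(≈50 recovered flashes), 12 s at 96×96 px for the pair, 300 frames for
the tracking-fidelity scene, and closed-form fixtures (sinusoids,
lines, filled squares, Brownian walks) for the signal analyses. These
sizes give means over enough flashes that recovered timing metrics are
stable to well under one frame period while keeping the whole suite
fast; nothing in the method is specific to these sizes.

## Known limitations

- Greedy linking has no identity re-acquisition: after a long occlusion
  or a track swap at a crossing, a new track id is born (the field's
  manual-tracing practice has the same limit).
- The interflash interval defined as the dark gap depends on the onset
  criterion; peak-to-peak spacing is exported alongside for
  convention-independent comparisons.
- Duration estimates inherit a small bias when a trace is rarely dark
  (high duty cycle): the 10th-percentile baseline then sits above the
  true dark level and pulls boundaries inward by a few milliseconds.
- Box-counting dimension on short tracks (seconds of flight) is a
  descriptive statistic; its fit R² should be inspected before
  interpretation.
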