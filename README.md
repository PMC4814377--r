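# flashtrace

Quantitative analysis of bioluminescent flash signals and flight paths
from time-lapse video.

Fireflies (and many marine luminescent organisms) communicate with
species-specific flash patterns: trains of light pulses whose durations
and intervals carry the signal. `flashtrace` turns a night-time video of
flashing individuals into per-individual numbers: it finds and follows
each light source, measures its background-corrected brightness over
time, cuts the brightness trace into flash events, and reports the
pattern metrics an entomologist actually compares between species —
flash duration, peak interval, interflash interval, and sub-pulse
structure (a "twinkling" flash resolved as a bimodal double pulse). It
is a scriptable library plus a small CLI; there is no GUI.

## What it computes

For each individual *i* with ROI-summed, background-subtracted intensity
trace *I_i(t)* sampled at the frame rate:

- **Flash segmentation.** Baseline *b* is the 10th-percentile trace
  value. A flash spans the interval where *I(t) > b + α (P − b)* with
  *P* the flash's own peak and *α* = 0.1 by default (boundaries by
  linear interpolation between samples; bursts separated by dark gaps
  shorter than `merge_gap` merge into one flash). Peaks are local maxima
  with topographic prominence ≥ a set fraction of the trace range, so a
  flash with two close peaks is classified as double-pulsed.
- **Pattern metrics.** Mean flash duration (onset→offset), mean peak
  interval (first peaks of successive flashes), mean interflash interval
  (offset→next onset), mean within-flash sub-pulse interval, and
  pulses-per-flash counts.
- **Synchrony.** Pairwise Pearson cross-correlation of traces at every
  integer-frame lag in ±`max_lag`; the mean pairwise zero-lag
  correlation serves as a group synchrony index.
- **Spectra.** One-sided periodogram of the mean-removed trace
  (Parseval-exact normalisation).
- **Flight-path geometry.** Box-counting fractal dimension of the
  densified path: the slope of log N(s) vs log(1/s) over a dyadic ladder
  of box sizes (1 for a straight path, →2 for a plane-filling one).
- **Figures and video.** The orbit-line figure with intensity quantized
  into seven ordinal steps drawn as growing circles along the path, the
  multi-track time-course plot (red/brown/green/purple/blue series, red
  frame cursor), and an overlay AVI with ROI circles and trailing paths
  burned in.

Tracking is either imported from a manual trace CSV (`frame,x,y`) or
automated: threshold → connected components → brightness-weighted
centroids → greedy nearest-neighbour linking with deterministic
tie-breaks, gap bridging, and linear interpolation across dark phases.

A fully parameterized scene simulator (`scene_spec()` / `make_scene()`)
renders moving Gaussian point sources with rectangular or raised-cosine
flash envelopes plus sensor noise, and returns exact ground truth — the
package's tests validate every stage against it.

## Worked example

Simulate a courting pair — the male-analog emits a bimodal double-pulsed
flash (566 ms duration, 140 ms sub-pulse interval, 624 ms dark gap), the
female-analog a rapid triple pulse — then recover the pattern with the
fully automated pipeline:

```r
library(flashtrace)

spec   <- preset_scene("lateralis_pair", duration = 12, seed = 7)
scene  <- make_scene(spec)          # 360 frames, 96 x 96 px, 30 fps
tracks <- link_tracks(detect_all(scene$seq), max_jump = 15, max_gap = 30,
                      radius = 6, min_length = 5)
traces <- measure_all(scene$seq, tracks)
events <- lapply(traces, segment_flashes, min_prominence_frac = 0.1)
for (i in seq_along(events))
  print(summarize_flashes(events[[i]], tracks[[i]]$track_id))
```

```
flash_summary '1': 8 flashes
  mean duration           568.7 ms
  mean peak interval     1190.5 ms
  mean interflash gap     620.0 ms
  mean subpulse gap       133.3 ms
  pulses per flash     2 2 2 2 2 2 2 2
flash_summary '2': 10 flashes
  mean duration           357.0 ms
  mean peak interval     1000.0 ms
  mean interflash gap     643.4 ms
  mean subpulse gap       100.0 ms
  pulses per flash     3 3 3 3 3 3 3 3 3 3
```

Every male flash is classified double-pulsed; the recovered duration
(568.7 ms vs 566 true), interflash gap (620.0 vs 624) and sub-pulse
interval (133.3 vs 140) all land within one frame period (33.3 ms) of
the simulated truth (`truth_summary(scene$truth)` prints it). Flashes
cut off by the recording window are excluded, so the two summaries count
8 and 10 measurable flashes of the 10 and 12 emitted.

The same run as one shot, with all outputs (CSVs, figures, overlay
video, JSON manifest):

```r
cfg <- run_config(scene$seq, "out_dir", auto = list(), roi_radius = 6)
run_pipeline(cfg)
```

or from the shell via the CLI (`inst/cli/flashtrace`):

```sh
flashtrace simulate --preset lateralis_pair -o scene.avi --seed 7
flashtrace run -c config.yaml
flashtrace extract-frames scene.avi frames/
```

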