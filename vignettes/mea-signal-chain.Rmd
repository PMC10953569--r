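---
title: "The MEA signal chain: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The MEA signal chain: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meapipe)
```

meapipe implements the offline analysis chain for in vitro microelectrode-array
(MEA) electrophysiology: band-pass conditioning of raw multichannel voltage
traces, robust threshold spike detection with waveform cutouts, PCA spike
sorting, channel and network statistics, MEA layout geometry, stimulation
protocol compilation, and concurrent calcium-trace analysis. Because real
recordings require living preparations, the package ships a ground-truth
simulator that exercises every stage end to end. This vignette explains the
models, the parameters that matter, and the choices made where the standard
practice leaves room.

## Signal model and preprocessing

A recording is a channels-by-samples matrix of voltages in µV sampled at a
common rate (30 kHz by convention for extracellular spikes). Spikes occupy
roughly 300–3000 Hz, so the first stage is a third-order Butterworth band-pass
with half-power edges at 200 and 3000 Hz (`design_bandpass()`); the edges are
the −3 dB points of the single-pass magnitude response and are verified by
numerical search (`half_power_points()`).

Two implementation decisions are worth stating:

* **Zero-phase application.** `apply_filter()` runs the filter forward and
  backward by default. This squares the magnitude response and removes group
  delay, so spike timestamps are not systematically shifted — important
  because all later statistics are computed on timestamps. A causal
  single-pass mode remains available (`zero_phase = FALSE`) for streaming-like
  use.
* **Second-order sections.** An order-3 band-pass at 30 kHz with a 200 Hz
  edge is numerically delicate in direct polynomial form, so the filter is
  factored into biquad sections (each one conjugate pole pair with one
  (+1, −1) zero pair) and applied as a cascade. The tests confirm the cascade
  reproduces the direct-form transfer function to 1e−8.

Edges are handled with odd-reflection padding of three times the filter
length. The low-pass used for LFP extraction pads proportionally to
`rate / cutoff` instead, because its transient is much longer.

## Noise estimation and spike detection

The detector thresholds each channel at

> threshold = 5 · median(|x|) / 0.6745

where x is the band-pass-filtered trace. The median absolute value of
zero-mean Gaussian noise equals 0.6745 σ, so the quotient estimates the noise
SD while remaining nearly insensitive to the rare large samples contributed
by spikes — unlike the raw SD, which a handful of 100 µV spikes inflates
badly. The multiplier 5 and divisor 0.6745 are exposed in
`detection_config()`.

A threshold crossing opens an event window that closes at the re-crossing;
the timestamp is the within-window extremum in the detection polarity. This
gives stable alignment for sorting. Detection behaviour is pinned by an
exact equivalence test against a brute-force O(n) scan written independently
of the implementation.

Unstated-by-convention parameters were fixed as follows:

* **Polarity** defaults to negative: extracellular somatic spikes are
  predominantly negative-going near the soma.
* **Dead time** defaults to 1 ms, comfortably above the refractory floor and
  below typical in-burst inter-spike intervals (~10 ms).
* **Cutout window** defaults to 1 ms before / 2 ms after the extremum —
  enough to contain the biphasic waveform and its rebound at 30 kHz.

## Spike sorting

Sorting is per channel: the cutout matrix is projected onto its top two
principal components and the scores are clustered with k-means. The number
of units is selected by mean silhouette width over k ∈ 2..5, with a fallback
to a single unit when the best silhouette is below 0.5 — a deliberately
conservative rule, since over-splitting is the more damaging error for
downstream rate statistics. Zero-variance cutout sets short-circuit to one
unit with a warning. k-means is seeded explicitly so results are
reproducible. Cross-channel template matching and drift correction are out
of scope; the simulator's spatial attenuation (below) is chosen so units are
effectively single-channel, matching this design.

## Channel and network statistics

* **Firing rate** is count/duration per channel; a channel is **active**
  when its rate strictly exceeds 0.5 Hz.
* **SNR** is the mean absolute spike peak amplitude divided by the SD of the
  channel's entire filtered trace. The "full signal" SD is computed on the
  filtered trace because the definition follows the filtering stage; silent
  channels report `NA`, never 0.
* **Correlation** is the Pearson product-moment correlation of spike counts
  binned at 10 ms, computed pairwise across channels. Half-open bins assign
  edge spikes to the later bin. Zero-variance channels yield missing
  entries; they are reported, not imputed, because an imputed 0 would be
  indistinguishable from measured independence.
* **Bursts** use a transparent maximum-ISI run rule: a burst is a maximal
  run of at least `min_spikes` (default 3) spikes with every ISI at most
  `max_isi_s` (default 100 ms). The field has many burst detectors; this one
  was chosen because it is exactly checkable against an independent run-scan
  oracle, which the tests do on 1000 random trains.
* **Box summaries** pin the quartile method to linear interpolation between
  order statistics (type 7) so that whiskers (box edge ± 1.5·IQR, clipped to
  the data range) and outliers are reproducible to the last digit.

## Layout geometry

Four generators cover the layout families used on custom MEAs, all in µm
with the origin at the array centroid and y up:

* `make_rect()` — 59 (the commercial-compatible 8×8 footprint minus corners
  and one reference site, 200 µm pitch, 30 µm diameter), 128 (12×11 minus
  corners), 256 (16×16), 512 (23×23 minus the 17 corner-most sites). The
  published figures do not print which grid position hosts the 59-layout
  reference site nor the exact 128/256/512 pitches; the reference site is
  placed at the left column mid-height and pitches default to 200 µm,
  configurable. Capacities other than 59 carry four dedicated
  stimulation-site annotations just outside the grid edges.
* `make_curved()` — every electrode row is bent onto a circular arc of
  radius 1/κ (default κ = 0.35 mm⁻¹, matching cortical curvature),
  preserving along-arc pitch. All rows share the same radius with vertically
  translated centres, so a circle fit to *any* row recovers 1/κ — the
  property the geometry is validated by. (Strictly concentric arcs would
  give each row a different curvature and break that invariant, which is why
  equal radii were chosen.)
* `make_perturbed()` — i.i.d. displacements drawn uniformly from the disk
  of radius `max_disp_um` (default 50 µm, bounded above by pitch/2 to
  exclude collisions). The uniform-disk choice is the maximum-entropy
  reading of "random displacements up to 50 µm"; the bound is verified over
  1000 seeds.
* `make_multiwell()` — n independent near-square grids with well spacing
  validated so that every inter-well electrode distance exceeds the largest
  intra-well distance, keeping wells geometrically separable.

## Stimulation protocols

`compile_biphasic()` expands trains of charge-balanced biphasic pulses
(positive phase then negative phase, each 400 µs by default, immediate
transition) at 20 Hz for 1 s per train; `compile_optical()` expands light
trains (default 40 Hz, 20% duty cycle, 1 s train every 5 s). Pulses are
anchored at the train start with period 1/rate and partial trailing pulses
are dropped (floor), a convention the compilers enforce identically so pulse
counts are exact. Compiled timelines are flat (t_on, t_off, level) tables
checked by `validate_timeline()` for ordering, overlap, and containment.
Amplitude values are voltage commands to an external stimulator; their
electrode-level effect is hardware-specific and out of scope.

## Calcium analysis

ΔF/F0 = (F − F0)/F0. "Initial fluorescence intensity" is operationalised as
the mean of the first second of frames (100 frames at the conventional
100 fps); a 10th-percentile baseline is available for drifting traces, and a
numeric F0 can be supplied directly. Event onsets are upward threshold
crossings separated by a minimum interval. LFP extraction low-passes at
100 Hz (order 3, zero-phase) and decimates to 1 kHz; the band is a declared
default, not a published constant. The two modalities are aligned by their
first edges: the first upward crossing of half the series' own peak,
linearly interpolated between samples. The half-peak fraction is a declared
default; on the simulator's joint data, calcium and LFP onsets align within
150 ms, consistent with a fast shared initiation phase.

## The simulator, and what passing tests do not show

`simulate_trains()` superposes per-channel homogeneous Poisson background
(default 2 Hz) with population bursts (default 0.2 Hz, 10 spikes per burst
at 10 ms ISI, small Gaussian timing jitter), thinned to a 2 ms refractory
floor. `render_recording()` inserts a biphasic difference-of-Gaussians
template (default −50 µV peak, 0.5 ms width) at each spike, attenuated
across the array by exp(−d/60 µm) — under 4% at a 200 µm neighbour, keeping
units effectively single-channel — over white Gaussian noise (default
5 µV SD, i.e. a 10× peak-to-noise ratio). `render_fluorescence()` convolves
the population rate with a (1 − e^(−t/rise)) · e^(−t/decay) kernel (rise
50 ms, decay 3 s) on top of F0.

The simulator emulates what the pipeline needs to be *checkable*: known
spike identities, controlled noise, controlled synchrony structure. It does
not emulate electrode drift, correlated or non-Gaussian noise, overlapping
spikes from multiple units on one channel, bursting non-stationarity, or
photobleaching. Passing the recovery tests therefore demonstrates that the
chain is internally correct and unbiased under its own assumptions — not
that it meets any particular accuracy on biological data.

Filter ringing is a real effect the simulator exposes: a sharp biphasic
template passed through the band-pass leaves oscillatory sidelobes of a few
percent of the peak. At the default 10× peak-to-noise this sits far below
threshold; at very high peak-to-noise ratios the sidelobes themselves can
cross a very low threshold, which is a property of threshold detection on
filtered data generally, not of this implementation.

## Problem sizes and numerical tolerances

The test suite fixes seeds everywhere and uses sizes chosen to make the
statistical assertions sharp at interactive runtimes: 1e6 samples for the
noise-estimator calibration (±1%), 100 random traces for exact
detection-oracle equivalence, 1000 trains for exact burst-oracle
equivalence, 1e−12 for correlation against a two-pass oracle, 20 seeds of
8-channel, 10 s, 30 kHz recordings for firing-rate recovery within 10%, and
20 seeds of 4-well, 120 s spike-train scenarios for the within-well versus
across-well correlation ordering. Curved-layout circle fits use an algebraic
(Kasa) least-squares fit, which is exact on noiseless arcs; curvature is
recovered to 1e−6 relative error.
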