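---
title: "Segmenting short particle trajectories with a sliding-window 1D U-Net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting short particle trajectories with a sliding-window 1D U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajseg)
```

## The model and its assumptions

A tracked vesicle alternates between directed, motor-driven runs and
non-directed behaviour (pauses, free diffusion, confinement). `trajseg`
labels every point of a 2D trajectory as `moving` (directed) or
`not_moving` (everything else). The central assumptions are:

* one point per consecutive frame (frame gaps are tolerated on read with a
  warning, but points are treated as consecutive);
* motion class is decidable from *local* displacement structure — an 8-point
  context window — rather than from long-range statistics such as a fitted
  MSD curve;
* absolute position carries no class information, only displacements do
  (the per-window origin normalization enforces this exactly, and tests
  verify full translation invariance of the predictions).

The classifier is a small 1D encoder–decoder over window positions: two
convolution + ReLU + maxpool(2) blocks, a bottleneck convolution, two
up-conv + skip-concatenation + convolution blocks, and a 1×1 convolution
with a sigmoid read as per-point `P(moving)`. With two classes, one sigmoid
channel plus its complement is equivalent to a two-channel softmax, and
binary cross-entropy is the matching likelihood loss. The network,
backpropagation and the Adam optimizer are implemented in the package in
plain R matrix algebra; at `W = 8` and 16/32/64 channels (~41k parameters)
this trains in CPU-minutes, and every analytic gradient is tested against
numerical differentiation.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `W` | 8 points | window length; must be divisible by 4 so two maxpools fit |
| `step` | `round(0.25 W)` = 2 | stride between window starts |
| `center_fraction` | 0.5 | fraction of each window stitched into the result |
| `learning_rate` | 1e-4 | Adam step size |
| `epochs` / `batch_size` | 200 / 32 | sized for CPU-minutes training on a few thousand windows |
| `coord_system` | `"polar"` | `(r, θ)` features; `"cartesian"` keeps `(x, y)` displacements |
| `include_padded_points_in_loss` | `TRUE` | padded tail counts as `not_moving` in the loss |

The window geometry and the learning rate follow the segmentation protocol
the package implements; epochs, batch size and shuffling are package
choices (nothing in the protocol pins them) and are fully exposed.

## Design choices where the protocol is open

Several details are underdetermined by the protocol; the package fixes
them as follows and documents each as its own choice:

* **Padding constant.** Short tracks are padded "with constant values";
  the package repeats the *last observed point*, making the pad a
  zero-displacement tail — exactly the stalled behaviour the pad is
  labelled as. Zero-padding the coordinates would instead inject a large
  artificial jump back to the origin after normalization.
* **Final stride.** Whether a trailing partial stride is dropped or
  snapped is unstated; the final window start is snapped to `L − W`, so
  the tail is always covered. A brute-force (point, window) enumeration
  oracle in the tests confirms every index is covered for all lengths
  8–60.
* **Overlap resolution.** With step 2 and a centre block of 4, interior
  centre blocks overlap pairwise. Overlapping probabilities are
  *averaged* before thresholding (not overwritten, not re-thresholded
  per window), which avoids quantization seams; stitching equality against
  an explicit contribution-list oracle is tested to 1e−12.
* **Ties.** A stitched probability of exactly 0.5 maps to `not_moving` —
  the conservative default for the rarer directed class.
* **θ convention.** `θ = atan2(y, x)` wrapped to `(−π, π]`, defined as 0
  at the origin, used raw with no unwrapping across the window; the
  discontinuity at ±π is accepted as a representation artifact.
* **Single-channel head.** "Two classes" could also be read as a
  two-channel output; the binary single-sigmoid reading is adopted as the
  exactly equivalent and simpler form.
* **Skip connections** are channel concatenation; up-sampling is a learned
  transposed convolution (kernel 2, stride 2). Channel widths (16→32→64)
  and kernel size 3 are package choices sized to `W = 8`.
* **Accuracy averaging.** Point accuracy is micro-averaged over all scored
  points (`correct / Σ(Lᵢ − 1)`), the plain reading of "accuracy of the
  segmentation"; per-trajectory accuracies are also reported for
  inspection.

## Numerical details

Probabilities are clamped to `[1e−7, 1 − 1e−7]` inside the loss so it is
always finite; training aborts with a diagnostic if the loss still becomes
non-finite (learning-rate or data pathology). Maxpool ties route the
gradient to the earlier position. Weight initialization is Glorot-uniform
from the model seed; the global RNG state is saved and restored around
every seeded stage, and one global seed derives per-stage seeds
(`simulation = seed + 1000`, `training = seed + 2000`) so pipeline stages
rerun in isolation reproduce the pipeline's artifacts bit for bit.

## What the simulator emulates — and what it does not

The synthetic generator reproduces the *structure* of short-track vesicle
datasets: many short trajectories (truncated-geometric lengths, default
mean 30, bounds 5–135), per-point two-class labels, and mixed regimes
within single tracks. Regimes switch with mean dwell 10 frames; per-frame
updates are

* directed: step of length `v` along a persistent heading with Gaussian
  jitter `σ_φ` (heading redrawn uniformly on state entry);
* Brownian: isotropic Gaussian steps, SD `σ_B`;
* confined: attraction `κ` toward an anchor (set on entry) plus Gaussian
  steps, SD `σ_C`;
* stalled: zero displacement;

all observed through additive Gaussian localization noise `σ_loc`. Labels
follow the true regime exactly.

The default `"separable"` preset (`v = 1.0`, `σ_B = σ_C = 0.25`,
`κ = 0.5`, `σ_loc = 0.05`, dwell 10) makes directed steps four times the
diffusive step scale, so per-point label recovery is genuinely achievable
and the end-to-end tests can assert a meaningful bound (test accuracy
≥ 0.85 with either coordinate system). A `"hard"` preset (`v = 0.4`,
`σ_B = 0.3`) overlaps the regimes for stress testing, with no accuracy
guarantee.

What the simulator does **not** capture: annotator ambiguity at regime
boundaries (real labels come from human annotation; simulated labels
switch exactly at the state change), detection dropouts and blinking,
motion blur, anisotropic or spatially varying noise, and 3D motion
projected through a finite depth of field. Passing the synthetic
label-recovery bound therefore demonstrates that the pipeline is wired
correctly end to end and can learn displacement-scale structure — it does
not certify any particular accuracy on real microscopy data, where
reported accuracies are far from saturation.

## Problem sizes used in the tests

The test suite trains the full experiment once: 250 simulated tracks
(200 train / 50 test, ~2650 training windows), 200 epochs per coordinate
system — a few minutes on one CPU — plus a 500-epoch overfit check on 10
windows and a 10⁴-step diffusion fidelity check. The windowing and
stitching oracles sweep all padded lengths 8–60.

## Known limitations

* Two classes only; distinguishing stalled from confined from Brownian
  within `not_moving` would need a multi-class head and labels.
* No post-hoc smoothing of the label sequence (no HMM decoding or
  minimum-run-length constraint); isolated single-point flips can occur
  at window seams.
* 2D trajectories only.
* Windows shorter than 8 points of context at track ends are informed
  only by the padded tail, which biases very short tracks toward the
  `not_moving` class by construction — intended behaviour, since the pad
  *is* stalled.
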