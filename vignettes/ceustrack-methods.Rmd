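---
title: "Lesion tracking in contrast-enhanced ultrasound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion tracking in contrast-enhanced ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceustrack)
```

## The problem

In gastrointestinal-filling contrast-enhanced ultrasound (CEUS) of the
stomach, a gastric-wall lesion appears as a hypoechoic (darker-than-tissue)
region that moves through the frame with respiration, probe motion and
peristalsis. A sonographer annotates the lesion once, on the first frame; the
tracker's job is to report the lesion's bounding box on every later frame so
that downstream measurements (size, wall invasion, perfusion) refer to the
same tissue. `ceustrack` implements such a tracker, the metrics used to
grade it, a synthetic scene generator used to exercise everything without
clinical data, and the contingency-table statistics used when CEUS staging
calls are compared against a pathological gold standard.

## The tracking pipeline

Each frame transition runs through the following stages.

**MSRCP enhancement.** Multiscale Retinex with chromaticity preservation.
The intensity channel $I$ (mean of the channels for RGB input) is processed
in the log domain against Gaussian surrounds at scales $\sigma \in \{15, 80,
250\}$ px with equal weights,
$\mathrm{MSR} = \frac{1}{K}\sum_k \left[\log(1+I) - \log(1+G_{\sigma_k} * I)\right]$,
stretched back to the original range by simplest color balance (percentile
clipping at 1%/99%), and the per-pixel gain $A = I_\text{enh}/I$ is applied
to every channel equally so channel ratios are preserved exactly. Where the
brightest channel would clip, the whole pixel is rescaled rather than
clipped per channel — that keeps chromaticity exact at the cost of slightly
dimming saturated pixels. Uniform and all-zero images are returned
unchanged (the stretch and the gain are undefined there, and a Retinex of a
constant is the constant). The Gaussian surrounds are applied in the
frequency domain with periodic boundary, so the largest scale costs the
same as the smallest and never builds a spatial kernel bigger than the
frame. Inside the tracker the percentile bounds are computed once, on the
first frame, and frozen for the whole sequence: a per-frame stretch
flickers as the moving lesion shifts the image's quantiles, and a
downstream flow solver reads that flicker as global apparent motion —
freezing the stretch halved the benchmark's mean tracking error.

**HSV features.** Frames are reduced to the value channel $V = \max(R,G,B)$
for motion and appearance processing; `rgb_to_hsv_img()` implements the full
conversion with the standard branch set ($H = 60(G-B)/d$ when $V=R$,
$120 + 60(B-R)/d$ when $V=G$, $240 + 60(R-G)/d$ when $V=B$, wrapped into
$[0, 360)$, $S = d/\max$, $H \equiv 0$ where $S = 0$). Grayscale frames pass
through untouched; a replication mode in the generator produces 3-channel
frames so the color path is exercisable.

**Differential optical flow.** Dense Lucas–Kanade: both frames are smoothed
(Gaussian $\sigma = 1$), spatial gradients are taken on their average,
the temporal gradient is the difference, and each pixel solves the windowed
(5×5) least-squares normal equations. Pixels whose structure tensor has a
smallest eigenvalue below $10^{-4}$ — flat speckle plateaus and borders —
get zero flow. Three warp-and-re-solve iterations remove the linearization
bias near the top of the small-motion regime: one-shot estimates overshoot
a 2 px shift by roughly 25%, while the iterated solver recovers shifts of
up to 2 px/frame to within a few hundredths of a pixel on textured
patterns. Velocities whose magnitude exceeds `max_flow` (5 px/frame) are
zeroed: the differential solver cannot measure such motion, so they are
artifacts of near-singular tensors, and left in place they occasionally
catapult a particle out of the frame. Larger displacements are out of
scope (no pyramids), which is the regime boundary the synthetic benchmark
respects.

**Flow summaries.** For a region of $z$ pixels the components are summed,
$h = (\sum v_r, \sum v_c)^\top$, and the motion intensity is
$w = \lVert h \rVert / z$ — the magnitude of the mean motion vector, in
px/frame. A temporally maintained reference model blends the summed flow of
the selected region as an exponential moving average,
$h_\alpha \leftarrow (1-\beta)\,h_{\alpha} + \beta\,h_s$ with update factor
$\beta = 0.5$ by default, and replaces $w_\alpha$ with the current frame's
intensity. $\beta = 0$ freezes the reference, $\beta = 1$ forgets it; a
constant input is a fixed point for every $\beta$.

**Particle filter.** 100 particles are initialized around the annotation
(isotropic Gaussian, sd = half the box diagonal) with uniform weights. Each
frame they are first *advected* by the local flow sampled at their centers —
on a static-background scene, particles riding the lesion move with it and
background particles stay put — and then refined by three mean-shift steps
toward the centroid of the local flow magnitude (window = twice the box
size, so particles sense the lesion's motion energy from anywhere in the
weight plateau; steps capped at 4 px). Motion energy is concentrated on the moving lesion, so this
is gradient ascent on the motion-energy surface and it is what keeps the
cloud centered; disabling it (`ms_iterations = 0`) degrades mean tracking
error several-fold. Weights are the Gaussian kernel of each particle's flow
similarity deficit,
$q_i \propto \exp\!\big(-(\mathrm{Consi}_i - \mathrm{Consi}_{\max})^2 / 2\varepsilon^2\big)$,
$\varepsilon = 0.2$, where $\mathrm{Consi}$ is the cosine similarity between
the particle region's summed flow and the reference $h_\alpha$ (zero when
either vector is zero: no motion carries no directional information). The
kernel's constant prefactor cancels under normalization and is dropped;
weights always sum to one, falling back to uniform (with a warning) only if
every kernel value underflows. Systematic resampling preserves the particle
count and jitters offspring by 1 px to restore diversity.

**Candidates and CNN classification.** The top-10 particles by weight
(ties to the lower index, centers deduplicated at 1 px) become candidate
boxes. Candidates implying a single-frame jump larger than `max_step = 5` px
are discarded as physically implausible in the small-motion regime — without
this gate an early misclassification can teleport the box tens of pixels.
A small convolutional network (3×3 conv ×8 → pool → 3×3 conv ×16 → pool →
dense 64 → softmax) scores each candidate patch; the argmax-score candidate
becomes the new position, and the flow model is then updated over it.
While the flow model reports motion intensity below 0.05 px/frame the
previous box is offered as an extra zero-motion candidate: on a static
scene the particle weights carry no positional information and the
incumbent is the only anchored hypothesis. On moving scenes the incumbent
is withheld — scored head-to-head it tends to win narrow appearance ties
and freezes the tracker.

**Classifier training.** The network trains per sequence on the annotated
first frame: positives are crops of boxes jittered by at most 1 px around
the annotation (a deliberately tight subset of the IoU ≥ 0.7 jitter range —
training 3 px offsets as positives teaches the network that 3 px offsets
are fine, and its score then cannot rank candidates at the 2 px scale),
negatives are same-size background crops with IoU ≤ 0.3 (half sampled near
the target so hard near-misses are seen). Each patch is
resampled bilinearly to 32×32 and the set is doubled by appearance
augmentation (random global gain and a smooth multiplicative noise field —
the same lesion seen over a different speckle realization). Patches are
standardized per patch (zero mean, unit sd) before entering the network:
the lesion's signature is a centrally placed dark blob *relative to its
surround*, and absolute brightness is a confounder on speckle backgrounds
where some background patches are as dark as the lesion. Training is
full-batch gradient descent with momentum, label smoothing 0.05 (so scores
stay graded rather than saturating at 0/1 — an argmax over saturated scores
is decided by float noise) and weight decay $10^{-4}$; 40 epochs on ~48
patches takes a few seconds on one CPU. An optional online-adaptation step
(`update_interval`) can continue training on patches from later frames; it
is off by default because on the synthetic benchmark it reinforces drift
more than it helps.

Classifier patches are cut from a despeckled copy of the enhanced frame
(Gaussian $\sigma = 2$): at the candidate-ranking stage speckle texture is
noise, and the blob geometry is the signal.

## The synthetic scene generator

The generator emulates what the tracker sees in gastrointestinal-filling
CEUS, with known ground truth:

- **Speckle.** A unit-mean multiplicative field: a zero-mean Gaussian field,
  low-pass filtered (grain sigma 1.2 px) and squared — fully developed
  speckle is multiplicative and positively skewed — normalized to mean one
  and blended with the constant field by `speckle_scale` (default 0.4).
  The field is *static across frames*, the behaviour of tissue speckle
  under a stationary probe; optional additive per-frame noise is available
  and off by default.
- **Lesion.** A hypoechoic ellipse (semi-axes 9×6 px, contrast 0.5, i.e. the
  interior mean is half the background mean) with a raised-cosine edge over
  the outer 35% of its radius, multiplied into the background. The interior
  keeps the speckle's relative variance, as echo-poor tissue does.
- **Trajectory.** Linear (default: start (34, 28), velocity (0.35, 0.7)
  px/frame — inside the flow solver's small-motion regime), sinusoidal, or
  random walk; the analytic center is the ground truth, the box is the
  ellipse's bounding box and never changes size (rigid lesion).
- **Wash-in.** An optional saturating-exponential global gain emulates
  contrast arrival.
- **Scale.** 96×96 px, 50 frames, 8-bit gray levels; frames are quantized to
  integers so in-memory stacks round-trip bit-exactly through PNG/TIFF.

These defaults constitute the package's standard benchmark: 20 sequences
(seeds 1–20) tracked by the full pipeline and by a flow-only ablation
(`use_cnn = FALSE`, position = argmax-weight particle). What the benchmark
does *not* emulate — tissue deformation, out-of-plane motion, shadowing,
probe pressure changes, speckle decorrelation — bounds what passing it
shows: the pipeline works where its assumptions (rigid lesion, static
background speckle, small per-frame motion) hold, which is also the regime
the underlying flow model is valid in.

## Metrics

- **CLE** — mean Euclidean distance (px) between predicted and true centers;
  the truth's exact analytic center is used when available, so box-grid
  quantization (up to half a pixel per axis) is charged to the tracker.
- **TOAR** — intersection-over-union of the predicted and true boxes,
  computed on the closed-form rectangle overlap and tested against a
  brute-force pixel-set count.
- **SI** — one minus the Bhattacharyya coefficient of two regions'
  normalized gray-level histograms (64 bins over the 8-bit range): 0 for
  identical distributions, 1 for disjoint support; reported between the
  first frame's tracked region and each later frame's. A `literal = TRUE`
  variant computes the raw cross-correlation normalization
  $1 - \sum H_1 H_2 / (\sum H_1 \sum H_2)$ for comparison; its denominator
  is identically 1 for normalized histograms, which is why the
  Bhattacharyya form is the default.

## Diagnostics

The clinical module reproduces the cohort statistics: per-stage predicted
positive rate $100\,d/g$ (gold-stage denominators — detection is counted
among pathologically staged cases), resectability sensitivity/specificity/
accuracy from a 2×2 table at two decimals, and a per-stage between-modality
comparison as a 2×2 Pearson χ² with continuity correction, replaced by
Fisher's exact test (and flagged) when any expected cell is below 5. The
shipped tables give CEUS 95.60 / 81.82 / 94.12 and CT 89.01 / 63.64 / 86.27
percent; the CT specificity is derived from its counts (7 of 11). The χ²
on 2×2 detection tables is used for the modality comparison because it is
the standard test for paired detection proportions of this shape; omnibus
ANOVA on count data is not reproducible from the published counts.

## Numerical choices and degenerate inputs

- Boxes are 1-based `(row, col, height, width)` in memory, 0-based and
  half-open on disk (`frame,row,col,height,width` CSVs); centers live on the
  pixel-index grid.
- Candidate score ties break by higher particle weight, then lower index;
  the weight-ranking tie in `candidates()` breaks by lower particle index.
- Zero-area boxes give TOAR 0 with a warning; empty regions, mismatched
  shapes and out-of-frame boxes are errors.
- The flow solver returns exact zeros where the structure tensor is
  near-singular rather than amplifying noise.
- All randomness (scene, particles, network initialization, augmentation,
  resampling) flows from a single seed per run; two runs with identical
  inputs are byte-identical, which the test suite asserts.

## Problem sizes used by the checks

The test suite and the acceptance script run the benchmark at its native
size (20 seeds × 50 frames of 96×96 px, both tracker variants, about three
minutes on one CPU), the flow oracle on 120×120 textured patterns, the
resampling Monte Carlo at 10,000 draws of 10 particles, and the TOAR oracle
on 1,000 random box pairs.

## Known limitations

- Box size is fixed to the annotation; no scale adaptation.
- Single target; no occlusion handling or re-detection.
- The flow solver is non-pyramidal: displacements much beyond 2 px/frame
  are outside the design envelope (the `max_step` gate reflects this).
- The classifier is trained from one annotated frame; appearance changes
  far from the training distribution (e.g. strong wash-in combined with
  fast motion) degrade its ranking, and the particle filter then carries
  the tracker.
- On a *noise-free* synthetic scene the Retinex surrounds paint a broad
  halo around the lesion; the halo moves with the lesion and smears the
  motion-energy surface the mean-shift step climbs. Enhancement exists to
  normalize low-contrast speckled imagery — on noise-free scenes it has
  nothing to normalize and `enhance = FALSE` tracks several times more
  precisely. The test suite exercises both paths.
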