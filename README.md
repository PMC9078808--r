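# ceustrack

Lesion tracking in contrast-enhanced ultrasound (CEUS) image sequences, with
the evaluation metrics and clinical contingency-table statistics that go with
it.

## What problem this solves, and for whom

In gastrointestinal-filling CEUS of the stomach, a gastric-wall lesion shows
up as a hypoechoic (darker) region that drifts through the frame with
breathing and probe motion. A sonographer marks the lesion once, on the first
frame; everything downstream — size measurements, wall-invasion assessment,
staging calls — needs the lesion's position on every later frame. `ceustrack`
is for researchers building or evaluating such trackers: it provides the
tracker itself, a synthetic CEUS scene generator with exact ground truth so
the pipeline can be exercised and graded without clinical data, and the
diagnostic statistics used when imaging staging calls are compared against
pathology.

## The method

The tracker (called D-CNN: differential optical flow + CNN) runs, per frame:

1. **MSRCP enhancement** — multiscale Retinex (Gaussian surrounds at
   σ ∈ {15, 80, 250} px) on the intensity channel with percentile
   stretching; the per-pixel gain is replicated across channels so
   chromaticity is preserved. HSV features: V = max(R, G, B).
2. **Differential optical flow** — dense Lucas–Kanade from spatiotemporal
   gradients (5×5 window, Gaussian presmoothing σ = 1, iterative
   refinement), valid for displacements ≲ 2 px/frame.
3. **Particle filter** — n = 100 particles advected by the local flow and
   mean-shifted onto the local motion-energy centroid; each particle's
   regional flow vector R_k is compared with a temporally maintained
   reference h_α (exponential moving average, update factor β = 0.5) by
   cosine similarity, and weights follow the Gaussian kernel
   q_i ∝ exp(−(Consi_i − Consi_max)² / 2ε²), ε = 0.2, normalized to sum 1.
   Systematic resampling with 1 px jitter.
4. **CNN classification** — the top-k particle regions become candidate
   boxes; a small per-sequence-trained convolutional network (two 3×3 conv
   layers, 8/16 filters, max-pooling, 64-unit embedding, softmax) scores
   each 32×32-normalized candidate patch, and the argmax-score candidate is
   the new position.

Evaluation uses the standard tracking metrics: **CLE** (mean center location
error, px), **TOAR** (intersection-over-union of predicted and true boxes),
and **SI** (1 − Bhattacharyya coefficient of gray-level histograms; lower is
better). The diagnostics module computes per-stage predicted positive rates
(PPR = 100·detected/gold), resectability sensitivity/specificity/accuracy,
and per-stage χ² modality comparisons, and ships the 102-patient
gastric-cancer cohort tables it reproduces.

## Worked example

```r
library(ceustrack)

# a 50-frame synthetic CEUS scene: static speckle, moving hypoechoic lesion
scene <- ceus_scene(seed = 11)
seq <- generate_sequence(scene)

# annotate frame 1 with the true box, then track
init <- with(seq$truth[1, ], ceus_box(row, col, height, width))
traj <- track_lesion(seq, init, seed = 11)
traj
#> <ceus_trajectory: 50 frames, 18x12 box>
#>   frame row col height width     score
#> 1     1  26  22     18    12        NA
#> 2     2  27  22     18    12 0.9695531
#> 3     3  28  23     18    12 0.9732907
#> 4     4  27  25     18    12 0.9366705
#> 5     5  27  25     18    12 0.9511265
#> ... 45 more frames

evaluate_tracking(traj, seq$truth, seq$frames)
#> Tracking evaluation over 50 frames
#>   mean CLE :  0.961 px
#>   mean TOAR:  0.871
#>   mean SI  :  0.083
```

The mean center error is under a pixel on an 18×12 px target, the predicted
box overlaps the true box at IoU ≈ 0.87 on average, and the tracked region's
gray-level distribution stays close to the first frame's (SI ≈ 0.08; 0 would
be identical histograms).

The clinical statistics reproduce the cohort's printed values from raw
counts:

```r
binary_performance(tp = 87, fn = 4, tn = 9, fp = 2)
#> sensitivity specificity    accuracy
#>       95.60       81.82       94.12

positive_rate(gold_n = 19, detected_n = 17)
#> [1] 89.47
```

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/ceustrack.R simulate --config scene.yaml --out frames/
Rscript inst/cli/ceustrack.R track --frames frames/ --init "25,21,18,12" \
    --seed 7 --out traj.csv
Rscript inst/cli/ceustrack.R eval --pred traj.csv --truth frames/truth.csv \
    --frames frames/ --report report.json
Rscript inst/cli/ceustrack.R stats --in counts.csv --out summary.json
```

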